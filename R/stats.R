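# Group-comparison chain -------------------------------------------------------
#
# The reporting chain used for every grouped measurement: Shapiro-Wilk
# normality check (reported alongside, never switching the test), one-way
# ANOVA, and Tukey's multiple comparison with the Tukey-Kramer correction for
# unbalanced groups.

#' Pool isogenic-control lines per patient
#'
#' Measurements from the isogenic-control lines of each patient are merged
#' into one pooled group (raw measurements pooled by default); edited lines
#' remain separate groups.
#'
#' @param records Tibble with columns `line` and `value`.
#' @param lineage_map Tibble `line`, `role` with role in
#'   `"edited"` / `"isogenic_control"`.
#' @param patient_map Tibble `line`, `patient`.
#' @param per_line_means Pool per-line means instead of raw measurements.
#' @return Tibble `group`, `value`; control groups are labelled
#'   `"<patient>-control"`.
#' @export
pool_isogenic_controls <- function(records, lineage_map, patient_map,
                                   per_line_means = FALSE) {
  stopifnot(all(c("line", "value") %in% names(records)))
  unmapped <- setdiff(unique(records$line),
                      intersect(lineage_map$line, patient_map$line))
  if (length(unmapped))
    oq_abort(paste("line(s) missing from the maps:",
                   paste(unmapped, collapse = ", ")), "parameter")
  d <- records |>
    dplyr::left_join(lineage_map, by = "line") |>
    dplyr::left_join(patient_map, by = "line") |>
    dplyr::mutate(group = ifelse(.data$role == "isogenic_control",
                                 paste0(.data$patient, "-control"),
                                 .data$line))
  if (per_line_means)
    d <- d |>
      dplyr::group_by(.data$group, .data$line) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  d |> dplyr::select("group", "value")
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric vector, 3 <= n <= 5000, not all equal.
#' @return One-row tibble: `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000)
    oq_abort("Shapiro-Wilk requires 3 <= n <= 5000.", "parameter")
  if (var(x) == 0)
    oq_abort("Shapiro-Wilk undefined for a constant sample.", "degenerate")
  sw <- shapiro.test(x)
  tibble(statistic = unname(sw$statistic), p_value = sw$p.value)
}

# validate and coerce a group/value tibble
check_groups <- function(data, group = "group", value = "value",
                         min_groups = 2) {
  stopifnot(all(c(group, value) %in% names(data)))
  g <- as.character(data[[group]])
  v <- as.numeric(data[[value]])
  if (any(!is.finite(v))) oq_abort("non-finite measurement value(s).", "parameter")
  sizes <- table(g)
  if (length(sizes) < min_groups)
    oq_abort(sprintf("need >= %d groups.", min_groups), "parameter")
  if (any(sizes < 2))
    oq_abort("every group needs >= 2 measurements.", "parameter")
  tibble(group = g, value = v)
}

#' One-way ANOVA
#'
#' `F = MS_between / MS_within` with `(k - 1, N - k)` degrees of freedom.
#' If all group means coincide (including the fully degenerate case of
#' identical data), `F = 0` and `p = 1`.
#'
#' @param data Tibble with group labels and measurements.
#' @param group,value Column names (default `"group"`, `"value"`).
#' @param welch Use Welch's heteroscedasticity-robust variant (off by
#'   default; the classical equal-variance form is the chain's standard).
#' @return An `oq_anova` object; see [tidy()]/[glance()] methods.
#' @export
one_way_anova <- function(data, group = "group", value = "value",
                          welch = FALSE) {
  d <- check_groups(data, group, value)
  if (welch) {
    w <- stats::oneway.test(value ~ group, data = d, var.equal = FALSE)
    gm <- tapply(d$value, d$group, mean)
    ns <- tapply(d$value, d$group, length)
    return(structure(
      list(statistic = unname(w$statistic), p_value = w$p.value,
           df_between = unname(w$parameter[1]),
           df_within = unname(w$parameter[2]),
           ms_within = NA_real_, group_means = gm, group_ns = ns, data = d,
           welch = TRUE),
      class = "oq_anova"))
  }
  k <- length(unique(d$group))
  n <- nrow(d)
  gm <- tapply(d$value, d$group, mean)
  ns <- tapply(d$value, d$group, length)
  grand <- mean(d$value)
  ss_between <- sum(ns * (gm - grand)^2)
  ss_within <- sum((d$value - gm[d$group])^2)
  df_b <- k - 1
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ss_between <= 0) {
    f <- 0; p <- 1
  } else if (ms_w == 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_b / ms_w
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(
    list(statistic = f, p_value = p, df_between = df_b, df_within = df_w,
         ms_within = ms_w, group_means = gm, group_ns = ns, data = d,
         welch = FALSE),
    class = "oq_anova"
  )
}

#' @export
print.oq_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F(%g, %.4g) = %.4g, p = %.4g\n",
              if (isTRUE(x$welch)) " (Welch)" else "",
              x$df_between, x$df_within, x$statistic, x$p_value))
  invisible(x)
}

#' @rdname one_way_anova
#' @param x An `oq_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.oq_anova <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within,
         ms_within = x$ms_within, n_groups = length(x$group_means),
         n = sum(x$group_ns))
}

#' @rdname one_way_anova
#' @exportS3Method generics::tidy
tidy.oq_anova <- function(x, ...) {
  tibble(group = names(x$group_means),
         n = as.integer(x$group_ns),
         mean = as.numeric(x$group_means))
}

#' Tukey's multiple comparison (Tukey-Kramer)
#'
#' For each pair of groups,
#' `q = |mean_i - mean_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))` and the
#' adjusted p-value comes from the studentized-range distribution with `k`
#' groups and the ANOVA's within degrees of freedom. The Tukey-Kramer form
#' handles unbalanced groups.
#'
#' @param x An `oq_anova` fit from [one_way_anova()], or a tibble of
#'   measurements (then `group`/`value` name the columns).
#' @param group,value Column names when `x` is a tibble.
#' @return Tibble: `group1`, `group2`, `diff` (mean1 - mean2), `q`, `p_adj`.
#' @export
tukey_hsd <- function(x, group = "group", value = "value") {
  fit <- if (inherits(x, "oq_anova")) x else one_way_anova(x, group, value)
  gm <- fit$group_means
  ns <- fit$group_ns
  k <- length(gm)
  pairs <- utils::combn(names(gm), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    dd <- gm[[g1]] - gm[[g2]]
    se <- sqrt(fit$ms_within / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- if (se == 0) { if (dd == 0) 0 else Inf } else abs(dd) / se
    p <- if (is.infinite(q)) 0 else
      ptukey(q, nmeans = k, df = fit$df_within, lower.tail = FALSE)
    tibble(group1 = g1, group2 = g2, diff = dd, q = q, p_adj = p)
  })
}

#' Full group-comparison report
#'
#' Runs the whole chain on grouped measurements: per-group Shapiro-Wilk
#' normality (reported, not acted on), one-way ANOVA and Tukey's post-hoc
#' comparisons.
#'
#' @inheritParams one_way_anova
#' @return An `oq_group_report`: list with `normality` (tibble), `anova`
#'   (`oq_anova`) and `tukey` (tibble).
#' @export
group_report <- function(data, group = "group", value = "value") {
  d <- check_groups(data, group, value)
  normality <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(dd, key) {
      if (length(dd$value) < 3 || var(dd$value) == 0)
        tibble(statistic = NA_real_, p_value = NA_real_)
      else shapiro_wilk(dd$value)
    }) |>
    dplyr::ungroup()
  fit <- one_way_anova(d)
  structure(list(normality = normality, anova = fit, tukey = tukey_hsd(fit)),
            class = "oq_group_report")
}

#' @export
print.oq_group_report <- function(x, ...) {
  print(x$anova)
  cat("Tukey pairs:\n")
  print(as.data.frame(x$tukey), digits = 4)
  invisible(x)
}
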