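# Thresholded colocalization volumes -------------------------------------------

#' Threshold one channel of a volume stack
#'
#' Produces the supra-threshold binary volume for a channel, by per-channel
#' Otsu (default; 256-bin histogram over all voxels) or a fixed threshold.
#' The threshold used is recorded for auditability.
#'
#' @param stack A [volume_stack()].
#' @param channel Channel name.
#' @param method `"otsu"` or `"fixed"`.
#' @param t Fixed threshold (required for `method = "fixed"`); voxels with
#'   intensity `>= t` are foreground.
#' @return Logical 3D array with attribute `threshold`.
#' @export
threshold_channel <- function(stack, channel, method = c("otsu", "fixed"),
                              t = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "volume_stack"))
  if (!channel %in% names(stack$channels))
    oq_abort(sprintf("channel '%s' not in the stack.", channel), "parameter")
  v <- stack$channels[[channel]]
  thr <- if (method == "otsu") otsu_threshold(as.vector(v)) else {
    if (is.null(t)) oq_abort("fixed thresholding needs `t`.", "parameter")
    t
  }
  structure(v >= thr, threshold = thr)
}

#' Thresholded volume of colocalization (TVC)
#'
#' The percentage of channel A's supra-threshold volume that overlaps channel
#' B's: `100 * |A n B| / |A|`. Note the asymmetry — A is the denominator.
#'
#' @param vol_a,vol_b Logical volumes of identical shape (from
#'   [threshold_channel()]).
#' @param pair Optional length-2 channel names recorded in the output.
#' @return One-row tibble: `channel_a`, `channel_b`, `percent`, `n_a`,
#'   `n_overlap`, `threshold_a`, `threshold_b`.
#' @export
tvc <- function(vol_a, vol_b, pair = c("A", "B")) {
  if (!identical(dim(vol_a), dim(vol_b)))
    oq_abort("volumes must share one shape.", "parameter")
  n_a <- sum(vol_a)
  if (n_a == 0) oq_abort("channel A's thresholded volume is empty.", "degenerate")
  n_ab <- sum(vol_a & vol_b)
  tibble(
    channel_a = pair[1], channel_b = pair[2],
    percent = 100 * n_ab / n_a,
    n_a = as.integer(n_a), n_overlap = as.integer(n_ab),
    threshold_a = attr(vol_a, "threshold") %||% NA_real_,
    threshold_b = attr(vol_b, "threshold") %||% NA_real_
  )
}

#' Colocalization report across regions
#'
#' For each stack: thresholds the `target`, `nuclear` and `neuronal` channels
#' and computes the TVC of target-in-nuclear and target-in-neuronal (target
#' volume as denominator), plus the reversed orientations for completeness.
#' With >= 2 regions, a one-way ANOVA of the target-denominator percentages
#' across regions is run per comparison.
#'
#' @param stacks List of [volume_stack()]s.
#' @param regions Character vector of region labels, one per stack (e.g.
#'   brain areas).
#' @param method,t Thresholding settings passed to [threshold_channel()].
#' @return An `oq_coloc_report`: list with `table` (per-stack TVC rows) and
#'   `stats` (named list of `oq_group_report` per comparison, `NULL` when
#'   fewer than 2 regions).
#' @export
coloc_report <- function(stacks, regions, method = "otsu", t = NULL) {
  stopifnot(length(stacks) == length(regions), length(stacks) >= 1)
  rows <- purrr::map_dfr(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    roles <- c("target", "nuclear", "neuronal")
    missing <- setdiff(roles, names(st$channels))
    if (length(missing))
      oq_abort(paste("stack missing channel role(s):",
                     paste(missing, collapse = ", ")), "parameter")
    vols <- lapply(setNames(roles, roles),
                   function(ch) threshold_channel(st, ch, method, t))
    dplyr::bind_rows(
      tvc(vols$target, vols$nuclear, c("target", "nuclear")),
      tvc(vols$target, vols$neuronal, c("target", "neuronal")),
      tvc(vols$nuclear, vols$target, c("nuclear", "target")),
      tvc(vols$neuronal, vols$target, c("neuronal", "target"))
    ) |>
      dplyr::mutate(region = regions[i], stack = i, .before = 1)
  })
  stats <- NULL
  if (length(unique(regions)) >= 2 && all(table(regions) >= 2)) {
    stats <- lapply(
      setNames(c("nuclear", "neuronal"), c("target_in_nuclear", "target_in_neuronal")),
      function(ch) {
        d <- rows |>
          dplyr::filter(.data$channel_a == "target", .data$channel_b == ch) |>
          dplyr::transmute(group = .data$region, value = .data$percent)
        group_report(d)
      })
  } else {
    warn("fewer than 2 regions (or < 2 stacks per region): statistics skipped.",
         class = "oq_warning_degenerate")
  }
  structure(list(table = rows, stats = stats), class = "oq_coloc_report")
}

#' @export
print.oq_coloc_report <- function(x, ...) {
  cat(sprintf("<oq_coloc_report> %d TVC rows, %d region(s)\n",
              nrow(x$table), length(unique(x$table$region))))
  if (!is.null(x$stats))
    for (nm in names(x$stats)) {
      cat(nm, ": ")
      print(x$stats[[nm]]$anova)
    }
  invisible(x)
}
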