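# Shapiro-Wilk / ANOVA / Tukey chain

test_that("isogenic-control pooling merges per patient", {
  recs <- tibble::tibble(
    line = c("p1-ctlA", "p1-ctlA", "p1-ctlB", "p1-ctlB", "p1-edit", "p2-ctlA",
             "p2-ctlB", "p2-edit", "p2-edit"),
    value = c(1, 2, 3, 4, 9, 5, 6, 7, 8))
  lineage <- tibble::tibble(
    line = c("p1-ctlA", "p1-ctlB", "p1-edit", "p2-ctlA", "p2-ctlB", "p2-edit"),
    role = c("isogenic_control", "isogenic_control", "edited",
             "isogenic_control", "isogenic_control", "edited"))
  patients <- tibble::tibble(line = lineage$line,
                             patient = rep(c("p1", "p2"), c(3, 3)))
  pooled <- pool_isogenic_controls(recs, lineage, patients)
  expect_setequal(pooled$value[pooled$group == "p1-control"], c(1, 2, 3, 4))
  expect_identical(sort(unique(pooled$group)),
                   c("p1-control", "p1-edit", "p2-control", "p2-edit"))
  expect_identical(unname(table(pooled$group)["p2-control"]), 2L)

  # no control lines: groups pass through unchanged
  edits <- dplyr::filter(recs, grepl("edit", line))
  pe <- pool_isogenic_controls(edits, lineage, patients)
  expect_setequal(unique(pe$group), c("p1-edit", "p2-edit"))

  expect_error(pool_isogenic_controls(
    tibble::tibble(line = "mystery", value = 1), lineage, patients),
    class = "oq_error_parameter")

  # per-line-mean mode pools line averages instead of raw values
  pm <- pool_isogenic_controls(recs, lineage, patients, per_line_means = TRUE)
  expect_setequal(pm$value[pm$group == "p1-control"], c(1.5, 3.5))
})

test_that("Shapiro-Wilk wrapper reproduces the reference behaviour", {
  x <- qnorm(ppoints(20))
  sw <- shapiro_wilk(x)
  expect_gt(sw$statistic, 0.99)
  y <- c(1, 1, 1, 2, 4, 8, 16, 32, 64, 128)
  expect_lt(shapiro_wilk(y)$p_value, 0.05)
  expect_error(shapiro_wilk(c(2, 2, 2, 2)), class = "oq_error_degenerate")
  expect_error(shapiro_wilk(c(1, 2)), class = "oq_error_parameter")
})

three_group_fixture <- function() {
  tibble::tibble(group = rep(c("a", "b", "c"), each = 3),
                 value = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
}

test_that("ANOVA matches hand sums of squares on the fixture", {
  fit <- one_way_anova(three_group_fixture())
  # by hand: group means 2, 3, 7; grand mean 4; SSB = 3*(4+1+9) = 42;
  # SSW = 6*1 = 6; F = (42/2)/(6/6) = 21
  expect_lt(abs(fit$statistic - 21), 1e-10)
  expect_lt(abs(fit$p_value - pf(21, 2, 6, lower.tail = FALSE)), 1e-10)
  expect_identical(c(fit$df_between, fit$df_within), c(2, 6L))
  g <- glance(fit)
  expect_identical(g$n, 9L)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  withr::with_seed(31, {
    d <- tibble::tibble(group = rep(c("x", "y"), c(7, 11)),
                        value = c(rnorm(7, 10, 2), rnorm(11, 12, 2)))
  })
  fit <- one_way_anova(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(fit$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("ANOVA F is shift- and scale-invariant and degenerates cleanly", {
  d <- three_group_fixture()
  f0 <- one_way_anova(d)$statistic
  d2 <- dplyr::mutate(d, value = 3.7 * value + 11)
  expect_equal(one_way_anova(d2)$statistic, f0, tolerance = 1e-12)
  # identical group means
  flat <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                         value = c(1, 2, 3, 3, 2, 1))
  ff <- one_way_anova(flat)
  expect_identical(ff$statistic, 0)
  expect_identical(ff$p_value, 1)
  expect_error(one_way_anova(tibble::tibble(group = c("a", "a", "b"),
                                            value = 1:3)),
               class = "oq_error_parameter")
})

test_that("the Welch variant relaxes the equal-variance assumption", {
  withr::with_seed(44, {
    d <- tibble::tibble(group = rep(c("a", "b", "c"), each = 8),
                        value = rnorm(24, rep(c(0, 0, 2), each = 8),
                                      rep(c(1, 1, 5), each = 8)))
  })
  cl <- one_way_anova(d)
  we <- one_way_anova(d, welch = TRUE)
  expect_true(isTRUE(we$welch))
  expect_lt(we$df_within, cl$df_within)  # Satterthwaite df shrink
  expect_false(identical(we$p_value, cl$p_value))
  # balanced equal-variance data: the two variants agree closely
  withr::with_seed(45, {
    dh <- tibble::tibble(group = rep(c("a", "b"), each = 50),
                         value = rnorm(100, rep(c(0, 1), each = 50)))
  })
  expect_equal(one_way_anova(dh, welch = TRUE)$p_value,
               one_way_anova(dh)$p_value, tolerance = 0.05)
})

test_that("Tukey q and p match the studentized-range oracle", {
  fit <- one_way_anova(three_group_fixture())
  tk <- tukey_hsd(fit)
  # cross-check against stats::TukeyHSD on the same data
  ref <- TukeyHSD(aov(value ~ group, data = three_group_fixture()))$group
  expect_equal(sort(tk$p_adj), sort(unname(ref[, "p adj"])), tolerance = 1e-8)
  # and against direct numeric integration of the q distribution
  for (j in seq_len(nrow(tk))) {
    p_oracle <- oracle_ptukey_upper(tk$q[j], k = 3, df = fit$df_within)
    expect_lt(abs(tk$p_adj[j] - p_oracle), 1e-6)
  }
})

test_that("identical groups give Tukey p near 1; gaps are monotone", {
  same <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                         value = rep(c(1, 2, 3, 4), 3))
  tk <- tukey_hsd(same)
  expect_true(all(tk$p_adj >= 0.99))

  # widening one group's mean gap monotonically decreases its adjusted p
  withr::with_seed(8, base <- rnorm(10))
  last_p <- 1
  for (gap in c(0.5, 1, 2, 4)) {
    d <- tibble::tibble(
      group = rep(c("a", "b", "c"), each = 10),
      value = c(base, base + 0.2, base + gap))
    p_ac <- dplyr::filter(tukey_hsd(d), group1 == "a", group2 == "c")$p_adj
    expect_lt(p_ac, last_p)
    last_p <- p_ac
  }
})

test_that("Tukey adjustment is never anti-conservative vs pairwise t", {
  withr::with_seed(12, {
    d <- tibble::tibble(group = rep(c("a", "b", "c", "d"), each = 6),
                        value = rnorm(24) + rep(c(0, 0.5, 1, 1.5), each = 6))
  })
  fit <- one_way_anova(d)
  tk <- tukey_hsd(fit)
  for (j in seq_len(nrow(tk))) {
    # unadjusted pairwise t on the same pooled error term (Fisher LSD):
    # t = q / sqrt(2) with the ANOVA's within degrees of freedom
    p_t <- 2 * pt(-tk$q[j] / sqrt(2), df = fit$df_within)
    expect_gte(tk$p_adj[j] + 1e-12, p_t)
  }
})

test_that("group_report assembles the full chain", {
  withr::with_seed(5, {
    d <- tibble::tibble(group = rep(c("ctl", "edit"), each = 12),
                        value = c(rnorm(12, 100, 10), rnorm(12, 130, 10)))
  })
  rep <- group_report(d)
  expect_identical(nrow(rep$normality), 2L)
  expect_true(all(rep$normality$p_value > 0))
  expect_lt(rep$anova$p_value, 0.01)
  expect_identical(nrow(rep$tukey), 1L)
  expect_s3_class(autoplot(rep), "ggplot")
})
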