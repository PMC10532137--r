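make_toy_cohort <- function(n1 = 8, n2 = 10, shift = 0, seed = 1) {
  set.seed(seed)
  base <- function(n, mu) data.frame(
    sv_csf_cerv = rnorm(n, mu, 1), alpha = rnorm(n, 1.5, 0.2),
    cbfa = rnorm(n, 700, 50), sv_blood = rnorm(n, 0.8, 0.1))
  rbind(cbind(group = "CS_with_syrinx", base(n1, 10 + shift)),
        cbind(group = "CS_without_syrinx", base(n2, 10)))
}

test_that("identical groups are not declared different", {
  vals <- c(1, 3, 5, 7, 9, 11, 13, 15)
  co <- data.frame(group = rep(c("CS_with_syrinx", "CS_without_syrinx"),
                               each = 8),
                   sv_csf_cerv = c(vals, vals))
  rep_ <- compare_groups(co)
  expect_gt(rep_$p_value, 0.9)
  expect_false(rep_$significant)
})

test_that("well-separated groups are detected at p < 0.001", {
  co <- make_toy_cohort(n1 = 50, n2 = 50, shift = 5, seed = 6)
  rep_ <- compare_groups(co)
  expect_lt(rep_$p_value[rep_$metric == "sv_csf_cerv"], 0.001)
  # and the echoed group statistics are the sample statistics
  x <- co$sv_csf_cerv[co$group == "CS_with_syrinx"]
  expect_equal(rep_$mean_with_syrinx[rep_$metric == "sv_csf_cerv"],
               mean(x))
  expect_equal(rep_$sd_with_syrinx[rep_$metric == "sv_csf_cerv"], sd(x))
})

test_that("exact test is used for small tie-free groups", {
  co <- make_toy_cohort(n1 = 9, n2 = 19, seed = 7)
  rep_ <- compare_groups(co)
  expect_true(all(grepl("exact", rep_$test)))
  big <- make_toy_cohort(n1 = 30, n2 = 30, seed = 8)
  expect_true(all(grepl("normal", compare_groups(big)$test)))
})

test_that("rank test is invariant under monotone transforms, t-test is not", {
  co <- make_toy_cohort(n1 = 12, n2 = 15, shift = 0.8, seed = 9)
  co_exp <- co
  co_exp$sv_csf_cerv <- exp(co$sv_csf_cerv / 5)
  p_mw <- compare_groups(co)$p_value
  p_mw_t <- compare_groups(co_exp)$p_value
  expect_equal(p_mw[1], p_mw_t[1], tolerance = 1e-12)
  p_t <- compare_groups(co, method = "t_test")$p_value
  p_t_t <- compare_groups(co_exp, method = "t_test")$p_value
  expect_gt(abs(p_t[1] - p_t_t[1]), 1e-6)
})

test_that("correlation and regression agree with the closed-form line", {
  co <- data.frame(group = "CS_with_syrinx",
                   alpha = seq(1, 2, length.out = 10))
  co$sv_csf_cerv <- 2 * co$alpha + 1
  out <- correlate(co, "alpha", "sv_csf_cerv", scope = "with_syrinx")
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$slope, 2, tolerance = 1e-12)
  expect_equal(out$intercept, 1, tolerance = 1e-12)
  expect_lt(out$p_value, 1e-10)
})

test_that("r is symmetric under swap but the regression slope is not", {
  co <- make_toy_cohort(n1 = 40, n2 = 5, seed = 10)
  co$sv_csf_cerv <- co$sv_csf_cerv + 0.5 * co$cbfa / 50
  a <- correlate(co, "sv_csf_cerv", "cbfa", scope = "with_syrinx")
  b <- correlate(co, "cbfa", "sv_csf_cerv", scope = "with_syrinx")
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$slope, b$slope)))
})

test_that("correlate guards its preconditions", {
  co <- make_toy_cohort(n1 = 2, n2 = 3)
  expect_error(correlate(co, "alpha", "cbfa", scope = "with_syrinx"),
               "at least 3")
  co2 <- make_toy_cohort(n1 = 10, n2 = 10)
  co2$alpha <- 1.5
  expect_error(correlate(co2, "alpha", "cbfa"), "zero variance")
})

test_that("estimated r is consistent for the generator target", {
  ns <- c(200, 2000)
  errs <- sapply(ns, function(n) {
    co <- make_cohort(cohort_spec(n_with_syrinx = n, n_without_syrinx = 5,
                                  seed = 31))
    abs(correlate(co, "alpha", "sv_csf_cerv", "with_syrinx")$r - (-0.80))
  })
  expect_lt(errs[2], 0.05)
  expect_lt(errs[2], errs[1] + 0.02)
})

test_that("the rendered tables have the published layout", {
  co <- make_cohort(cohort_spec(seed = 17))
  tabs <- build_tables(co)
  t3 <- tabs$group_comparison
  expect_equal(nrow(t3), 9L)
  expect_named(t3, c("Flow Parameters", "CS with a Syrinx",
                     "CS without a Syrinx", "p Value"))
  # the syrinx stroke volume exists in one group only: "/" placeholders
  syr_row <- t3[t3$`Flow Parameters` == "SV_syrinx (µL/CC)", ]
  expect_equal(syr_row$`CS without a Syrinx`, "/")
  expect_equal(syr_row$`p Value`, "/")
  expect_match(syr_row$`CS with a Syrinx`, "^[0-9]+ ± [0-9]+$")

  expect_equal(nrow(tabs$sv_blood_correlations), 4L)
  expect_equal(nrow(tabs$alpha_correlations), 5L)
  expect_match(tabs$alpha_correlations[5, 2],
               "^-?[01]\\.[0-9]{2} \\((<0\\.01|0\\.[0-9]{2})\\)$")
  # deterministic rendering for a fixed cohort
  expect_identical(build_tables(co), tabs)

  paths <- write_tables(tabs, file.path(tempdir(), "tabs_test"))
  expect_true(all(file.exists(paths)))
  unlink(file.path(tempdir(), "tabs_test"), recursive = TRUE)
})
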