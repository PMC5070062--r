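test_that("the Shapiro gate separates near-normal from degenerate samples", {
  expect_true(shapiro_gate(qnorm(seq(0.05, 0.95, length.out = 20))))
  expect_false(shapiro_gate(c(rep(0, 19), 100)))
  expect_error(shapiro_gate(c(1, 2)), "at least 3")
  expect_false(shapiro_gate(rep(5, 10))) # constant: treated as non-normal
})

make_groups <- function(n1 = 10, n2 = 10, shift = 0, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    group = rep(c("ASD", "TD"), c(n1, n2)),
    covariate = rnorm(n1 + n2, 100, 15),
    dv = rnorm(n1 + n2) + shift * rep(c(1, 0), c(n1, n2))
  )
}

test_that("ANCOVA returns a null result when groups are identical", {
  d <- make_groups()
  d$dv <- rep(seq_len(10), 2) # identical values in both groups
  fit <- ja_ancova(d, "dv")
  # identical dv distributions: only covariate imbalance leaks into the
  # group term, so F stays near its null scale
  expect_lt(fit$F, 0.1)
  expect_lt(fit$eta2_partial, 0.01)
  expect_gt(fit$p, 0.5)
})

test_that("ANCOVA group F and eta2 match a normal-equations cross-check", {
  d <- make_groups(12, 9, shift = 1.5, seed = 7)
  fit <- ja_ancova(d, "dv")
  g <- as.numeric(factor(d$group)) - 1
  X_full <- cbind(1, g, d$covariate)
  X_null <- cbind(1, d$covariate)
  rss_full <- oracle_rss(X_full, d$dv)
  rss_null <- oracle_rss(X_null, d$dv)
  ss_g <- rss_null - rss_full
  df2 <- nrow(d) - 3
  expect_equal(fit$F, (ss_g / 1) / (rss_full / df2), tolerance = 1e-10)
  expect_equal(fit$eta2_partial, ss_g / (ss_g + rss_full), tolerance = 1e-10)
  expect_equal(fit$p, pf(fit$F, 1, df2, lower.tail = FALSE))
  expect_gt(fit$eta2_partial, 0.14) # constructed large effect
})

test_that("ANCOVA group F is invariant to affine transforms of the covariate", {
  d <- make_groups(11, 13, shift = 0.8, seed = 3)
  f1 <- ja_ancova(d, "dv")$F
  d2 <- d; d2$covariate <- 3.7 * d2$covariate - 250
  expect_equal(ja_ancova(d2, "dv")$F, f1, tolerance = 1e-9)
})

test_that("ANCOVA demands two observations per group", {
  d <- make_groups(5, 5)
  d$dv[d$group == "TD"] <- NA
  expect_error(ja_ancova(d, "dv"), "analysis error.*dv")
})

test_that("rank ANCOVA is invariant under monotone transforms of the dv", {
  d <- make_groups(10, 12, shift = 1, seed = 9)
  f1 <- ja_rank_ancova(d, "dv")
  d2 <- d; d2$dv <- exp(d2$dv)
  f2 <- ja_rank_ancova(d2, "dv")
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
  expect_true(f1$ranked)
})

test_that("rank ANCOVA degenerates to F = 0 on an all-tied dv", {
  d <- make_groups(6, 6)
  d$dv <- 1
  fit <- ja_rank_ancova(d, "dv")
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
})

test_that("rank ANCOVA on a small set matches hand-ranked OLS", {
  d <- tibble::tibble(
    group = c("ASD", "ASD", "ASD", "TD", "TD", "TD"),
    dv = c(5, 1, 9, 2, 2, 7),
    covariate = c(90, 60, 120, 80, 100, 110)
  )
  fit <- ja_rank_ancova(d, "dv")
  r_dv <- c(4, 1, 6, 2.5, 2.5, 5)     # midranks by hand
  r_cov <- c(3, 1, 6, 2, 4, 5)
  g <- c(0, 0, 0, 1, 1, 1)
  rss_full <- oracle_rss(cbind(1, g, r_cov), r_dv)
  rss_null <- oracle_rss(cbind(1, r_cov), r_dv)
  ss_g <- rss_null - rss_full
  expect_equal(fit$F, ss_g / (rss_full / 3), tolerance = 1e-10)
})

test_that("tidy and glance expose the comparison as tibbles", {
  fit <- ja_ancova(make_groups(8, 8, shift = 1, seed = 2), "dv")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("mean_ASD", "sd_TD", "F", "p", "eta2_partial", "ranked")
                  %in% names(td)))
  expect_equal(glance(fit)$n, 16)
})

test_that("BH FDR matches its worked examples and boundary convention", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(TRUE, 4))
  expect_equal(bh_fdr(c(0.5, 0.6)), c(FALSE, FALSE))
  expect_true(bh_fdr(0.05)) # p = q at k = m: rejected
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("distribution-gated correlation picks the right method", {
  set.seed(4)
  x <- rnorm(20)
  d <- tibble::tibble(x = x, y = x)
  r <- correlate_auto(d, "x", "y")
  expect_equal(r$method, "pearson")
  expect_equal(r$r, 1)

  heavy <- rt(20, df = 1)
  d2 <- tibble::tibble(x = heavy, y = heavy^3) # monotone, nonlinear
  r2 <- correlate_auto(d2, "x", "y")
  expect_equal(r2$method, "spearman")
  expect_equal(r2$r, 1)

  d3 <- tibble::tibble(x = rnorm(10), y = rep(2, 10))
  r3 <- correlate_auto(d3, "x", "y")
  expect_equal(r3$method, "undefined")
  expect_true(is.na(r3$r))
  expect_error(correlate_auto(tibble::tibble(x = 1:3, y = 1:3), "x", "y"),
               "at least 4")
})

test_that("the usable-trial repeated-measures ANOVA behaves at the extremes", {
  grid <- expand.grid(participant_id = sprintf("p%02d", 1:12),
                      task = c("RJA", "IJA1", "IJA2"),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("p", "", grid$participant_id)) <= 6,
                       "ASD", "TD")
  same <- grid; same$n_usable <- 11
  res <- usable_trials_anova(same)
  expect_equal(res$F[res$term == "task"], 0)
  expect_equal(res$F[res$term == "group:task"], 0)

  set.seed(8)
  shifted <- grid
  shifted$n_usable <- 10 + 2 * (shifted$task == "RJA") + rnorm(nrow(grid), 0, 0.3)
  res2 <- usable_trials_anova(shifted)
  expect_lt(res2$p[res2$term == "task"], 0.01)
  expect_gt(res2$p[res2$term == "group:task"], 0.05)

  solo <- grid[grid$participant_id == "p01", ]
  solo$n_usable <- 11
  expect_error(usable_trials_anova(solo), "analysis error")
})

test_that("rank ANCOVA rejects most of the time under a 1-SD group shift", {
  set.seed(123)
  rej <- vapply(1:400, function(i) {
    d <- tibble::tibble(
      group = rep(c("ASD", "TD"), c(17, 15)),
      covariate = rnorm(32, 100, 15),
      dv = rnorm(32) + rep(c(1, 0), c(17, 15))
    )
    ja_rank_ancova(d, "dv")$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.6)
})

test_that("compare_groups gates on normality and applies FDR per task", {
  set.seed(31)
  n <- 40
  m <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n),
    group = rep(c("ASD", "TD"), each = n / 2),
    covariate = rnorm(n, 100, 15),
    task = "IJA1",
    normal_var = rnorm(n) + 2 * (seq_len(n) <= n / 2),
    skewed_var = exp(rnorm(n, sd = 1.5)),
    null_var = rnorm(n)
  )
  out <- compare_groups(m, c("normal_var", "skewed_var", "null_var"))
  expect_equal(nrow(out), 3)
  expect_false(out$ranked[out$variable == "normal_var"])
  expect_true(out$ranked[out$variable == "skewed_var"])
  expect_true(out$fdr_significant[out$variable == "normal_var"])
  expect_true(all(c("levene_p", "eta2_partial") %in% names(out)))
})
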