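test_that("covariate adjustment preserves orthogonal contrasts and removes linear effects", {
  set.seed(101)
  n <- 40
  group <- rep(c(0, 1), each = n / 2)
  # covariates orthogonal to group, to each other, and (by projection)
  # to the outcome
  cov_orth <- cbind(age = rep(c(-1, 1), n / 2),
                    sex = rep(c(-1, -1, 1, 1), n / 4))
  y <- rnorm(n) + 0.8 * group
  y <- y - cov_orth %*% solve(crossprod(cov_orth), crossprod(cov_orth, y))
  y <- as.numeric(y)
  adj <- adjust_covariates(y, cov_orth)
  t_raw <- two_sample_t(y[group == 1], y[group == 0])
  t_adj <- two_sample_t(adj[group == 1], adj[group == 0])
  expect_equal(t_adj$t_statistic, t_raw$t_statistic, tolerance = 1e-9)

  age <- rnorm(n, 60, 8)
  y_lin <- 2 + 0.5 * age
  expect_lt(max(abs(adjust_covariates(y_lin, cbind(age = age)) -
                      mean(y_lin))), 1e-9)

  dup <- cbind(age = age, age2 = age)
  expect_error(adjust_covariates(y, dup), "rank deficient")
})

test_that("adjusting for a planted confound moves t toward the confound-free value", {
  set.seed(202)
  hits <- 0
  for (i in 1:50) {
    n <- 40
    group <- rep(c(0, 1), each = n / 2)
    age <- rnorm(n, 60, 8) + 6 * group     # confounded covariate
    y_clean <- rnorm(n) + 0.5 * group
    y <- y_clean + 0.15 * age
    t_free <- two_sample_t(y_clean[group == 1],
                           y_clean[group == 0])$t_statistic
    t_unadj <- two_sample_t(y[group == 1], y[group == 0])$t_statistic
    adj <- adjust_covariates(y, cbind(age = age))
    t_adj <- two_sample_t(adj[group == 1], adj[group == 0])$t_statistic
    if (abs(t_adj - t_free) < abs(t_unadj - t_free)) hits <- hits + 1
  }
  expect_gt(hits / 50, 0.7)
})

test_that("two-sample t handles identical groups and matches its summary form", {
  x <- c(1, 2, 3, 4)
  res <- two_sample_t(x, x)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$cohens_d, 0)

  set.seed(7)
  x1 <- rnorm(12, 1); x2 <- rnorm(17)
  raw <- two_sample_t(x1, x2, "pooled")
  summ <- t_from_summary(mean(x1), sd(x1), 12, mean(x2), sd(x2), 17)
  expect_equal(raw$t_statistic, summ$t_statistic, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  expect_equal(raw$df, summ$df)

  welch <- two_sample_t(x1, x2, "welch")
  expect_false(isTRUE(all.equal(welch$df, raw$df)))
})

test_that("pooled-t p-values agree with the exhaustive permutation oracle at n = 4 + 4", {
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(8) + rep(c(0, 0.8), each = 4)
    splits <- combn(8, 4)
    tstat <- function(i1) {
      two_sample_t(x[i1], x[-i1])$t_statistic
    }
    t_obs <- abs(tstat(1:4))
    t_all <- abs(apply(splits, 2, tstat))
    p_perm <- mean(t_all >= t_obs - 1e-12)
    p_t <- two_sample_t(x[1:4], x[5:8])$p_value
    expect_lt(abs(p_t - p_perm), 0.05)
  }
})

test_that("summary-statistic t reproduces a published age comparison", {
  res <- t_from_summary(62.44, 9.76, 34, 59.58, 9.15, 50)
  expect_equal(round(res$t_statistic, 3), 1.369)
  expect_equal(round(res$p_value, 3), 0.175)
  expect_equal(res$df, 82)

  expect_equal(t_from_summary(5, 1, 10, 5, 2, 12)$t_statistic, 0)
  swap <- t_from_summary(59.58, 9.15, 50, 62.44, 9.76, 34)
  expect_equal(swap$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-12)
})

test_that("2x2 chi-square matches the textbook formulas with and without correction", {
  res <- chi_square_2x2(21, 13, 25, 25)
  expect_equal(round(res$statistic, 3), 0.706)
  expect_equal(round(res$p_value, 3), 0.401)
  expect_equal(res$df, 1)

  expect_equal(chi_square_2x2(10, 10, 20, 20)$statistic, 0)

  # uncorrected statistic vs brute-force sum over cells
  oracle <- function(a, b, c, d) {
    o <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    sum((o - e)^2 / e)
  }
  un <- chi_square_2x2(21, 13, 25, 25, continuity = FALSE)
  expect_equal(round(un$statistic, 3), 1.131)
  expect_equal(un$statistic, oracle(21, 13, 25, 25), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    cells <- rpois(4, 15) + 1
    expect_equal(chi_square_2x2(cells[1], cells[2], cells[3], cells[4],
                                continuity = FALSE)$statistic,
                 oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  expect_warning(res0 <- chi_square_2x2(0, 0, 5, 5), "marginal")
  expect_true(is.na(res0$statistic))
})

test_that("Cohen's d uses the pooled SD and is antisymmetric", {
  set.seed(12)
  x2 <- rnorm(20)
  sp <- sd(x2)  # equal-variance construction
  x1 <- x2 + sp
  d <- cohens_d(x1, x2)
  expect_equal(d, 1, tolerance = 1e-12)
  expect_equal(cohens_d(x2, x1), -d, tolerance = 1e-12)
  expect_equal(cohens_d(x2, x2), 0)
})

test_that("correlations handle linear, monotone and hand-ranked cases", {
  x <- c(0.2, 1.5, 2.1, 3.3, 4.8)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$r, 1)
  expect_equal(correlate(x, 2 * x + 1, "spearman")$r, 1)

  y <- exp(x)
  expect_equal(correlate(x, y, "spearman")$r, 1)
  expect_lt(correlate(x, y, "pearson")$r, 1)

  # n = 5 hand-ranked oracle with a tie: mid-ranks
  a <- c(3, 1, 4, 1, 5); b <- c(2, 7, 1, 8, 2)
  ra <- c(3, 1.5, 4, 1.5, 5); rb <- c(2.5, 4, 1, 5, 2.5)
  expect_equal(correlate(a, b, "spearman")$r, cor(ra, rb),
               tolerance = 1e-12)

  res <- correlate(x, 2 * x + rnorm(5, sd = 0.1), "pearson")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_warning(flat <- correlate(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(flat$r))
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  set.seed(13)
  p <- runif(25)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  ord <- sample(25)
  expect_equal(bh_fdr(p[ord]), q[ord])
})

test_that("subgroup analysis flags planted effects and rejects degenerate splits", {
  set.seed(404)
  n <- 34
  tab <- data.frame(fma = c(rep(40, 17), rep(60, 17)),
                    age = rnorm(n, 62, 9), sex = rbinom(n, 1, 0.5))
  for (v in paste0("null", 1:5)) tab[[v]] <- rnorm(n)
  tab$effect <- rnorm(n) + 1.2 * (tab$fma > 55)
  res <- run_subgroup_analysis(tab, "fma", 55,
                               c(paste0("null", 1:5), "effect"))
  expect_equal(nrow(res), 6)
  expect_equal(res$n_high[1], 17)
  expect_lt(res$q_value[res$variable == "effect"], 0.05)
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  expect_error(run_subgroup_analysis(tab, "fma", 100, "effect"),
               "degenerate")
  expect_error(run_subgroup_analysis(tab, "nope", 50, "effect"),
               "missing")
  empty <- run_subgroup_analysis(tab, "fma", 55, character(0))
  expect_equal(nrow(empty), 0)
})

test_that("correlation batches report r, p and q per requested pair", {
  set.seed(15)
  tab <- data.frame(a = rnorm(30))
  tab$b <- tab$a + rnorm(30, sd = 0.3)
  tab$c <- rnorm(30)
  res <- run_correlations(tab, rbind(c("a", "b"), c("a", "c")))
  expect_equal(nrow(res), 2)
  expect_gt(res$r[1], 0.8)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_error(run_correlations(tab, rbind(c("a", "zz"))), "missing")
})
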