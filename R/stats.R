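#' Covariate adjustment by OLS residualization
#'
#' Fits an ordinary-least-squares model of `y` on the covariates plus
#' an intercept and returns the residuals plus the grand mean, so
#' downstream group tests run on covariate-adjusted values.
#'
#' @param y Numeric outcome vector.
#' @param covariates Numeric matrix or data frame of per-subject
#'   covariates (columns may include factors coded numerically; a sex
#'   indicator works as 0/1).
#' @return Numeric vector of adjusted values (residuals + mean of `y`).
#' @export
adjust_covariates <- function(y, covariates) {
  x <- as.matrix(as.data.frame(covariates))
  stopifnot(length(y) == nrow(x))
  if (length(y) <= ncol(x) + 1) {
    stop("need more subjects than covariates + 1")
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
  if (fit$rank < ncol(x) + 1) {
    dropped <- colnames(cbind(1, x))[is.na(fit$coefficients)]
    stop("covariate matrix is rank deficient; offending columns: ",
         paste(dropped, collapse = ", "))
  }
  as.numeric(fit$residuals) + mean(y)
}

#' Cohen's d with pooled SD
#'
#' `d = (m1 - m2) / s_p` with the df-weighted pooled standard
#' deviation.
#'
#' @param x1,x2 Numeric group samples (each n >= 2).
#' @return Cohen's d; `NA` (with a warning) when the pooled SD is zero.
#' @export
cohens_d <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    warning("Cohen's d undefined: zero pooled SD")
    return(NA_real_)
  }
  (mean(x1) - mean(x2)) / sqrt(sp2)
}

#' Two-sample t-test on raw values
#'
#' Pooled (Student) or Welch (Satterthwaite) two-sample t-test,
#' two-tailed, with Cohen's d attached. The pooled variant is the
#' default throughout the pipeline.
#'
#' @param x1,x2 Numeric group samples (each n >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @param variable Optional variable name carried into the result.
#' @return A one-row data frame of class `group_comparison`: variable,
#'   t_statistic, df, p_value, cohens_d, n1, n2.
#' @export
two_sample_t <- function(x1, x2, variant = c("pooled", "welch"),
                         variable = NA_character_) {
  variant <- match.arg(variant)
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  if (stats::var(x1) == 0 && stats::var(x2) == 0 &&
      mean(x1) == mean(x2)) {
    res <- list(statistic = 0, parameter = length(x1) + length(x2) - 2,
                p.value = 1)
  } else if (stats::var(x1) == 0 && stats::var(x2) == 0) {
    warning("t undefined: zero variance in both groups")
    res <- list(statistic = NA_real_, parameter = NA_real_,
                p.value = NA_real_)
  } else {
    ht <- stats::t.test(x1, x2, var.equal = (variant == "pooled"))
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter),
                p.value = ht$p.value)
  }
  structure(data.frame(variable = variable,
                       t_statistic = res$statistic, df = res$parameter,
                       p_value = res$p.value,
                       cohens_d = suppressWarnings(cohens_d(x1, x2)),
                       n1 = length(x1), n2 = length(x2)),
            class = c("group_comparison", "data.frame"))
}

#' Pooled two-sample t-test from summary statistics
#'
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))` with the pooled SD and
#' `df = n1 + n2 - 2`; two-tailed p from the t distribution. Reproduces
#' published mean +/- SD group comparisons.
#'
#' @param m1,sd1,n1 Mean, SD, and size of group 1.
#' @param m2,sd2,n2 Mean, SD, and size of group 2.
#' @param variable Optional variable name.
#' @return A one-row `group_comparison` data frame.
#' @export
#' @examples
#' t_from_summary(62.44, 9.76, 34, 59.58, 9.15, 50)
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                           variable = NA_character_) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) {
    warning("t undefined: zero pooled variance")
    return(structure(data.frame(variable = variable,
                                t_statistic = NA_real_, df = df,
                                p_value = NA_real_, cohens_d = NA_real_,
                                n1 = n1, n2 = n2),
                     class = c("group_comparison", "data.frame")))
  }
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(data.frame(variable = variable, t_statistic = tval, df = df,
                       p_value = 2 * stats::pt(-abs(tval), df),
                       cohens_d = (m1 - m2) / sqrt(sp2),
                       n1 = n1, n2 = n2),
            class = c("group_comparison", "data.frame"))
}

#' 2x2 chi-square test
#'
#' Chi-square test of independence on a 2x2 table, with the Yates
#' continuity correction by default (the convention that reproduces
#' published sex-ratio comparisons); df = 1, upper-tail p.
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` in group 1, `(c, d)`
#'   in group 2.
#' @param continuity Apply the Yates correction (default TRUE).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_2x2(21, 13, 25, 25)
chi_square_2x2 <- function(a, b, c, d, continuity = TRUE) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("chi-square undefined: zero marginal total")
    return(list(statistic = NA_real_, df = 1, p_value = NA_real_))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Pearson or Spearman correlation with two-tailed p
#'
#' Pearson on raw values, or Spearman on mid-ranks (ties averaged).
#' Both use the t-approximation for the two-tailed p-value:
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `df = n - 2`.
#'
#' @param x,y Paired numeric vectors (n >= 3, finite).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `method`, `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: zero variance")
    return(list(method = method, r = NA_real_, p_value = NA_real_,
                n = n))
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(method = method, r = r, p_value = p, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values: `q_(i) = min_{j >= i} (m / j) p_(j)`, capped at
#' 1, mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Covariate-adjusted subgroup comparison with FDR
#'
#' Splits subjects into two groups at a cutoff on `split_var`
#' (`> cutoff` versus `<= cutoff`), adjusts each outcome for the named
#' covariates by OLS residualization over all subjects, runs a pooled
#' two-sample t-test per outcome with Cohen's d on the adjusted values
#' (raw-value d is also reported), and applies Benjamini-Hochberg FDR
#' across the outcome family.
#'
#' @param table Per-subject data frame holding split variable,
#'   outcomes, and covariates.
#' @param split_var Name of the splitting variable.
#' @param cutoff Numeric cutoff; groups are `> cutoff` vs `<= cutoff`.
#' @param outcomes Character vector of outcome column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty for unadjusted comparisons).
#' @param variant t-test variant (default pooled).
#' @return Data frame with one row per outcome: variable, n_high,
#'   n_low, t_statistic, df, p_value, cohens_d (adjusted),
#'   cohens_d_raw, q_value; ordered as `outcomes`.
#' @export
run_subgroup_analysis <- function(table, split_var, cutoff, outcomes,
                                  covariates = c("age", "sex"),
                                  variant = "pooled") {
  miss <- setdiff(c(split_var, outcomes, covariates), names(table))
  if (length(miss)) {
    stop("columns missing from the subject table: ",
         paste(miss, collapse = ", "))
  }
  hi <- table[[split_var]] > cutoff
  if (sum(hi) < 2 || sum(!hi) < 2) {
    stop("degenerate split: '", split_var, "' > ", cutoff,
         " leaves fewer than 2 subjects in a group (",
         sum(hi), "/", sum(!hi), ")")
  }
  if (length(outcomes) == 0) {
    return(data.frame(variable = character(0), n_high = integer(0),
                      n_low = integer(0), t_statistic = numeric(0),
                      df = numeric(0), p_value = numeric(0),
                      cohens_d = numeric(0), cohens_d_raw = numeric(0),
                      q_value = numeric(0)))
  }
  rows <- lapply(outcomes, function(v) {
    y <- table[[v]]
    adj <- if (length(covariates)) {
      adjust_covariates(y, table[covariates])
    } else y
    res <- two_sample_t(adj[hi], adj[!hi], variant = variant,
                        variable = v)
    data.frame(variable = v, n_high = sum(hi), n_low = sum(!hi),
               t_statistic = res$t_statistic, df = res$df,
               p_value = res$p_value, cohens_d = res$cohens_d,
               cohens_d_raw = suppressWarnings(cohens_d(y[hi], y[!hi])))
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Correlation analyses over a subject table
#'
#' Computes the requested pairwise correlations with two-tailed
#' p-values and BH-FDR adjustment across the family.
#'
#' @param table Per-subject data frame.
#' @param pairs Data frame (or 2-column matrix) of variable-name pairs.
#' @param method `"pearson"` or `"spearman"`.
#' @return Data frame: x, y, method, r, p_value, n, q_value.
#' @export
run_correlations <- function(table, pairs,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    vx <- as.character(pairs[i, 1]); vy <- as.character(pairs[i, 2])
    miss <- setdiff(c(vx, vy), names(table))
    if (length(miss)) {
      stop("columns missing from the subject table: ",
           paste(miss, collapse = ", "))
    }
    res <- correlate(table[[vx]], table[[vy]], method)
    data.frame(x = vx, y = vy, method = method, r = res$r,
               p_value = res$p_value, n = res$n)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
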