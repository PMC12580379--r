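#!/usr/bin/env Rscript
# Stage 5: subgroup comparisons and correlations.
#
# Joins clinical covariates, actigraphy metrics and microstate
# parameters into one per-subject table, then runs the
# covariate-adjusted (age, sex) pooled two-sample comparisons across
# the study's subgroup splits (FMA 55, night ULAR 30%, coordination r
# 0.62, moderate-activity 150 min, 90-day mRS 1) with Cohen's d and
# BH-FDR per outcome family, plus the Pearson correlation analyses
# between activity metrics and clinical scales.

library(microdyn)

clinical <- read.csv("scratch/cohort/clinical.csv",
                     stringsAsFactors = FALSE)
metrics <- read.csv("results/actigraphy_metrics.csv",
                    stringsAsFactors = FALSE)
params <- read.csv("results/microstate_parameters.csv",
                   stringsAsFactors = FALSE)
trans <- read.csv("results/microstate_transitions.csv",
                  stringsAsFactors = FALSE)
dir.create("results", showWarnings = FALSE)

# wide microstate columns per subject
wide <- reshape(params, direction = "wide", idvar = "subject_id",
                timevar = "state")
names(wide) <- sub("\\.(\\w)$", "_\\1", names(wide))
trans$key <- paste0("trans_", trans$from, trans$to)
tw <- reshape(trans[, c("subject_id", "key", "probability")],
              direction = "wide", idvar = "subject_id",
              timevar = "key")
names(tw) <- sub("^probability\\.", "", names(tw))
tab <- Reduce(function(a, b) merge(a, b, by = "subject_id"),
              list(clinical, metrics, wide, tw))

ms_outcomes <- grep("^(coverage|duration|occurrence)_",
                    names(tab), value = TRUE)
act_outcomes <- c("r_night", "ular_day", "ular_night")

splits <- list(
  list(var = "fma", cut = 55, outcomes = c(ms_outcomes, act_outcomes)),
  list(var = "ular_night", cut = 30, outcomes = ms_outcomes),
  list(var = "r_all", cut = 0.62, outcomes = ms_outcomes),
  list(var = "moderate_minutes_affected", cut = 150,
       outcomes = ms_outcomes),
  list(var = "mrs_90d", cut = 1, outcomes = ms_outcomes)
)

all_res <- list()
for (s in splits) {
  hi <- sum(tab[[s$var]] > s$cut); lo <- nrow(tab) - hi
  if (hi < 2 || lo < 2) {
    cat(sprintf("split %s > %s: degenerate (%d/%d), skipped\n",
                s$var, s$cut, hi, lo))
    next
  }
  res <- run_subgroup_analysis(tab, s$var, s$cut, s$outcomes,
                               covariates = c("age", "sex"))
  res <- cbind(split = paste0(s$var, ">", s$cut), res)
  all_res[[length(all_res) + 1]] <- res
  sig <- res[res$q_value < 0.05, "variable"]
  cat(sprintf("split %s > %s (n = %d/%d): %d outcomes, %s\n",
              s$var, s$cut, hi, lo, nrow(res),
              if (length(sig)) paste("q<0.05:", paste(sig, collapse = ", "))
              else "none at q<0.05"))
}
subgroups <- do.call(rbind, all_res)
write.csv(subgroups, "results/subgroup_comparisons.csv",
          row.names = FALSE)

pairs <- rbind(
  c("r_night", "mmse"), c("r_night", "moca"), c("r_night", "nihss"),
  c("ular_day", "fma"), c("ular_night", "fma"),
  c("ular_day", "nihss"), c("ular_night", "nihss")
)
cors <- run_correlations(tab, pairs, method = "pearson")
write.csv(cors, "results/correlations.csv", row.names = FALSE)
sig <- cors[cors$p_value < 0.05, ]
cat(sprintf("correlations: %d pairs, %d with p < 0.05\n",
            nrow(cors), nrow(sig)))
for (i in seq_len(nrow(sig))) {
  cat(sprintf("  %s ~ %s: r = %.2f, p = %.3f\n", sig$x[i], sig$y[i],
              sig$r[i], sig$p_value[i]))
}
cat("Tables -> results/subgroup_comparisons.csv, results/correlations.csv\n")
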