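# End-to-end wiring: cohort simulation, per-subject microstate fitting
# with group-map aggregation, and the joined subject table for the
# statistical layer. The analysis/ drivers are thin wrappers over these.

#' Simulate one synthetic study subject
#'
#' Generates a resting-state EEG with planted microstate structure
#' (five 10-s epochs' worth by default) and a 24-h bilateral actigraphy
#' series, plus a clinical covariate row. Actigraphy targets are taken
#' from the supplied clinical row so cohort-level couplings between
#' clinical scales and activity metrics can be planted upstream.
#'
#' @param templates `microstate_templates` shared by the cohort.
#' @param clinical One-row data frame with at least `subject_id`,
#'   `target_r`, `target_ular_pct`, `affected_side`.
#' @param seed Integer seed.
#' @param snr EEG signal-to-noise ratio (default 4).
#' @param mean_dwell_ms Mean microstate dwell (default 60).
#' @param n_epochs,epoch_length_s EEG epoch layout (5 x 10 s).
#' @param sampling_rate_hz EEG sampling rate (default 500).
#' @param transition_matrix Distinct-state transition matrix (default
#'   uniform off-diagonal).
#' @param n_minutes Actigraphy length (default 1440).
#' @return List with `eeg` (`synthetic_eeg`), `labels` (truth state
#'   series), `acti` (`actigraphy_pair`), `clinical`.
#' @export
simulate_subject <- function(templates, clinical, seed, snr = 4,
                             mean_dwell_ms = 60, n_epochs = 5,
                             epoch_length_s = 10,
                             sampling_rate_hz = 500,
                             transition_matrix = NULL,
                             n_minutes = 1440) {
  k <- nrow(templates$maps)
  if (is.null(transition_matrix)) {
    transition_matrix <- uniform_transitions(k)
  }
  sspec <- state_sequence_spec(
    transition_matrix, mean_dwell_ms = mean_dwell_ms,
    sampling_rate_hz = sampling_rate_hz,
    total_duration_s = n_epochs * epoch_length_s, seed = seed
  )
  labels <- simulate_state_sequence(sspec)
  eeg <- synthesize_eeg(templates, labels, sampling_rate_hz, snr,
                        seed = seed + 1L)
  aspec <- actigraphy_spec(
    n_minutes = n_minutes,
    target_r = clinical$target_r,
    target_ular_pct = clinical$target_ular_pct,
    affected_side = clinical$affected_side,
    seed = seed + 2L
  )
  acti <- synthesize_actigraphy(aspec)
  list(eeg = eeg, labels = labels, acti = acti, clinical = clinical,
       state_spec = sspec)
}

#' Simulate a synthetic stroke-cohort clinical table
#'
#' Draws per-subject clinical covariates (age, sex, NIHSS, FMA, MoCA,
#' MMSE, 90-day mRS, affected side) with the couplings the study
#' design expects: upper-limb motor function (FMA) is negatively
#' related to stroke severity (NIHSS), and the actigraphy generation
#' targets (`target_ular_pct`, `target_r`) increase with FMA, so that
#' activity metrics carry a recoverable clinical signal.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param seed Integer seed.
#' @return Data frame, one row per subject.
#' @export
simulate_clinical_table <- function(n_subjects = 10, seed = 1) {
  with_private_seed(seed, {
    fma <- pmin(66, pmax(10, round(stats::rnorm(n_subjects, 48, 14))))
    nihss <- pmin(25, pmax(1, round(14 - 0.15 * fma +
                                      stats::rnorm(n_subjects, 0, 2))))
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      age = round(stats::rnorm(n_subjects, 62, 10)),
      sex = stats::rbinom(n_subjects, 1, 0.6),  # 1 = male
      nihss = nihss,
      fma = fma,
      moca = pmin(30, pmax(10, round(26 - 0.3 * nihss +
                                       stats::rnorm(n_subjects, 0, 2)))),
      mmse = pmin(30, pmax(12, round(27 - 0.25 * nihss +
                                       stats::rnorm(n_subjects, 0, 2)))),
      mrs_90d = pmin(5, pmax(0, round(3 - 0.04 * fma +
                                        stats::rnorm(n_subjects, 0, 0.7)))),
      affected_side = sample(c("left", "right"), n_subjects,
                             replace = TRUE),
      target_ular_pct = pmin(95, pmax(10, 10 + 0.7 * fma +
                                        stats::rnorm(n_subjects, 0, 6))),
      target_r = pmin(0.95, pmax(0.2, 0.25 + 0.007 * fma +
                                   stats::rnorm(n_subjects, 0, 0.05))),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates the clinical table, one shared template set, and
#' per-subject EEG plus actigraphy. With `out_dir` set, writes each
#' subject's EEG (EDF and delimited), actigraphy table, ground-truth
#' sidecars (true labels and templates), and a manifest.
#'
#' @param n_subjects Cohort size (default 10).
#' @param seed Integer seed.
#' @param snr EEG signal-to-noise ratio (default 4).
#' @param out_dir Optional output directory.
#' @param ... Passed to [simulate_subject()].
#' @return List with `subjects` (list of [simulate_subject()] results),
#'   `clinical` (data frame), `templates`, and `manifest` (data frame
#'   of written paths, or NULL).
#' @export
simulate_cohort <- function(n_subjects = 10, seed = 1, snr = 4,
                            out_dir = NULL, ...) {
  clinical <- simulate_clinical_table(n_subjects, seed = seed)
  templates <- generate_templates(k = 4, seed = seed)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    simulate_subject(templates, clinical[i, , drop = FALSE],
                     seed = seed + 1000L * i, snr = snr, ...)
  })
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(subjects, function(s) {
      id <- s$clinical$subject_id
      edf <- file.path(out_dir, paste0(id, ".edf"))
      write_edf(s$eeg$data, s$eeg$channel_labels,
                s$eeg$sampling_rate_hz, edf)
      act <- file.path(out_dir, paste0(id, "_actigraphy.csv"))
      write_actigraphy(s$acti, act)
      truth <- file.path(out_dir, paste0(id, "_truth_labels.txt"))
      writeLines(as.character(s$labels), truth)
      data.frame(subject_id = id, edf = edf, actigraphy = act,
                 truth_labels = truth, stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
    tpl_path <- file.path(out_dir, "truth_templates.tsv")
    utils::write.table(
      cbind(state = rownames(templates$maps),
            as.data.frame(templates$maps)),
      tpl_path, sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(clinical, file.path(out_dir, "clinical.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  list(subjects = subjects, clinical = clinical, templates = templates,
       manifest = manifest)
}

#' Fit the microstate pipeline to one subject's epochs
#'
#' GFP-peak extraction, polarity-invariant modified k-means, canonical
#' A-D relabelling, back-fitting, and temporal parameters.
#'
#' @param epochs An `epoch_set`.
#' @param k Number of microstate classes (default 4).
#' @param n_restarts,seed Clustering restarts and seed.
#' @param backfit_model Optional model to back-fit instead of the
#'   subject's own (e.g. group mean maps).
#' @return List with `model`, `segmentation`, `parameters`,
#'   `peak_count`.
#' @export
microstate_pipeline <- function(epochs, k = 4, n_restarts = 50,
                                seed = 1, backfit_model = NULL) {
  pk <- collect_peak_maps(epochs)
  model <- modified_kmeans(pk$maps, k = k, n_restarts = n_restarts,
                           seed = seed)
  model <- assign_canonical_labels(model)
  fit_model <- if (is.null(backfit_model)) model else backfit_model
  seg <- backfit(epochs, fit_model)
  params <- compute_parameters(seg)
  list(model = model, segmentation = seg, parameters = params,
       peak_count = nrow(pk$maps))
}

#' Run microstate analysis across a cohort
#'
#' Per subject: preprocessing-free epoch split of the synthetic EEG,
#' individual modified k-means maps; then group mean maps by aligned
#' averaging; finally back-fitting of every subject with the group
#' maps and per-subject temporal parameters, mirroring the
#' individual-maps-to-group-maps-to-back-fit workflow.
#'
#' @param subjects List of [simulate_subject()] results (or any list
#'   with an `epoch_set` under `$epochs` or a `synthetic_eeg` under
#'   `$eeg`).
#' @param k,n_restarts,seed Clustering parameters.
#' @param n_epochs,epoch_length_s Epoch layout for splitting raw
#'   synthetic matrices.
#' @return List with `group_model`, `individual_models`, `parameters`
#'   (per-subject list), `parameter_table`, `transition_table`.
#' @export
cohort_microstates <- function(subjects, k = 4, n_restarts = 50,
                               seed = 1, n_epochs = 5,
                               epoch_length_s = 10) {
  get_epochs <- function(s) {
    if (!is.null(s$epochs) && inherits(s$epochs, "epoch_set")) {
      return(s$epochs)
    }
    epochs_from_matrix(s$eeg$data, s$eeg$sampling_rate_hz,
                       n = n_epochs, length_s = epoch_length_s)
  }
  eps <- lapply(subjects, get_epochs)
  models <- lapply(seq_along(eps), function(i) {
    pk <- collect_peak_maps(eps[[i]])
    modified_kmeans(pk$maps, k = k, n_restarts = n_restarts,
                    seed = seed + i)
  })
  group <- assign_canonical_labels(aggregate_group_maps(models))
  params <- vector("list", length(eps))
  ptab <- list(); ttab <- list()
  for (i in seq_along(eps)) {
    seg <- backfit(eps[[i]], group)
    params[[i]] <- compute_parameters(seg)
    id <- if (!is.null(subjects[[i]]$clinical)) {
      subjects[[i]]$clinical$subject_id
    } else sprintf("S%03d", i)
    ptab[[i]] <- parameters_to_df(params[[i]], id)
    ttab[[i]] <- transitions_to_df(params[[i]], id)
  }
  list(group_model = group, individual_models = models,
       parameters = params,
       parameter_table = do.call(rbind, ptab),
       transition_table = do.call(rbind, ttab))
}

#' Build the joined per-subject analysis table
#'
#' Joins the clinical covariates, the actigraphy metric rows, and the
#' wide-format microstate parameters (coverage/duration/occurrence per
#' state, plus distinct-state transition probabilities) into the table
#' consumed by the statistical layer.
#'
#' @param clinical Clinical data frame with `subject_id`.
#' @param acti_metrics Data frame of [activity_metrics()] rows with
#'   `subject_id`.
#' @param ms_params Named list (by subject id) or unnamed list (in
#'   clinical order) of `microstate_parameters`.
#' @return One row per subject.
#' @export
build_subject_table <- function(clinical, acti_metrics, ms_params) {
  wide <- lapply(seq_along(ms_params), function(i) {
    p <- ms_params[[i]]
    labs <- p$state_labels
    row <- c(
      stats::setNames(as.numeric(p$coverage),
                      paste0("coverage_", labs)),
      stats::setNames(as.numeric(p$duration_ms),
                      paste0("duration_", labs)),
      stats::setNames(as.numeric(p$occurrence_per_s),
                      paste0("occurrence_", labs))
    )
    tr <- transitions_to_df(p)
    row <- c(row, stats::setNames(tr$probability,
                                  paste0("trans_", tr$from, tr$to)))
    as.data.frame(as.list(row))
  })
  wide <- do.call(rbind, wide)
  wide$subject_id <- if (!is.null(names(ms_params))) {
    names(ms_params)
  } else clinical$subject_id[seq_len(nrow(wide))]
  out <- merge(clinical, acti_metrics, by = "subject_id")
  merge(out, wide, by = "subject_id")
}
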