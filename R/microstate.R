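#' Global field power of an epoch
#'
#' GFP at sample `t` is the spatial standard deviation of the scalp
#' potential across electrodes, with the population (divide-by-n)
#' convention:
#' `GFP(t) = sqrt( sum_i (v_i(t) - vbar(t))^2 / n )`,
#' where `vbar(t)` is the mean across the `n` electrodes at `t`.
#'
#' @param epoch `n_channels x n_samples` numeric matrix.
#' @return Numeric vector of per-sample GFP values (same units as the
#'   data).
#' @export
#' @examples
#' compute_gfp(matrix(c(3, -1, -1, -1), ncol = 1))  # sqrt(3)
compute_gfp <- function(epoch) {
  epoch <- as.matrix(epoch)
  stopifnot(nrow(epoch) >= 2)
  cm <- colMeans(epoch)
  v <- colMeans(epoch^2) - cm^2
  sqrt(pmax(v, 0))
}

#' Find GFP peaks
#'
#' Strict local maxima of the GFP series: samples whose value exceeds
#' both neighbours. Endpoints are never peaks, and plateaus produce no
#' peak under the strict rule. With `min_separation_samples > 0`, peaks
#' are admitted in decreasing order of GFP and any peak closer than the
#' separation to an already-admitted one is dropped.
#'
#' @param gfp Numeric GFP series (length >= 3).
#' @param min_separation_samples Minimum index distance between
#'   retained peaks (default 0 = no constraint).
#' @return Integer vector of peak indices in increasing order.
#' @export
find_gfp_peaks <- function(gfp, min_separation_samples = 0) {
  n <- length(gfp)
  stopifnot(n >= 3)
  core <- 2:(n - 1)
  is_peak <- gfp[core] > gfp[core - 1] & gfp[core] > gfp[core + 1]
  peaks <- core[is_peak]
  if (min_separation_samples > 0 && length(peaks) > 1) {
    ord <- peaks[order(gfp[peaks], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (all(abs(kept - p) >= min_separation_samples)) kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  peaks
}

# Collect GFP-peak topographies (rows) and their GFP values from an
# epoch set.
collect_peak_maps <- function(epochs, min_separation_samples = 0) {
  stopifnot(inherits(epochs, "epoch_set"))
  maps <- list(); gfps <- list()
  for (ep in epochs$epochs) {
    g <- compute_gfp(ep)
    pk <- find_gfp_peaks(g, min_separation_samples)
    maps[[length(maps) + 1]] <- t(ep[, pk, drop = FALSE])
    gfps[[length(gfps) + 1]] <- g[pk]
  }
  list(maps = do.call(rbind, maps), gfp = unlist(gfps))
}

# All permutations of 1..k in lexicographic order (k small).
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in k:1) out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  }
  # regenerate lexicographically
  m <- do.call(rbind, out)
  m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  lapply(seq_len(nrow(m)), function(i) m[i, ])
}

# Best permutation of rows of `maps` against `ref` maximizing total
# absolute spatial correlation; strict improvement keeps the first
# (lexicographically smallest) optimum, giving a deterministic
# tie-break. Returns the permutation, per-row signs, and the score.
best_alignment <- function(ref, maps) {
  k <- nrow(ref)
  cors <- ref %*% t(maps)  # ref and maps zero-mean unit-norm rows
  best <- NULL; best_score <- -Inf
  for (p in all_perms(k)) {
    sc <- sum(abs(cors[cbind(seq_len(k), p)]))
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best <- p
    }
  }
  signs <- sign(cors[cbind(seq_len(k), best)])
  signs[signs == 0] <- 1
  list(perm = best, signs = signs, score = best_score,
       corrs = abs(cors[cbind(seq_len(k), best)]))
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' The standard microstate clustering: the assignment step maximizes
#' squared spatial correlation (polarity ignored), and the update step
#' sets each centroid to the first principal component of its assigned
#' maps (GFP^2-weighted, sign-indeterminate, normalized). The objective
#' maximized across restarts is the GFP^2-weighted global explained
#' variance (GEV).
#'
#' @param peak_maps `P x n_channels` matrix of topographies (rows),
#'   typically GFP-peak maps.
#' @param k Number of clusters (default 4).
#' @param n_restarts Random restarts (default 50).
#' @param max_iter Iteration cap per restart (default 500).
#' @param tol Convergence tolerance on the GEV objective (default 1e-7).
#' @param seed Integer seed; the fit is deterministic given it.
#' @return An object of class `microstate_model`: list with `maps`
#'   (`k x n_channels`, zero-mean unit-norm rows), `labels`, `gev`,
#'   `k`, `channel_labels`.
#' @export
modified_kmeans <- function(peak_maps, k = 4, n_restarts = 50,
                            max_iter = 500, tol = 1e-7, seed = 1) {
  x <- as.matrix(peak_maps)
  p <- nrow(x)
  stopifnot(k >= 1)
  if (p < k) stop("need at least as many maps as clusters (P >= k)")
  xc <- x - rowMeans(x)
  nrm <- sqrt(rowSums(xc^2))
  if (any(nrm < 1e-12)) stop("degenerate (zero-norm) input maps")
  w <- rowMeans(xc^2)           # GFP^2 per map
  xn <- xc / nrm
  if (nrow(unique(round(xn * 1e9))) < k) {
    stop("fewer distinct maps than k")
  }
  sw <- sum(w)

  fit_once <- function(init_idx) {
    cmat <- xn[init_idx, , drop = FALSE]
    gev_prev <- -Inf
    lab <- rep(1L, p)
    for (it in seq_len(max_iter)) {
      proj <- xn %*% t(cmat)               # P x k cosines
      lab <- max.col(proj^2, ties.method = "first")
      expl <- proj[cbind(seq_len(p), lab)]^2
      # empty cluster: re-seed from the worst-explained map
      for (j in seq_len(k)) {
        if (!any(lab == j)) {
          worst <- which.min(expl)
          cmat[j, ] <- xn[worst, ]
          lab[worst] <- j
          expl[worst] <- 1
        }
      }
      gev <- sum(w * expl) / sw
      for (j in seq_len(k)) {
        idx <- which(lab == j)
        s <- crossprod(xn[idx, , drop = FALSE] * sqrt(w[idx]))
        v1 <- eigen(s, symmetric = TRUE)$vectors[, 1]
        v1 <- v1 - mean(v1)
        cmat[j, ] <- v1 / sqrt(sum(v1^2))
      }
      if (abs(gev - gev_prev) < tol) break
      gev_prev <- gev
    }
    proj <- xn %*% t(cmat)
    lab <- max.col(proj^2, ties.method = "first")
    gev <- sum(w * proj[cbind(seq_len(p), lab)]^2) / sw
    list(maps = cmat, gev = gev)
  }

  with_private_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- fit_once(sample.int(p, k))
      if (is.null(best) || fit$gev > best$gev) best <- fit
    }
    maps <- normalize_maps(best$maps)
    rownames(maps) <- paste0("M", seq_len(k))
    if (!is.null(colnames(x))) colnames(maps) <- colnames(x)
    structure(list(maps = maps, labels = rownames(maps),
                   gev = best$gev, k = k,
                   channel_labels = colnames(x)),
              class = "microstate_model")
  })
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d, GEV = %.3f, labels: %s\n",
              x$k, x$gev, paste(x$labels, collapse = " ")))
  invisible(x)
}

#' Global explained variance of a labelled assignment
#'
#' `GEV = sum_t (GFP(t) * corr(v(t), map_label(t)))^2 / sum_t GFP(t)^2`,
#' where the correlation uses the zero-mean map convention (spatial
#' correlation = cosine similarity).
#'
#' @param model A `microstate_model` (or a bare `k x n_channels` map
#'   matrix with zero-mean unit-norm rows).
#' @param epochs An `epoch_set`, a single matrix, or a list of matrices.
#' @param assignment Integer per-sample labels over the concatenated
#'   epochs.
#' @return GEV in `[0, 1]`.
#' @export
compute_gev <- function(model, epochs, assignment) {
  maps <- if (inherits(model, "microstate_model")) model$maps else model
  mats <- if (inherits(epochs, "epoch_set")) epochs$epochs
          else if (is.list(epochs)) epochs else list(epochs)
  v <- do.call(cbind, mats)
  stopifnot(length(assignment) == ncol(v))
  vc <- sweep(v, 2, colMeans(v))
  n <- nrow(vc)
  num <- (colSums(t(maps)[, assignment, drop = FALSE] * vc) / sqrt(n))^2
  den <- colSums(vc^2) / n
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

#' Aggregate individual microstate models into group mean maps
#'
#' Aligns every model to a running reference (the first model) with the
#' best row permutation maximizing total absolute spatial correlation,
#' flips signs so correlations are positive, then averages channel-wise
#' and renormalizes.
#'
#' @param models List of `microstate_model` objects sharing `k` and
#'   channel count.
#' @return A `microstate_model` of group mean maps (GEV set to the mean
#'   of the inputs' GEVs).
#' @export
aggregate_group_maps <- function(models) {
  stopifnot(length(models) >= 1)
  k <- models[[1]]$k
  nch <- ncol(models[[1]]$maps)
  for (m in models) {
    if (m$k != k || ncol(m$maps) != nch) {
      stop("all models must share k and channel count")
    }
  }
  ref <- models[[1]]$maps
  acc <- matrix(0, k, nch)
  for (m in models) {
    al <- best_alignment(ref, m$maps)
    acc <- acc + m$maps[al$perm, , drop = FALSE] * al$signs
  }
  maps <- normalize_maps(acc / length(models))
  rownames(maps) <- rownames(ref)
  colnames(maps) <- colnames(models[[1]]$maps)
  structure(list(maps = maps, labels = rownames(maps),
                 gev = mean(vapply(models, function(m) m$gev, 0)),
                 k = k, channel_labels = models[[1]]$channel_labels),
            class = "microstate_model")
}

#' Relabel a model against the canonical A-D templates
#'
#' Finds the row permutation of the model's maps that maximizes total
#' absolute spatial correlation with the canonical templates (polarity
#' ignored), reorders the maps accordingly, and labels them A, B, C, D.
#' Exact ties are broken deterministically in favour of the smallest
#' label indices.
#'
#' @param model A `microstate_model` with `k` equal to the canonical set
#'   size.
#' @param canonical Canonical map matrix (default [canonical_maps()] on
#'   the model's channels).
#' @return The relabelled `microstate_model`, with a `canonical_corr`
#'   field giving each map's absolute correlation to its template.
#' @export
assign_canonical_labels <- function(model, canonical = NULL) {
  stopifnot(inherits(model, "microstate_model"))
  if (is.null(canonical)) {
    canonical <- canonical_maps(model$channel_labels)
  }
  if (inherits(canonical, "microstate_templates")) {
    canonical <- canonical$maps
  }
  if (nrow(canonical) != model$k) stop("canonical set size must equal k")
  al <- best_alignment(canonical, model$maps)
  out <- model
  out$maps <- model$maps[al$perm, , drop = FALSE]
  rownames(out$maps) <- rownames(canonical)
  out$labels <- rownames(canonical)
  out$canonical_corr <- stats::setNames(al$corrs, rownames(canonical))
  out
}

#' Back-fit a microstate model to epochs
#'
#' Assigns every sample to the map with the highest absolute spatial
#' correlation (no temporal smoothing by default). Runs are computed
#' per epoch and never span epoch boundaries. Optionally, segments
#' shorter than `min_duration_ms` are absorbed into the neighbouring
#' state with the higher mean absolute correlation over the segment.
#'
#' @param epochs An `epoch_set` (or single matrix).
#' @param model A `microstate_model`.
#' @param min_duration_ms Minimum segment duration; 0 (default)
#'   disables the merge.
#' @return An object of class `labeled_segmentation`: list with
#'   `labels` (list of per-epoch integer vectors), `segments` (data
#'   frame: epoch, state, start_sample, length_samples),
#'   `sampling_rate_hz`, `k`, `state_labels`.
#' @export
backfit <- function(epochs, model, min_duration_ms = 0) {
  stopifnot(inherits(model, "microstate_model"))
  if (!inherits(epochs, "epoch_set")) {
    m <- as.matrix(epochs)
    epochs <- structure(list(epochs = list(m), start_samples = 1L,
                             epoch_length_s = NA_real_,
                             sampling_rate_hz = NA_real_,
                             channel_labels = rownames(m)),
                        class = "epoch_set")
  }
  fs <- epochs$sampling_rate_hz
  min_len <- if (min_duration_ms > 0 && is.finite(fs)) {
    ceiling(min_duration_ms * fs / 1000)
  } else 0L
  lab_list <- vector("list", length(epochs$epochs))
  seg_rows <- list()
  for (e in seq_along(epochs$epochs)) {
    v <- epochs$epochs[[e]]
    vc <- sweep(v, 2, colMeans(v))
    proj <- abs(model$maps %*% vc)       # k x n
    lab <- max.col(t(proj), ties.method = "first")
    if (min_len > 1) lab <- merge_short_runs(lab, proj, min_len)
    lab_list[[e]] <- lab
    r <- rle(lab)
    seg_rows[[e]] <- data.frame(
      epoch = e, state = r$values,
      start_sample = cumsum(c(1L, utils::head(r$lengths, -1))),
      length_samples = r$lengths
    )
  }
  structure(list(labels = lab_list,
                 segments = do.call(rbind, seg_rows),
                 sampling_rate_hz = fs, k = model$k,
                 state_labels = model$labels),
            class = "labeled_segmentation")
}

# Absorb runs shorter than min_len into the neighbouring state whose
# map correlates better with the run's samples. The shortest run is
# merged first and run lengths are recomputed after every merge, so
# merges cascade until no run is below the minimum.
merge_short_runs <- function(lab, proj, min_len) {
  for (iter in seq_len(length(lab))) {
    r <- rle(lab)
    if (length(r$lengths) <= 1 || all(r$lengths >= min_len)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    i <- which.min(ifelse(r$lengths < min_len, r$lengths, Inf))
    cand <- unique(c(if (i > 1) r$values[i - 1],
                     if (i < length(r$values)) r$values[i + 1]))
    idx <- starts[i]:ends[i]
    sc <- vapply(cand, function(s) mean(proj[s, idx]), 0)
    lab[idx] <- cand[which.max(sc)]
  }
  lab
}

#' Build a segmentation from per-epoch label vectors
#'
#' Constructs a `labeled_segmentation` directly from integer state
#' labels (one vector per epoch), e.g. for ground-truth sequences.
#'
#' @param labels_list List of integer per-sample label vectors (or a
#'   single vector).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param k Number of states (default: maximum observed label).
#' @param state_labels Optional state names of length `k`.
#' @return A `labeled_segmentation`.
#' @export
segmentation_from_labels <- function(labels_list, sampling_rate_hz,
                                     k = NULL, state_labels = NULL) {
  if (!is.list(labels_list)) labels_list <- list(labels_list)
  if (is.null(k)) k <- max(unlist(labels_list))
  seg_rows <- lapply(seq_along(labels_list), function(e) {
    r <- rle(as.integer(labels_list[[e]]))
    data.frame(epoch = e, state = r$values,
               start_sample = cumsum(c(1L, utils::head(r$lengths, -1))),
               length_samples = r$lengths)
  })
  if (is.null(state_labels)) state_labels <- paste0("M", seq_len(k))
  structure(list(labels = labels_list,
                 segments = do.call(rbind, seg_rows),
                 sampling_rate_hz = sampling_rate_hz, k = k,
                 state_labels = state_labels),
            class = "labeled_segmentation")
}

#' Microstate temporal parameters of a segmentation
#'
#' Computes, per state: coverage (fraction of analyzed samples),
#' mean duration (ms), occurrence (runs per second), and the matrix of
#' conditional transition probabilities between distinct states
#' (`transition[s, s']` = probability that a run of `s` is immediately
#' followed by a run of `s'` within an epoch; epoch-final runs
#' contribute no transition). States with no outgoing transitions have
#' an `NA` transition row (flagged undefined, not zero-filled).
#'
#' @param seg A `labeled_segmentation`.
#' @param k Number of states (default: from the segmentation).
#' @return An object of class `microstate_parameters`: list with
#'   `coverage`, `duration_ms`, `occurrence_per_s`, `transition`
#'   (`k x k`), `n_transitions`, `state_labels`.
#' @export
compute_parameters <- function(seg, k = seg$k) {
  stopifnot(inherits(seg, "labeled_segmentation"))
  segs <- seg$segments
  if (nrow(segs) == 0) stop("empty segmentation")
  fs <- seg$sampling_rate_hz
  total_samples <- sum(segs$length_samples)
  total_seconds <- total_samples / fs
  coverage <- duration_ms <- occurrence <- numeric(k)
  for (s in seq_len(k)) {
    rows <- segs[segs$state == s, , drop = FALSE]
    coverage[s] <- sum(rows$length_samples) / total_samples
    duration_ms[s] <- if (nrow(rows)) {
      mean(rows$length_samples) * 1000 / fs
    } else 0
    occurrence[s] <- nrow(rows) / total_seconds
  }
  trans_counts <- matrix(0, k, k)
  for (e in unique(segs$epoch)) {
    st <- segs$state[segs$epoch == e]
    if (length(st) >= 2) {
      from <- st[-length(st)]; to <- st[-1]
      for (i in seq_along(from)) {
        trans_counts[from[i], to[i]] <- trans_counts[from[i], to[i]] + 1
      }
    }
  }
  outgoing <- rowSums(trans_counts)
  transition <- trans_counts / ifelse(outgoing > 0, outgoing, NA)
  labs <- seg$state_labels
  if (is.null(labs) || length(labs) != k) labs <- paste0("M", seq_len(k))
  names(coverage) <- names(duration_ms) <- names(occurrence) <- labs
  dimnames(transition) <- list(labs, labs)
  structure(list(coverage = coverage, duration_ms = duration_ms,
                 occurrence_per_s = occurrence, transition = transition,
                 n_transitions = sum(trans_counts),
                 state_labels = labs),
            class = "microstate_parameters")
}

#' Tidy per-state parameter table
#'
#' @param params A `microstate_parameters`.
#' @param subject_id Optional subject identifier column.
#' @return Data frame: subject_id (if given), state, coverage,
#'   duration_ms, occurrence_per_s.
#' @export
parameters_to_df <- function(params, subject_id = NULL) {
  out <- data.frame(state = params$state_labels,
                    coverage = as.numeric(params$coverage),
                    duration_ms = as.numeric(params$duration_ms),
                    occurrence_per_s = as.numeric(params$occurrence_per_s))
  if (!is.null(subject_id)) out <- cbind(subject_id = subject_id, out)
  rownames(out) <- NULL
  out
}

#' Long-format transition probability table
#'
#' @param params A `microstate_parameters`.
#' @param subject_id Optional subject identifier column.
#' @return Data frame: subject_id (if given), from, to, probability
#'   (distinct-state pairs only).
#' @export
transitions_to_df <- function(params, subject_id = NULL) {
  k <- length(params$state_labels)
  idx <- which(row(params$transition) != col(params$transition))
  out <- data.frame(
    from = params$state_labels[row(params$transition)[idx]],
    to = params$state_labels[col(params$transition)[idx]],
    probability = params$transition[idx]
  )
  out <- out[order(out$from, out$to), ]
  if (!is.null(subject_id)) out <- cbind(subject_id = subject_id, out)
  rownames(out) <- NULL
  out
}

#' Export a microstate model as a delimited table
#'
#' Writes the K maps with a channel-label header, preceded by comment
#' lines carrying k, GEV, and the state labels.
#'
#' @param model A `microstate_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_microstate_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# k=%d", model$k),
               sprintf("# gev=%.6f", model$gev),
               sprintf("# labels=%s", paste(model$labels, collapse = ","))),
             con)
  tab <- as.data.frame(model$maps)
  utils::write.table(cbind(state = model$labels, tab), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
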