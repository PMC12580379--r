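#' Built-in 19-channel 10-20 montage
#'
#' Unit-sphere electrode coordinates for the classic 19-channel
#' international 10-20 montage. Coordinates use the neurological
#' convention: x increases to the right, y to the front (nasion),
#' z upward; every position has unit Euclidean norm.
#'
#' Legacy temporal labels (T3, T4, T5, T6) are accepted everywhere a
#' channel label is resolved and map to their modern equivalents
#' (T7, T8, P7, P8).
#'
#' @param labels Optional character vector of channel labels to look up
#'   (in order). Default returns the full 19-channel montage.
#' @return A data frame with columns `label`, `x`, `y`, `z`.
#' @export
#' @examples
#' head(montage_1020())
#' montage_1020(c("Fp1", "T3", "O2"))
montage_1020 <- function(labels = NULL) {
  m <- .montage_table
  if (is.null(labels)) return(m)
  canon <- resolve_1020_labels(labels)
  idx <- match(canon, m$label)
  out <- m[idx, , drop = FALSE]
  out$label <- labels
  rownames(out) <- NULL
  out
}

# Unit-sphere 10-20 positions (x right, y anterior, z superior).
.montage_table <- data.frame(
  label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
            "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
  x = c(-0.329991, 0.330899, -0.847627, -0.595220, 0.003526, 0.606623,
        0.846108, -0.976571, -0.706876, 0.003983, 0.720988, 0.978884,
        -0.701950, -0.480960, 0.002804, 0.498504, 0.706832, -0.252329,
        0.256398),
  y = c(0.940726, 0.940402, 0.512395, 0.629189, 0.660786, 0.635512,
        0.514567, -0.185874, -0.125802, -0.091066, -0.117092, -0.172815,
        -0.711819, -0.714878, -0.700597, -0.703519, -0.706954, -0.964666,
        -0.963610),
  z = c(-0.078359, -0.078426, -0.137767, 0.499834, 0.750566, 0.477633,
        -0.139004, -0.108447, 0.696060, 0.995837, 0.682983, -0.109187,
        -0.024101, 0.507570, 0.713552, 0.506513, -0.024575, 0.075827,
        0.075607),
  stringsAsFactors = FALSE
)

.label_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Resolve 10-20 channel labels to canonical montage names
#'
#' Case-insensitive lookup accepting the legacy temporal labels
#' (T3/T4/T5/T6). Unknown labels raise an error naming them.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector of canonical labels.
#' @export
resolve_1020_labels <- function(labels) {
  canon_lower <- tolower(.montage_table$label)
  out <- character(length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    ali <- .label_aliases[toupper(lab)]
    lab2 <- if (!is.na(ali)) ali else lab
    j <- match(tolower(lab2), canon_lower)
    if (is.na(j)) {
      stop("unknown 10-20 channel label: '", labels[i], "'", call. = FALSE)
    }
    out[i] <- .montage_table$label[j]
  }
  out
}

# Montage coordinates as an n x 3 matrix for a label vector.
montage_xyz <- function(labels) {
  m <- montage_1020(labels)
  as.matrix(m[, c("x", "y", "z")])
}

#' Canonical microstate template maps A-D
#'
#' Fixed 19-channel topographies implementing the four textbook
#' microstate classes used for canonical relabelling:
#' A (right-frontal to left-posterior diagonal), B (left-frontal to
#' right-posterior diagonal), C (symmetric anterior-posterior), and
#' D (fronto-central versus peripheral). Rows are average-referenced
#' (zero mean) and unit-norm; polarity is arbitrary since all
#' comparisons ignore it.
#'
#' @param labels Channel labels defining the order (default: the full
#'   built-in montage).
#' @return A `k x n_channels` numeric matrix with rownames `A`-`D` and
#'   colnames set to `labels`.
#' @export
canonical_maps <- function(labels = montage_1020()$label) {
  xyz <- montage_xyz(labels)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  maps <- rbind(
    A = x + y,        # right-frontal positive, left-posterior negative
    B = -x + y,       # left-frontal positive, right-posterior negative
    C = y,            # anterior-posterior axis, left-right symmetric
    D = z             # vertex (fronto-central) versus peripheral
  )
  maps <- normalize_maps(maps)
  colnames(maps) <- labels
  maps
}

# Zero-mean (average reference) and unit-norm each row of a map matrix.
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("degenerate (constant) map cannot be normalized")
  maps / nrm
}

# Absolute spatial correlation between two zero-mean map vectors.
# With the zero-mean map convention spatial correlation equals cosine
# similarity, which is what all assignment steps use.
spatial_corr <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
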