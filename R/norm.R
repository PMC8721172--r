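# ERCC spike-in normalization and sample-level QC.

AVOGADRO <- 6.02214076e23

#' Expected spike molecules from attomoles
#'
#' @param attomoles Non-negative amount in attomoles.
#' @return Expected molecule count (`attomoles * 1e-18 * Avogadro`).
#' @export
expected_molecules <- function(attomoles) {
  if (any(attomoles < 0)) stop_arg("'attomoles' must be >= 0")
  attomoles * 1e-18 * AVOGADRO
}

#' ERCC median-ratio size factors
#'
#' For each sample the factor is the median, over detected spikes, of
#' observed count / expected molecules; factors are then rescaled to have
#' geometric mean 1. Requires at least `min_spikes` detected (count > 0)
#' spikes per sample.
#'
#' @param counts Feature x sample count matrix (spike rows included).
#' @param design Spike design `data.frame` with `spike_id` and either
#'   `expected_molecules` or `attomoles`.
#' @param min_spikes Minimum detected spikes per sample (default 8).
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts, design, min_spikes = 8) {
  if (is.null(design$expected_molecules)) {
    design$expected_molecules <- expected_molecules(design$attomoles)
  }
  keep <- design$expected_molecules > 0 & design$spike_id %in% rownames(counts)
  design <- design[keep, , drop = FALSE]
  sc <- counts[design$spike_id, , drop = FALSE]
  f <- vapply(seq_len(ncol(sc)), function(s) {
    det <- sc[, s] > 0
    if (sum(det) < min_spikes) {
      stop_arg(sprintf("sample '%s' has %d detected spikes (need >= %d)",
                       colnames(sc)[s], sum(det), min_spikes))
    }
    stats::median(sc[det, s] / design$expected_molecules[det])
  }, numeric(1))
  names(f) <- colnames(sc)
  f / geomean(f)
}

#' Normalize counts by size factors
#'
#' @param counts Feature x sample matrix.
#' @param factors Positive per-sample size factors ([size_factors()]).
#' @param pseudocount Added before the log2 transform (default 1).
#' @param samples Optional sample metadata carried along.
#' @param annotation Optional annotation carried along.
#' @return List of class `norm_matrix`: `normalized`, `log2`
#'   (`log2(normalized + pseudocount)`), `size_factors`, `pseudocount`,
#'   plus `samples`/`annotation` when given.
#' @export
normalize_counts <- function(counts, factors, pseudocount = 1,
                             samples = NULL, annotation = NULL) {
  if (any(factors <= 0)) stop_arg("size factors must be positive")
  stopifnot(length(factors) == ncol(counts), pseudocount > 0)
  normalized <- sweep(counts, 2, factors, "/")
  structure(list(normalized = normalized,
                 log2 = log2(normalized + pseudocount),
                 size_factors = factors, pseudocount = pseudocount,
                 samples = samples, annotation = annotation),
            class = "norm_matrix")
}

#' Top highly and variably expressed genes
#'
#' Among features whose mean log expression is at or above the matrix-wide
#' median, returns the `n` with the largest variance across samples.
#' Deterministic: ties are broken by feature id.
#'
#' @param log_matrix Feature x sample log-expression matrix.
#' @param n Number of features (default 500).
#' @return Character vector of feature ids.
#' @export
top_variable_genes <- function(log_matrix, n = 500) {
  n <- check_count(n, "n", min = 1L)
  if (n > nrow(log_matrix)) stop_arg("'n' exceeds the number of features")
  mu <- rowMeans(log_matrix)
  cand <- which(mu >= stats::median(mu))
  if (length(cand) < n) cand <- seq_len(nrow(log_matrix))
  v <- apply(log_matrix[cand, , drop = FALSE], 1, stats::var)
  ids <- rownames(log_matrix)[cand]
  ids[order(-v, ids)][seq_len(n)]
}

#' Spearman-correlation distance between samples
#'
#' `d(i, j) = 1 - rho(i, j)` with average-rank tie handling. A constant
#' column has undefined correlation; it is treated as rho 0 (distance 1)
#' with a warning. The diagonal is exactly 0.
#'
#' @param log_matrix Feature x sample matrix.
#' @param features Optional feature subset (e.g. [top_variable_genes()]).
#' @return Symmetric sample x sample distance matrix.
#' @export
spearman_distance <- function(log_matrix, features = NULL) {
  m <- if (is.null(features)) log_matrix else log_matrix[features, , drop = FALSE]
  if (nrow(m) < 3) stop_arg("need at least 3 features")
  const <- apply(m, 2, function(x) max(x) == min(x))
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (any(const)) {
    warning("constant column(s): Spearman rho undefined, treated as 0")
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' PCA quality control
#'
#' Feature-centered SVD of the samples. Component signs are fixed so the
#' largest-magnitude feature loading of each component is positive, making
#' scores deterministic.
#'
#' @param log_matrix Feature x sample matrix.
#' @param n_components Components to return (default all).
#' @return List: `scores` (samples x components), `variance_explained`
#'   (fractions, summing to <= 1), `loadings`.
#' @export
pca_qc <- function(log_matrix, n_components = NULL) {
  if (ncol(log_matrix) < 2) stop_arg("need at least 2 samples")
  pc <- stats::prcomp(t(log_matrix), center = TRUE, scale. = FALSE)
  k <- if (is.null(n_components)) ncol(pc$x) else min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    w <- pc$rotation[, j]
    sign(w[which.max(abs(w))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  list(scores = scores,
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       loadings = loadings)
}
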