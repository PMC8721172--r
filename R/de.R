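# Per-gene linear models with surrogate covariates, empirical-Bayes
# moderated t-statistics, BH FDR, directional DEG lists, and the 4-set
# Venn partition into sex-chromosome-dosage categories.

#' Genotype design matrix
#'
#' Intercept + treatment-coded genotype indicators (XX reference), with
#' optional surrogate covariate columns appended.
#'
#' @param samples Sample metadata with a `genotype` column.
#' @param surrogates Optional samples x k matrix from
#'   [estimate_surrogates()].
#' @return Numeric design matrix (full column rank required downstream).
#' @export
design_matrix <- function(samples, surrogates = NULL) {
  geno <- factor(samples$genotype, levels = genotype_levels())
  if (any(table(geno) < 2)) stop_arg("each genotype needs >= 2 samples")
  X <- stats::model.matrix(~geno)
  colnames(X) <- c("(Intercept)", "XO", "XY")
  if (!is.null(surrogates) && NCOL(surrogates) > 0) {
    surrogates <- as.matrix(surrogates)
    colnames(surrogates) <- paste0("SV", seq_len(ncol(surrogates)))
    X <- cbind(X, surrogates)
  }
  rownames(X) <- samples$sample_id
  X
}

# Pairwise contrasts on the treatment-coded design, expressed as
# log2FC of the first genotype over the second.
contrast_matrix <- function(design) {
  p <- ncol(design)
  cm <- matrix(0, p, 3, dimnames = list(colnames(design),
                                        c("XXvsXO", "XXvsXY", "XOvsXY")))
  cm["XO", "XXvsXO"] <- -1
  cm["XY", "XXvsXY"] <- -1
  cm["XO", "XOvsXY"] <- 1
  cm["XY", "XOvsXY"] <- -1
  cm
}

#' Surrogate covariates by residual-matrix PCA
#'
#' Regresses the primary design out of each gene, then takes the top `k`
#' left singular vectors of the sample x gene residual matrix. The
#' surrogates are orthogonal to the design by construction and capture
#' shared unmodelled structure such as batch. Signs are fixed as in
#' [pca_qc()].
#'
#' @param log_matrix Feature x sample matrix.
#' @param design Primary design matrix (no surrogates).
#' @param k Number of surrogates; 0 returns `NULL`.
#' @return Samples x k matrix, or `NULL` when `k = 0`.
#' @export
estimate_surrogates <- function(log_matrix, design, k) {
  k <- check_count(k, "k")
  if (k == 0L) return(NULL)
  df_resid <- ncol(log_matrix) - qr(design)$rank
  if (k >= df_resid) stop_arg("'k' must be smaller than the residual df")
  fit <- stats::lm.fit(design, t(log_matrix))
  R <- fit$residuals  # samples x genes
  sv <- svd(R, nu = k, nv = 0)
  u <- sv$u
  for (j in seq_len(k)) {
    if (u[which.max(abs(u[, j])), j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- colnames(log_matrix)
  colnames(u) <- paste0("SV", seq_len(k))
  u
}

#' Choose the number of surrogates by permutation parallel analysis
#'
#' Compares the residual-matrix singular values to those obtained after
#' independently permuting each gene's residuals across samples, and
#' keeps components whose singular value exceeds the permutation
#' `quantile` (Buja-Eyuboglu style).
#'
#' @param log_matrix,design As in [estimate_surrogates()].
#' @param n_perm Number of permutations (default 20).
#' @param quantile Null quantile to exceed (default 0.95).
#' @param seed Seed for the permutations.
#' @return Integer >= 0.
#' @export
num_surrogates <- function(log_matrix, design, n_perm = 20,
                           quantile = 0.95, seed = 1L) {
  fit <- stats::lm.fit(design, t(log_matrix))
  R <- fit$residuals
  prop <- function(d) d^2 / sum(d^2)
  p_obs <- prop(svd(R, nu = 0, nv = 0)$d)
  kmax <- ncol(log_matrix) - qr(design)$rank - 1L
  if (kmax < 1L) return(0L)
  with_seed(seed, {
    null_p <- matrix(0, n_perm, length(p_obs))
    for (b in seq_len(n_perm)) {
      # permute each gene's residuals across samples, then re-residualize
      # so the null matrix has the same rank structure as the observed
      # one; variance proportions are compared because residualization
      # shrinks the total variance
      Rp <- stats::lm.fit(design, apply(R, 2, sample))$residuals
      null_p[b, ] <- prop(svd(Rp, nu = 0, nv = 0)$d)
    }
    thr <- apply(null_p, 2, stats::quantile, probs = quantile)
    k <- 0L
    for (j in seq_len(kmax)) {
      if (p_obs[j] > thr[j]) k <- j else break
    }
    k
  })
}

#' Per-gene ordinary least squares with pairwise contrasts
#'
#' One OLS fit per gene against the shared design; the three pairwise
#' genotype contrasts (XX vs XO, XX vs XY, XO vs XY, as log2FC of first
#' over second) are evaluated from the coefficients.
#'
#' @param log_matrix Feature x sample log2-expression matrix.
#' @param design From [design_matrix()]; must be full column rank.
#' @param contrasts Optional coefficients x contrasts matrix; defaults to
#'   the three pairwise genotype contrasts of [design_matrix()].
#' @return List of class `gene_fit`: `coefficients`, `contrasts`
#'   (genes x contrasts, log2FC), `contrast_se_unscaled` (multiply by
#'   residual sd for a standard error), `sigma2`, `df_residual`,
#'   `design`.
#' @export
fit_models <- function(log_matrix, design, contrasts = NULL) {
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop_arg("design matrix is rank deficient")
  n <- ncol(log_matrix)
  fit <- stats::lm.fit(design, t(log_matrix))
  B <- t(fit$coefficients)              # genes x p
  res <- fit$residuals                  # samples x genes
  df <- n - qrX$rank
  s2 <- colSums(res^2) / df
  cm <- if (is.null(contrasts)) contrast_matrix(design) else as.matrix(contrasts)
  xtxi <- chol2inv(qr.R(qrX))
  est <- B %*% cm
  se_un <- sqrt(diag(t(cm) %*% xtxi %*% cm))  # per-contrast, gene-free
  structure(list(coefficients = B, contrasts = est,
                 contrast_se_unscaled = se_un,
                 sigma2 = s2, df_residual = df, design = design),
            class = "gene_fit")
}

# Invert the trigamma function by Newton-bisection; tolerance 1e-10.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  lo <- 1e-8; hi <- 1e8
  if (trigamma(lo) < y) return(lo)
  if (trigamma(hi) > y) return(hi)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi / lo - 1 < 1e-10) break
  }
  sqrt(lo * hi)
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates a scaled inverse-chi-square prior (d0, s0^2) for the
#' residual variances by method of moments on log s^2 (the variances are
#' modelled as s0^2 times an F(d, d0) draw), shrinks each gene's variance
#' to `(d0 s0^2 + d s^2) / (d0 + d)`, and recomputes t-statistics and
#' two-sided p-values on `d0 + d` degrees of freedom.
#'
#' @param fit From [fit_models()].
#' @param d0 Optional prior df override: `0` reproduces the ordinary
#'   per-gene t-test, `Inf` the fully pooled test.
#' @return `data.frame` of class `de_result` with one row per gene and
#'   contrast: `feature_id`, `contrast`, `log2FC`, `t`, `p`, `fdr`,
#'   `df_total`; prior estimates in attributes `d0` and `s02`.
#' @export
moderate <- function(fit, d0 = NULL) {
  stopifnot(inherits(fit, "gene_fit"))
  s2 <- fit$sigma2
  d <- fit$df_residual
  if (length(s2) < 10) stop_arg("need >= 10 genes for prior estimation")
  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e)
  rhs <- evar - trigamma(d / 2)
  if (is.null(d0)) {
    d0 <- if (rhs > 0) 2 * trigamma_inverse(rhs) else Inf
  }
  s02 <- if (is.infinite(d0) || d0 == 0) {
    exp(mean(e))  # at d0 = 0 the prior carries no weight
  } else {
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_tilde <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  df_total <- d0 + d
  cn <- colnames(fit$contrasts)
  res <- do.call(rbind, lapply(seq_along(cn), function(j) {
    se <- sqrt(s2_tilde) * fit$contrast_se_unscaled[j]
    t <- fit$contrasts[, j] / se
    t[se == 0 & fit$contrasts[, j] == 0] <- 0
    p <- 2 * stats::pt(-abs(t), df = df_total)
    p <- pmin(pmax(p, 1e-300), 1)  # keep p in (0, 1] for BH
    data.frame(feature_id = rownames(fit$contrasts), contrast = cn[j],
               log2FC = fit$contrasts[, j], t = t, p = p,
               fdr = bh_fdr(p), df_total = df_total,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(res, class = c("de_result", "data.frame"), d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1), delegated to
#' [stats::p.adjust()] after range validation.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop_arg("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select a directional DEG list
#'
#' Genes with `p < alpha`, log2FC sign matching `direction` (`"over"`:
#' first genotype of the contrast higher), and `|log2FC| > lfc_min`.
#'
#' @param results A `de_result`.
#' @param contrast One of `"XXvsXO"`, `"XXvsXY"`, `"XOvsXY"`.
#' @param direction `"over"` or `"under"`.
#' @param alpha Per-gene p threshold (default 0.05).
#' @param lfc_min Minimum |log2FC| (default 0; use 1 for the stringent
#'   lists).
#' @return Character vector of feature ids.
#' @export
select_degs <- function(results, contrast, direction = c("over", "under"),
                        alpha = 0.05, lfc_min = 0) {
  direction <- match.arg(direction)
  if (!contrast %in% unique(results$contrast)) {
    stop_arg(sprintf("unknown contrast '%s'", contrast))
  }
  r <- results[results$contrast == contrast, ]
  sgn <- if (direction == "over") r$log2FC > 0 else r$log2FC < 0
  r$feature_id[r$p < alpha & sgn & abs(r$log2FC) > lfc_min]
}

#' The six directional DEG lists
#'
#' Over- and under-expression lists from each of the three pairwise
#' genotype contrasts, named by the winning genotype, e.g. `"XX>XO"`.
#'
#' @inheritParams select_degs
#' @return Named list of six character vectors.
#' @export
deg_lists <- function(results, alpha = 0.05, lfc_min = 0) {
  list(
    "XX>XO" = select_degs(results, "XXvsXO", "over", alpha, lfc_min),
    "XX<XO" = select_degs(results, "XXvsXO", "under", alpha, lfc_min),
    "XX>XY" = select_degs(results, "XXvsXY", "over", alpha, lfc_min),
    "XX<XY" = select_degs(results, "XXvsXY", "under", alpha, lfc_min),
    "XY>XO" = select_degs(results, "XOvsXY", "under", alpha, lfc_min),
    "XY<XO" = select_degs(results, "XOvsXY", "over", alpha, lfc_min))
}

#' Four-set Venn partition with dosage categories
#'
#' Partitions the union of four named directional DEG sets into the 16
#' disjoint membership cells and derives the named dosage categories used
#' for the gain-by-the-second-X comparison:
#' \describe{
#'   \item{red}{higher in XX than both XO and XY, no XO/XY difference:
#'     `(XX>XO) & (XX>XY) & !(XY>XO) & !(XY<XO)` — X-dosage dependent.}
#'   \item{purple_solid}{`(XX>XO) & (XY>XO) & !(XX>XY)` — equally high in
#'     XX and XY, low in XO.}
#'   \item{purple_broken}{`(XX>XY) & (XY>XO)` — ordered XX > XY > XO.}
#'   \item{brown}{`(XX>XY) & (XY<XO)` — lowest in XY.}
#' }
#'
#' @param sets Named list of exactly four character vectors with names
#'   `"XX>XO"`, `"XX>XY"`, `"XY>XO"`, `"XY<XO"`.
#' @return List of class `venn_partition`: `cells` (named by the 4-bit
#'   membership pattern in the order above), `cell_counts`, `categories`,
#'   `category_counts`, `sets`.
#' @export
venn_partition <- function(sets) {
  wanted <- c("XX>XO", "XX>XY", "XY>XO", "XY<XO")
  if (!setequal(names(sets), wanted)) {
    stop_arg(sprintf("set names must be exactly: %s",
                     paste(wanted, collapse = ", ")))
  }
  sets <- sets[wanted]
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  memb <- matrix(vapply(sets, function(s) universe %in% s,
                        logical(length(universe))),
                 ncol = 4, dimnames = list(NULL, names(sets)))
  pat <- apply(memb, 1, function(b) paste(as.integer(b), collapse = ""))
  all_pat <- apply(expand.grid(rep(list(0:1), 4))[, 4:1], 1, paste,
                   collapse = "")
  cells <- lapply(stats::setNames(all_pat, all_pat), function(p) {
    universe[pat == p]
  })
  m <- function(nm) if (length(universe)) memb[, nm] else logical(0)
  categories <- list(
    red = universe[m("XX>XO") & m("XX>XY") & !m("XY>XO") & !m("XY<XO")],
    purple_solid = universe[m("XX>XO") & m("XY>XO") & !m("XX>XY")],
    purple_broken = universe[m("XX>XY") & m("XY>XO")],
    brown = universe[m("XX>XY") & m("XY<XO")])
  structure(list(cells = cells,
                 cell_counts = vapply(cells, length, integer(1)),
                 categories = categories,
                 category_counts = vapply(categories, length, integer(1)),
                 sets = sets),
            class = "venn_partition")
}
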