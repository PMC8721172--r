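# qRT-PCR relative quantification (reference-gene normalized) and the
# group-comparison statistics used across genotypes and oocyte size bins.

#' Relative expression from Cq values
#'
#' `efficiency^(-(cq_gene - cq_reference))`: the delta-Cq model with a
#' configurable amplification efficiency (2 = perfect doubling).
#'
#' @param cq_gene,cq_reference Quantification cycles, each in (0, 45).
#' @param efficiency Amplification efficiency per cycle, in (1, 2].
#' @return Relative expression level(s), > 0.
#' @export
relative_expression <- function(cq_gene, cq_reference, efficiency = 2) {
  if (any(cq_gene <= 0 | cq_gene >= 45) ||
      any(cq_reference <= 0 | cq_reference >= 45)) {
    stop_arg("Cq values must lie in (0, 45)")
  }
  if (efficiency <= 1 || efficiency > 2) {
    stop_arg("'efficiency' must be in (1, 2]")
  }
  efficiency^(-(cq_gene - cq_reference))
}

#' Summarize relative expression per group
#'
#' Mean and standard error of the mean per (gene, genotype, size_bin).
#'
#' @param records `data.frame` with `gene`, `genotype`, `size_bin`,
#'   `cq_gene`, `cq_reference`.
#' @param efficiency Passed to [relative_expression()].
#' @return `data.frame` with `gene`, `genotype`, `size_bin`, `n`, `mean`,
#'   `sem`.
#' @export
summarize_qpcr <- function(records, efficiency = 2) {
  records$level <- relative_expression(records$cq_gene, records$cq_reference,
                                       efficiency)
  grp <- interaction(records$gene, records$genotype, records$size_bin,
                     drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(records, grp), function(d) {
    data.frame(gene = d$gene[1], genotype = d$genotype[1],
               size_bin = d$size_bin[1], n = nrow(d), mean = mean(d$level),
               sem = stats::sd(d$level) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise group comparisons
#'
#' Compares expression levels between groups (typically genotypes within
#' one size bin) with one of the study's tests: pairwise Welch t-tests,
#' one-way ANOVA followed by Tukey's HSD, or Kruskal-Wallis-style rank
#' sums with Dunn's pairwise z-tests (normal approximation, tie-corrected,
#' Bonferroni-adjusted over pairs).
#'
#' @param values Numeric vector of expression levels.
#' @param groups Factor/character of the same length.
#' @param method `"welch_t"`, `"anova_tukey"`, or `"kruskal_dunn"`.
#' @return `data.frame` with `group1`, `group2`, `p` (adjusted for
#'   `anova_tukey` and `kruskal_dunn`, unadjusted Welch otherwise).
#' @export
compare_groups <- function(values, groups,
                           method = c("welch_t", "anova_tukey",
                                      "kruskal_dunn")) {
  method <- match.arg(method)
  groups <- factor(groups)
  lv <- levels(groups)
  if (length(lv) < 2) stop_arg("need at least 2 groups")
  sizes <- table(groups)
  min_n <- if (method == "kruskal_dunn") 1L else 2L
  if (any(sizes < min_n)) stop_arg("degenerate group (too few observations)")
  pairs <- utils::combn(lv, 2)

  if (method == "welch_t") {
    p <- apply(pairs, 2, function(pr) {
      a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (mean(a) == mean(b)) 1 else 0)
      }
      stats::t.test(a, b)$p.value
    })
  } else if (method == "anova_tukey") {
    fit <- stats::aov(values ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    key <- paste(pairs[2, ], pairs[1, ], sep = "-")
    key2 <- paste(pairs[1, ], pairs[2, ], sep = "-")
    idx <- match(key, rownames(tk))
    idx[is.na(idx)] <- match(key2[is.na(idx)], rownames(tk))
    p <- tk[idx, "p adj"]
  } else {
    p <- dunn_test(values, groups, pairs)
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = unname(p),
             stringsAsFactors = FALSE)
}

# Dunn's pairwise rank-sum z-tests with tie correction and Bonferroni
# adjustment over the tested pairs.
dunn_test <- function(values, groups, pairs) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n <- table(groups)
  p <- apply(pairs, 2, function(pr) {
    z <- (mean_rank[pr[1]] - mean_rank[pr[2]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[pr[1]] + 1 / n[pr[2]]))
    2 * stats::pnorm(-abs(z))
  })
  pmin(p * ncol(pairs), 1)
}

#' Simulate a small qPCR data set
#'
#' Tiny generator for testing: Cq values for a reference-stable gene set
#' across genotypes and oocyte size bins, with X-linked genes one cycle
#' higher (halved expression) in XO/XY when `dosage_effect` is `TRUE`.
#'
#' @param genes Character vector of target genes.
#' @param x_linked Logical vector marking which targets are X-linked.
#' @param size_bins Size-bin labels.
#' @param replicates Biological replicates per cell.
#' @param dosage_effect Apply the +1 cycle shift in XO/XY for X-linked
#'   targets.
#' @param sd_cq Technical Cq noise (cycles).
#' @param seed Integer seed.
#' @return `data.frame` ready for [summarize_qpcr()] /
#'   [compare_groups()].
#' @export
simulate_qpcr <- function(genes = c("Eif2s3x", "Bmp15", "Atrx", "Obox5"),
                          x_linked = c(TRUE, TRUE, TRUE, FALSE),
                          size_bins = c("20-30", "30-40", "40-50", "FG"),
                          replicates = 3, dosage_effect = TRUE,
                          sd_cq = 0.15, seed = 1L) {
  stopifnot(length(genes) == length(x_linked))
  with_seed(seed, {
    grid <- expand.grid(gene = genes, genotype = genotype_levels(),
                        size_bin = size_bins, replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    base_cq <- 24 + 2 * (match(grid$gene, genes) - 1)
    shift <- ifelse(dosage_effect & x_linked[match(grid$gene, genes)] &
                      grid$genotype != "XX", 1, 0)
    grid$cq_gene <- base_cq + shift + stats::rnorm(nrow(grid), 0, sd_cq)
    grid$cq_reference <- 20 + stats::rnorm(nrow(grid), 0, sd_cq)
    grid
  })
}
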