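# Dosage statistics: lognormal X-dosage ratio fits, 6-bin bootstrap X:A
# ratios, bin-6 genotype-ratio bootstrap, Y-gene expression classes, and
# homolog-sum comparison.

# Arithmetic mean of normalized expression per genotype (replicate mean).
genotype_means <- function(norm, genotypes = genotype_levels()) {
  stopifnot(inherits(norm, "norm_matrix"), !is.null(norm$samples))
  vapply(genotypes, function(g) {
    cols <- norm$samples$sample_id[norm$samples$genotype == g]
    rowMeans(norm$normalized[, cols, drop = FALSE])
  }, numeric(nrow(norm$normalized)))
}

#' Lognormal fit of expression ratios against XX
#'
#' Per gene, the ratio is the geometric mean of pseudocount-stabilized
#' normalized expression across numerator-genotype replicates divided by
#' the same quantity across XX replicates. The set of log ratios is
#' summarized by its lognormal parameters: geometric mean
#' `exp(mean(log r))`, multiplicative SD `exp(sd(log r))`, the one-SD
#' multiplicative interval, and a 95% t confidence interval for the
#' geometric mean. With `numerator = "pooled"`, the XO- and XY-ratio
#' vectors are concatenated before fitting.
#'
#' @param norm A `norm_matrix` with sample metadata.
#' @param genes Non-empty character vector of feature ids.
#' @param numerator `"XO"`, `"XY"`, or `"pooled"` (both against XX).
#' @param pseudocount Added to every replicate value before logs
#'   (default 0.5 normalized units).
#' @return List of class `ratio_fit`: `n`, `geometric_mean`, `sdlog`,
#'   `mult_sd_interval`, `ci_mean`, and `ratios` (per-gene table ordered
#'   by `start_bp` when annotation is attached to `norm`).
#' @export
ratio_fit <- function(norm, genes, numerator = c("pooled", "XO", "XY"),
                      pseudocount = 0.5) {
  numerator <- match.arg(numerator)
  if (length(genes) == 0L) stop_arg("empty gene set")
  stopifnot(all(genes %in% rownames(norm$normalized)))
  num_genos <- if (numerator == "pooled") c("XO", "XY") else numerator

  gm_geno <- function(g, ids) {
    cols <- norm$samples$sample_id[norm$samples$genotype == g]
    apply(norm$normalized[ids, cols, drop = FALSE] + pseudocount, 1, geomean)
  }
  den <- gm_geno("XX", genes)
  per_geno <- lapply(num_genos, function(g) gm_geno(g, genes) / den)
  log_r <- log(unlist(per_geno, use.names = FALSE))

  ratio_tab <- data.frame(feature_id = genes,
                          ratio = exp(rowMeans(do.call(cbind,
                                                       lapply(per_geno, log)))),
                          stringsAsFactors = FALSE)
  if (!is.null(norm$annotation)) {
    idx <- match(genes, norm$annotation$feature_id)
    ratio_tab$chromosome <- norm$annotation$chromosome[idx]
    ratio_tab$start_bp <- norm$annotation$start_bp[idx]
    ratio_tab <- ratio_tab[order(ratio_tab$start_bp, ratio_tab$feature_id), ]
    rownames(ratio_tab) <- NULL
  }

  n <- length(log_r)
  mu <- mean(log_r)
  sdl <- if (n > 1) stats::sd(log_r) else 0
  gm <- exp(mu)
  half <- if (n > 1) stats::qt(0.975, n - 1) * sdl / sqrt(n) else 0
  structure(list(n = n, geometric_mean = gm, sdlog = sdl,
                 mult_sd_interval = c(gm / exp(sdl), gm * exp(sdl)),
                 ci_mean = c(exp(mu - half), exp(mu + half)),
                 numerator = numerator, ratios = ratio_tab),
            class = "ratio_fit")
}

#' Assign genes to equally sized expression bins
#'
#' Genes are sorted by mean normalized expression (ties broken by feature
#' id) and split into `n_bins` contiguous groups whose sizes differ by at
#' most one; the extra genes go to the highest-expression bins. Bin 1 is
#' the lowest-expressed, bin `n_bins` the highest.
#'
#' @param mean_expr Named numeric vector (mean normalized expression
#'   across all samples).
#' @param n_bins Number of bins (default 6).
#' @return Named integer vector of bin labels (1..`n_bins`).
#' @export
assign_bins <- function(mean_expr, n_bins = 6) {
  n_bins <- check_count(n_bins, "n_bins", min = 1L)
  n <- length(mean_expr)
  if (n < n_bins) stop_arg("fewer genes than bins")
  ids <- names(mean_expr)
  ord <- order(mean_expr, ids)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- base + as.integer(seq_len(n_bins) > n_bins - extra)
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  names(bins) <- ids
  bins
}

#' Binned bootstrap X:autosome expression ratio
#'
#' Within each expression bin and genotype: draw `resample_size` X-linked
#' genes and `resample_size` autosomal genes with replacement
#' (independently), take the median per-genotype mean expression of each
#' draw, and record the X:A ratio of medians; repeated `reps` times.
#' Y-linked and PAR-Y genes and spike-ins are excluded from the universe;
#' PAR-X genes count as X-linked.
#'
#' @param norm A `norm_matrix` with annotation and samples attached.
#' @param bins From [assign_bins()] on the same universe.
#' @param resample_size Genes per draw (default 100).
#' @param reps Bootstrap repetitions (default 5000).
#' @param seed Integer seed; cells are drawn in a fixed (bin, genotype)
#'   order so results are reproducible.
#' @return `data.frame` of class `bin_bootstrap`: `bin`, `genotype`,
#'   `rep`, `ratio`; boxplot summaries via [bootstrap_stats()].
#' @export
xa_bootstrap <- function(norm, bins, resample_size = 100, reps = 5000,
                         seed = 1L) {
  ann <- norm$annotation
  stopifnot(!is.null(ann))
  gm <- genotype_means(norm)
  strat <- feature_stratum(ann)[match(rownames(gm), ann$feature_id)]
  with_seed(seed, {
    out <- list()
    for (b in sort(unique(bins))) {
      in_bin <- names(bins)[bins == b]
      xg <- in_bin[strat[match(in_bin, rownames(gm))] == "X"]
      ag <- in_bin[strat[match(in_bin, rownames(gm))] == "A"]
      if (length(xg) == 0L) stop_arg(sprintf("bin %d: empty X stratum", b))
      if (length(ag) == 0L) stop_arg(sprintf("bin %d: empty autosomal stratum", b))
      for (g in genotype_levels()) {
        xv <- gm[xg, g]; av <- gm[ag, g]
        xmed <- resample_medians(xv, resample_size, reps)
        amed <- resample_medians(av, resample_size, reps)
        out[[length(out) + 1L]] <- data.frame(
          bin = b, genotype = g, rep = seq_len(reps), ratio = xmed / amed)
      }
    }
    res <- do.call(rbind, out)
    attr(res, "params") <- list(resample_size = resample_size, reps = reps,
                                seed = seed)
    class(res) <- c("bin_bootstrap", "data.frame")
    res
  })
}

# Stratum per feature for the X:A universe: X (x_linked + par_x),
# A (autosomal), or NA (excluded: y_linked, par_y, spike).
feature_stratum <- function(ann) {
  ifelse(ann$feature_class %in% c("x_linked", "par_x"), "X",
         ifelse(ann$feature_class == "autosomal", "A", NA_character_))
}

resample_medians <- function(v, size, reps) {
  idx <- sample.int(length(v), size * reps, replace = TRUE)
  m <- matrix(v[idx], nrow = reps)
  apply(m, 1, stats::median)
}

#' Mean expression over the X:A bootstrap universe
#'
#' Convenience wrapper: mean normalized expression across all samples for
#' the genes eligible for [xa_bootstrap()] (X-linked/PAR-X + autosomal).
#'
#' @param norm A `norm_matrix` with annotation.
#' @return Named numeric vector.
#' @export
xa_universe_means <- function(norm) {
  ann <- norm$annotation
  strat <- feature_stratum(ann)[match(rownames(norm$normalized),
                                      ann$feature_id)]
  keep <- !is.na(strat)
  rowMeans(norm$normalized[keep, , drop = FALSE])
}

#' Boxplot summaries of bootstrap draws
#'
#' @param boot A `bin_bootstrap` (or the bin-6 genotype-ratio result).
#' @param by Grouping columns (default `c("bin", "genotype")`).
#' @return `data.frame` with median, quartiles, and 1.5-IQR whiskers per
#'   group.
#' @export
bootstrap_stats <- function(boot, by = intersect(c("bin", "genotype", "ratio_of"),
                                                 names(boot))) {
  by <- setdiff(by, "ratio")
  grp <- interaction(boot[by], drop = TRUE, lex.order = TRUE)
  res <- do.call(rbind, lapply(split(seq_len(nrow(boot)), grp), function(i) {
    st <- grDevices::boxplot.stats(boot$ratio[i])$stats
    cbind(boot[i[1], by, drop = FALSE],
          data.frame(lower_whisker = st[1], q1 = st[2], median = st[3],
                     q3 = st[4], upper_whisker = st[5]))
  }))
  rownames(res) <- NULL
  res
}

#' Bin-6 bootstrap of XO:XX and XY:XX ratios
#'
#' Among the X-linked genes of the highest expression bin: per repetition
#' draw `resample_size` genes with replacement and compute the ratio of
#' the median XO (or XY) mean expression of the drawn genes to the median
#' XX mean expression of the same genes.
#'
#' @inheritParams xa_bootstrap
#' @param bin Which bin to use (default the highest).
#' @return `data.frame` of class `bin_bootstrap` with columns `ratio_of`
#'   (`"XO:XX"`, `"XY:XX"`), `rep`, `ratio`.
#' @export
bin6_genotype_ratio_bootstrap <- function(norm, bins, bin = max(bins),
                                          resample_size = 100, reps = 5000,
                                          seed = 1L) {
  ann <- norm$annotation
  gm <- genotype_means(norm)
  strat <- feature_stratum(ann)[match(rownames(gm), ann$feature_id)]
  xg <- names(bins)[bins == bin &
                      strat[match(names(bins), rownames(gm))] == "X"]
  if (length(xg) == 0L) stop_arg(sprintf("bin %d: empty X stratum", bin))
  with_seed(seed, {
    idx <- matrix(sample.int(length(xg), resample_size * reps, replace = TRUE),
                  nrow = reps)
    out <- lapply(c(XO = "XO", XY = "XY"), function(g) {
      num <- apply(matrix(gm[xg, g][idx], nrow = reps), 1, stats::median)
      den <- apply(matrix(gm[xg, "XX"][idx], nrow = reps), 1, stats::median)
      num / den
    })
    res <- data.frame(
      ratio_of = rep(c("XO:XX", "XY:XX"), each = reps),
      rep = rep(seq_len(reps), 2),
      ratio = c(out$XO, out$XY))
    attr(res, "params") <- list(resample_size = resample_size, reps = reps,
                                seed = seed, bin = bin)
    class(res) <- c("bin_bootstrap", "data.frame")
    res
  })
}

#' Classify Y-linked and PAR-Y genes by XY/XX expression
#'
#' `log2FC = log2((mean_XY + pc) / (mean_XX + pc))` on genotype-mean
#' normalized expression; classes follow the fixed boundaries: `high`
#' when log2FC >= 3, `medium` when 1 < log2FC < 3, `none` when
#' log2FC <= 1. When a `de_result` is supplied, the XXvsXY p-values of
#' these genes are BH-adjusted over the Y-gene subset and attached.
#'
#' @param norm A `norm_matrix` with annotation.
#' @param de Optional `de_result` for FDR annotation.
#' @param pseudocount Stabilizer (default 0.5 normalized units).
#' @return `data.frame`: `feature_id`, `chromosome`, `start_bp`,
#'   `log2FC`, `class`, `fdr` (NA without `de`).
#' @export
classify_y_genes <- function(norm, de = NULL, pseudocount = 0.5) {
  ann <- norm$annotation
  yg <- ann$feature_id[ann$feature_class %in% c("y_linked", "par_y")]
  if (length(yg) == 0L) stop_arg("annotation contains no Y-linked features")
  gm <- genotype_means(norm)
  lfc <- log2((gm[yg, "XY"] + pseudocount) / (gm[yg, "XX"] + pseudocount))
  cls <- ifelse(lfc >= 3, "high", ifelse(lfc > 1, "medium", "none"))
  fdr <- rep(NA_real_, length(yg))
  if (!is.null(de)) {
    sub <- de[de$contrast == "XXvsXY" & de$feature_id %in% yg, ]
    fdr <- bh_fdr(sub$p)[match(yg, sub$feature_id)]
  }
  idx <- match(yg, ann$feature_id)
  data.frame(feature_id = yg, chromosome = ann$chromosome[idx],
             start_bp = ann$start_bp[idx], log2FC = lfc, class = cls,
             fdr = fdr, stringsAsFactors = FALSE, row.names = NULL)
}

#' Homolog-group expression summaries and X+Y sums
#'
#' Per homolog group, per member, per genotype: the geometric mean of the
#' replicate normalized values (pseudocount-shifted logs, so zero
#' replicates are defined; equal replicates are reproduced exactly) with
#' its lognormal one-SD multiplicative interval. The SD of logs uses the
#' population (1/n) convention so that replicates (2, 8) yield geometric
#' mean 4 with interval (2, 8). The group "sum" per
#' genotype adds the member geometric means; Y members contribute zero in
#' XX and XO.
#'
#' @param norm A `norm_matrix` with annotation and samples.
#' @param groups Optional character vector of homolog group ids (default
#'   all groups in the annotation).
#' @param pseudocount Log shift (default 0.5 normalized units).
#' @return List of class `homolog_summary` with one element per group:
#'   `members` (`data.frame`: feature, genotype, geometric mean, sdlog,
#'   interval) and `sum` (named by genotype).
#' @export
homolog_sum <- function(norm, groups = NULL, pseudocount = 0.5) {
  ann <- norm$annotation
  avail <- unique(ann$homolog_group[!is.na(ann$homolog_group)])
  if (is.null(groups)) groups <- sort(avail)
  if (!all(groups %in% avail)) {
    stop_arg(sprintf("unknown homolog group(s): %s",
                     paste(setdiff(groups, avail), collapse = ", ")))
  }
  out <- lapply(stats::setNames(groups, groups), function(grp) {
    members <- ann$feature_id[!is.na(ann$homolog_group) &
                                ann$homolog_group == grp]
    rows <- list()
    sums <- stats::setNames(numeric(3), genotype_levels())
    for (f in members) {
      for (g in genotype_levels()) {
        cols <- norm$samples$sample_id[norm$samples$genotype == g]
        v <- as.numeric(norm$normalized[f, cols])
        lg <- log(v + pseudocount)
        gmv <- exp(mean(lg)) - pseudocount
        gmv <- max(gmv, 0)
        sdl <- sqrt(mean((lg - mean(lg))^2))
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = f, genotype = g, geometric_mean = gmv, sdlog = sdl,
          lo = max(exp(mean(lg) - sdl) - pseudocount, 0),
          hi = max(exp(mean(lg) + sdl) - pseudocount, 0),
          stringsAsFactors = FALSE)
        sums[g] <- sums[g] + gmv
      }
    }
    members_df <- do.call(rbind, rows)
    rownames(members_df) <- NULL
    list(members = members_df, sum = sums)
  })
  structure(out, class = "homolog_summary")
}
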