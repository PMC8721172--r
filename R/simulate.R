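# Genotype-specific true expression, UMI count matrices, and tagged reads.
#
# The noise model is Poisson-lognormal: molecule counts are
# Poisson(mean * lib * exp(eps)) with gene-wise multiplicative biological
# noise eps ~ N(0, sdlog^2) shared within a sample, and lib a per-sample
# capture/library factor. Spike-ins carry no biological noise (sdlog = 0),
# which is what makes them usable as an absolute normalization anchor and
# lets tests separate technical from biological variance.

#' Sample metadata for the standard three-genotype design
#'
#' @param replicates Biological replicates per genotype (default 3,
#'   matching a triplicate design).
#' @param batches Optional character vector of batch labels recycled over
#'   samples; default a single batch.
#' @return `data.frame` with `sample_id`, `genotype`, `replicate`, `batch`.
#' @export
make_samples <- function(replicates = 3, batches = "b1") {
  replicates <- check_count(replicates, "replicates", min = 1L)
  geno <- rep(genotype_levels(), each = replicates)
  rep_i <- rep(seq_len(replicates), times = 3)
  data.frame(
    sample_id = paste0(geno, rep_i),
    genotype = geno,
    replicate = rep_i,
    batch = rep_len(batches, length(geno)),
    stringsAsFactors = FALSE)
}

#' Simulation parameter defaults
#'
#' The defaults encode the emulated study conditions: per-allele
#' transcription gives an X-dosage ratio of 0.5; baseline expression is
#' lognormal over more than four orders of magnitude so that six
#' expression bins are non-degenerate; spike-ins target ~4.5% of total
#' reads (middle of the 3-6% design band).
#'
#' @param rho True dosage ratio for X-dosage-dependent genes (XO and XY
#'   mean relative to XX), in (0, 1].
#' @param sdlog_bio Biological lognormal noise (sdlog) for genes; spikes
#'   always use 0.
#' @param sdlog_lib Spread of per-sample library/capture factors.
#' @param meanlog_expr,sdlog_expr Baseline lognormal expression
#'   distribution (molecules per sample).
#' @param spike_fraction Target fraction of molecules that are spike-ins.
#' @param batch_effect Multiplicative log2 shift applied to a random 30%
#'   of genes in non-reference batches (0 disables).
#' @return Named list of parameters.
#' @export
sim_params <- function(rho = 0.5, sdlog_bio = 0.2, sdlog_lib = 0.15,
                       meanlog_expr = log(3), sdlog_expr = 2.3,
                       spike_fraction = 0.045, batch_effect = 0) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1) {
    stop_arg("'rho' must be in (0, 1]")
  }
  stopifnot(sdlog_bio >= 0, sdlog_lib >= 0, sdlog_expr > 0,
            spike_fraction > 0, spike_fraction < 1)
  list(rho = rho, sdlog_bio = sdlog_bio, sdlog_lib = sdlog_lib,
       meanlog_expr = meanlog_expr, sdlog_expr = sdlog_expr,
       spike_fraction = spike_fraction, batch_effect = batch_effect)
}

#' Simulate genotype-specific true mean expression
#'
#' Draws a baseline mean per gene and applies the truth-class rules
#' exactly: dosage-dependent X genes have XO = XY = rho * XX; compensated
#' genes are equal across genotypes; Y-linked classes are zero in XX and
#' XO; PAR genes are elevated in XY; spikes are equal across genotypes
#' with total abundance set so spike molecules are `spike_fraction` of
#' all molecules.
#'
#' @param annotation From [make_annotation()].
#' @param params From [sim_params()].
#' @param seed Integer seed.
#' @return `data.frame` with `feature_id` and true mean molecule columns
#'   `mean_XX`, `mean_XO`, `mean_XY`; `params` kept as an attribute.
#' @export
simulate_truth <- function(annotation, params = sim_params(), seed = 1L) {
  validate_annotation(annotation)
  if (params$rho <= 0) stop_arg("'rho' must be positive")
  n <- nrow(annotation)
  with_seed(seed, {
    base <- stats::rlnorm(n, params$meanlog_expr, params$sdlog_expr)
    m <- matrix(0, n, 3, dimnames = list(annotation$feature_id,
                                         genotype_levels()))
    cls <- annotation$truth_class
    for (g in genotype_levels()) m[, g] <- base
    dd <- cls == "dosage_dependent"
    m[dd, "XO"] <- params$rho * base[dd]
    m[dd, "XY"] <- params$rho * base[dd]
    # compensated / neutral: equal across genotypes (already set)
    yh <- cls == "y_high"; ym <- cls == "y_medium"; ys <- cls == "y_silent"
    m[yh | ym | ys, c("XX", "XO")] <- 0
    m[yh, "XY"] <- stats::rlnorm(sum(yh), log(100), 0.5)
    m[ym, "XY"] <- stats::rlnorm(sum(ym), log(1.5), 0.3)
    m[ys, "XY"] <- 0
    par_x <- annotation$feature_class == "par_x"
    par_y <- annotation$feature_class == "par_y"
    m[par_x, "XY"] <- 1.5 * base[par_x]
    m[par_y, c("XX", "XO")] <- 0
    m[par_y, "XY"] <- stats::rlnorm(sum(par_y), log(20), 0.5)

    sp <- cls == "spike"
    if (any(sp)) {
      # relative Mix-1-like abundances over ~4 logs, scaled to the target
      # molecule fraction of the genotype-averaged gene total
      rel <- stats::rlnorm(sum(sp), 0, 1.5)
      gene_total <- mean(colSums(m[!sp, , drop = FALSE]))
      tot_spike <- params$spike_fraction / (1 - params$spike_fraction) * gene_total
      sp_mean <- rel / sum(rel) * tot_spike
      for (g in genotype_levels()) m[sp, g] <- sp_mean
    }
    out <- data.frame(feature_id = annotation$feature_id,
                      mean_XX = m[, "XX"], mean_XO = m[, "XO"],
                      mean_XY = m[, "XY"], stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "params") <- params
    out
  })
}

#' Spike design table implied by a truth table
#'
#' Converts the simulated true spike molecule counts back to nominal
#' attomoles per sample, i.e. the table an experimenter would supply for
#' size-factor estimation. Synthetic stand-in for the commercial Mix 1
#' concentration sheet.
#'
#' @param annotation,truth Matching annotation and truth tables.
#' @return `data.frame` with `spike_id`, `attomoles`, `expected_molecules`.
#' @export
spike_design_from_truth <- function(annotation, truth) {
  sp <- annotation$feature_class == "spike"
  if (!any(sp)) stop_arg("annotation contains no spike features")
  mol <- truth$mean_XX[match(annotation$feature_id[sp], truth$feature_id)]
  data.frame(spike_id = annotation$feature_id[sp],
             attomoles = mol / 6.02214076e23 / 1e-18,
             expected_molecules = mol,
             stringsAsFactors = FALSE)
}

#' Simulate a UMI count matrix from true means
#'
#' count(g, s) ~ Poisson(mean_{g,genotype(s)} * lib_s * exp(eps_{g,s})),
#' eps ~ N(0, sdlog_bio^2); spikes use sdlog 0. An optional batch effect
#' multiplies a fixed random 30% of genes by 2^batch_effect in every
#' batch other than the first.
#'
#' @param truth From [simulate_truth()].
#' @param samples From [make_samples()]; needs >= 1 sample per genotype.
#' @param params From [sim_params()] (noise and batch settings).
#' @param annotation Annotation (identifies spike rows).
#' @param seed Integer seed.
#' @param poisson Set `FALSE` to skip Poisson sampling (debug; counts are
#'   rounded means after noise).
#' @return List with integer matrix `counts` (features x samples), the
#'   true per-sample `lib_factors`, `samples`, and `batch_genes`.
#' @export
simulate_counts <- function(truth, samples, params = sim_params(),
                            annotation = NULL, seed = 1L, poisson = TRUE) {
  stopifnot(all(genotype_levels() %in% samples$genotype))
  n <- nrow(truth)
  ns <- nrow(samples)
  spike <- if (!is.null(annotation)) {
    annotation$feature_class[match(truth$feature_id, annotation$feature_id)] == "spike"
  } else rep(FALSE, n)
  with_seed(seed, {
    lib <- if (params$sdlog_lib > 0) stats::rlnorm(ns, 0, params$sdlog_lib) else rep(1, ns)
    lib <- lib / geomean(lib)
    batch_genes <- integer(0)
    if (params$batch_effect != 0) {
      batch_genes <- sort(sample(which(!spike), round(0.3 * sum(!spike))))
    }
    counts <- matrix(0L, n, ns,
                     dimnames = list(truth$feature_id, samples$sample_id))
    mean_cols <- paste0("mean_", samples$genotype)
    ref_batch <- samples$batch[1]
    for (s in seq_len(ns)) {
      mu <- truth[[mean_cols[s]]]
      eps <- rep(0, n)
      if (params$sdlog_bio > 0) {
        eps[!spike] <- stats::rnorm(sum(!spike), 0, params$sdlog_bio)
      }
      lam <- mu * lib[s] * exp(eps)
      if (length(batch_genes) && samples$batch[s] != ref_batch) {
        lam[batch_genes] <- lam[batch_genes] * 2^params$batch_effect
      }
      counts[, s] <- if (poisson) stats::rpois(n, lam) else as.integer(round(lam))
    }
    list(counts = counts, lib_factors = stats::setNames(lib, samples$sample_id),
         samples = samples, batch_genes = truth$feature_id[batch_genes])
  })
}

#' Simulate tagged 5' reads from a count matrix
#'
#' Each molecule receives a UMI drawn uniformly from the 4^12 12-mers and
#' one tagged 5' read laid out as anchor + UMI + post-UMI bases + G-stretch
#' + cDNA. Every gene has one fixed cDNA sequence (drawn once per call),
#' so reads from the same gene share sequence, as aligned reads do.
#' Untagged internal reads (no tag, no UMI, the gene's internal sequence)
#' are added so that they make up `untagged_fraction` of all reads.
#' Substitution errors are applied independently per base at
#' `error_rate`.
#'
#' @param sim From [simulate_counts()] (or any list with `counts` and
#'   `samples`).
#' @param pattern From [tag_pattern()].
#' @param error_rate,untagged_fraction Probabilities in `[0, 1)`.
#' @param read_length Output read length in bases.
#' @param seed Integer seed.
#' @return List with `reads` (`data.frame`: `read_id`, `sample_id`,
#'   `sequence`, `quality`), `truth` (`read_id`, `sample_id`,
#'   `truth_gene`, `truth_umi`; `truth_umi` is `NA` for untagged reads),
#'   and `umi_counts`, the realized distinct-(gene, UMI) matrix per
#'   sample. UMI collisions are allowed (uniform over the 4^12 12-mers)
#'   and not corrected, so `umi_counts` can fall below the molecule
#'   matrix by the handful of collisions; it is the exact ground truth
#'   for deduplicated counting.
#' @export
simulate_reads <- function(sim, pattern = tag_pattern(), error_rate = 0.001,
                           untagged_fraction = 0.5, read_length = 150,
                           seed = 1L) {
  check_prob(error_rate, "error_rate", open_hi = TRUE)
  check_prob(untagged_fraction, "untagged_fraction", open_hi = TRUE)
  counts <- sim$counts
  samples <- sim$samples
  with_seed(seed, {
    prefix_len <- nchar(pattern$anchor) + pattern$umi_length +
      nchar(pattern$post_umi) + pattern$min_g_stretch + 1L
    cdna <- stats::setNames(random_dna(nrow(counts),
                                       read_length - prefix_len),
                            rownames(counts))
    internal <- stats::setNames(random_dna(nrow(counts), read_length),
                                rownames(counts))
    res <- vector("list", nrow(samples))
    for (s in seq_len(nrow(samples))) {
      cs <- counts[, s]
      genes <- rep(rownames(counts), cs)
      n_mol <- length(genes)
      umi <- random_umis(n_mol, pattern$umi_length)
      tagged <- paste0(pattern$anchor, umi, pattern$post_umi,
                       strrep("G", pattern$min_g_stretch + 1L),
                       cdna[genes])
      n_untag <- if (untagged_fraction > 0) {
        round(n_mol * untagged_fraction / (1 - untagged_fraction))
      } else 0L
      untag_genes <- if (n_untag > 0 && n_mol > 0) {
        sample(genes, n_untag, replace = TRUE)
      } else character()
      untagged <- unname(internal[untag_genes])
      seqs <- c(tagged, untagged)
      seqs <- apply_seq_errors(seqs, error_rate)
      ids <- sprintf("%s:%07d", samples$sample_id[s], seq_along(seqs))
      res[[s]] <- data.frame(
        read_id = ids,
        sample_id = samples$sample_id[s],
        sequence = seqs,
        quality = strrep("I", nchar(seqs)),
        truth_gene = c(genes, untag_genes),
        truth_umi = c(umi, rep(NA_character_, n_untag)),
        stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, res)
    rownames(all) <- NULL
    tagged <- !is.na(all$truth_umi)
    key <- paste(all$truth_gene[tagged], all$sample_id[tagged],
                 all$truth_umi[tagged], sep = "\r")
    first <- !duplicated(key)
    umi_counts <- matrix(0L, nrow(counts), ncol(counts),
                         dimnames = dimnames(counts))
    if (any(first)) {
      tab <- table(factor(all$truth_gene[tagged][first],
                          levels = rownames(counts)),
                   factor(all$sample_id[tagged][first],
                          levels = colnames(counts)))
      umi_counts[] <- as.integer(tab)
    }
    list(reads = all[c("read_id", "sample_id", "sequence", "quality")],
         truth = all[c("read_id", "sample_id", "truth_gene", "truth_umi")],
         umi_counts = umi_counts)
  })
}

# Uniform random k-mers encoded from integers for speed.
random_umis <- function(n, k) {
  if (n == 0L) return(character())
  mat <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  if (len <= 0L) return(rep("", n))
  mat <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# Per-base substitution errors, vectorized: the number of errors per read
# is Binomial(len, rate); each error replaces the base with one of the
# other three.
apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), len, rate)
  mx <- max(nerr)
  if (mx == 0L) return(seqs)
  for (r in seq_len(mx)) {
    idx <- which(nerr >= r)
    pos <- 1L + floor(stats::runif(length(idx)) * len[idx])
    orig <- substring(seqs[idx], pos, pos)
    bases <- c("A", "C", "G", "T")
    oi <- match(orig, bases)
    oi[is.na(oi)] <- 1L  # N or other: overwrite with any base
    shift <- sample.int(3L, length(idx), replace = TRUE)
    repl <- bases[((oi - 1L + shift) %% 4L) + 1L]
    s <- seqs[idx]
    substring(s, pos, pos) <- repl
    seqs[idx] <- s
  }
  seqs
}

#' Write reads to a FASTQ file
#'
#' @param reads `data.frame` with `read_id`, `sequence`, `quality`.
#' @param path Output path (plain text, 4-line records).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  rec <- paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", reads$quality)
  writeLines(rec, path)
  invisible(path)
}

#' Read a 4-line-record FASTQ file
#'
#' @param path FASTQ path.
#' @return `data.frame` with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L) stop_arg("malformed FASTQ: length not multiple of 4")
  i <- seq(1L, length(ln), by = 4L)
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", ln[i])),
             sequence = ln[i + 1L], quality = ln[i + 3L],
             stringsAsFactors = FALSE)
}
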