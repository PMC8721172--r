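# Shared fixtures and independent oracles, built in code at test time.

# Small simulated data set used by several files; computed once per run.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ann <- make_annotation(300, 60, 20, 6, 20, seed = 1)
      params <- sim_params()
      truth <- simulate_truth(ann, params, seed = 2)
      samples <- make_samples()
      sim <- simulate_counts(truth, samples, params, annotation = ann,
                             seed = 3)
      spikes <- spike_design_from_truth(ann, truth)
      sf <- size_factors(sim$counts, spikes)
      norm <- normalize_counts(sim$counts, sf, samples = samples,
                               annotation = ann)
      cache <<- list(ann = ann, params = params, truth = truth,
                     samples = samples, sim = sim, spikes = spikes,
                     sf = sf, norm = norm)
    }
    cache
  }
})

# Wrap a bare expression matrix (already normalized units) as a
# norm_matrix for the dosage statistics.
as_norm <- function(values, annotation = NULL, samples = NULL) {
  normalize_counts(values, rep(1, ncol(values)), samples = samples,
                   annotation = annotation)
}

# Minimal annotation for matrices built by hand.
bare_annotation <- function(feature_ids, feature_class,
                            chromosome = NULL, start_bp = NULL) {
  data.frame(feature_id = feature_ids,
             chromosome = if (is.null(chromosome)) {
               ifelse(feature_class %in% c("x_linked", "par_x"), "X",
                      ifelse(feature_class %in% c("y_linked", "par_y"), "Y",
                             ifelse(feature_class == "spike", "ERCC", "1")))
             } else chromosome,
             start_bp = if (is.null(start_bp)) seq_along(feature_ids) else start_bp,
             feature_class = feature_class,
             truth_class = "neutral",
             homolog_group = NA_character_,
             stringsAsFactors = FALSE)
}

# Samples table for matrices built by hand (equal replicates, column
# order XX1..XO1..XY1..).
bare_samples <- function(replicates = 3) make_samples(replicates)

# Brute-force tag extraction oracle: enumerate every anchor placement and
# accept the smallest offset whose full layout is valid.
bf_extract_one <- function(seq, pat) {
  chars <- strsplit(seq, "")[[1]]
  a <- strsplit(pat$anchor, "")[[1]]
  alen <- length(a)
  for (off in 0:pat$max_start_offset) {
    need <- off + alen + pat$umi_length + nchar(pat$post_umi) +
      pat$min_g_stretch
    if (length(chars) < need) next
    mm <- sum(chars[(off + 1):(off + alen)] != a)
    if (mm > pat$allowed_mismatches_in_anchor) next
    umi <- paste(chars[(off + alen + 1):(off + alen + pat$umi_length)],
                 collapse = "")
    if (grepl("N", umi, fixed = TRUE)) next
    ps <- off + alen + pat$umi_length + 1
    post <- paste(chars[ps:(ps + nchar(pat$post_umi) - 1)], collapse = "")
    if (post != pat$post_umi) next
    gs <- ps + nchar(pat$post_umi)
    g_run <- 0
    while (gs + g_run <= length(chars) && chars[gs + g_run] == "G") {
      g_run <- g_run + 1
    }
    if (g_run < pat$min_g_stretch) next
    return(list(matched = TRUE, umi = umi, cdna_start = gs + g_run))
  }
  list(matched = FALSE, umi = NA_character_, cdna_start = NA_integer_)
}

random_reads <- function(n, len = 60, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(0.24, 0.24, 0.28, 0.23, 0.01)), collapse = "")
  }, character(1))
}

# Reads that exercise tag matching: valid layouts with random offsets and
# anchor mismatches, plus pure-random decoys.
tagged_test_reads <- function(n, pat = tag_pattern(), seed = 1) {
  set.seed(seed)
  mk <- function() {
    off <- sample(0:(pat$max_start_offset + 1), 1)  # sometimes too far
    anchor <- strsplit(pat$anchor, "")[[1]]
    nmm <- sample(0:(pat$allowed_mismatches_in_anchor + 1), 1,
                  prob = c(0.5, 0.35, 0.15))
    if (nmm > 0) {
      pos <- sample(length(anchor), nmm)
      for (p in pos) anchor[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 anchor[p]), 1)
    }
    umi <- paste(sample(c("A", "C", "G", "T", "N"), pat$umi_length,
                        replace = TRUE, prob = c(rep(0.2425, 4), 0.03)),
                 collapse = "")
    g <- strrep("G", sample(c(pat$min_g_stretch - 1, pat$min_g_stretch,
                              pat$min_g_stretch + 2), 1))
    paste0(paste(sample(c("A", "C", "T"), off, replace = TRUE), collapse = ""),
           paste(anchor, collapse = ""), umi, pat$post_umi, g,
           paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = ""))
  }
  c(vapply(seq_len(ceiling(n * 0.7)), function(i) mk(), character(1)),
    random_reads(floor(n * 0.3), seed = seed + 1))
}

# Brute-force Venn oracle: classify each universe member by direct
# membership tests.
bf_venn_cells <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  pat <- vapply(universe, function(g) {
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = "")
  }, character(1))
  split(universe, factor(pat, levels = apply(
    expand.grid(rep(list(0:1), 4))[, 4:1], 1, paste, collapse = "")))
}
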