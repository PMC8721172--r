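# End-to-end orchestration: generate -> demux -> normalize -> de ->
# dosage, with one config, per-stage seeds, and deterministic artifacts.

#' Default pipeline configuration
#'
#' All tunables of every stage with the emulated study design as
#' defaults: 5,000 genes plus 92 spike-ins, three genotypes in biological
#' triplicate, 6 expression bins, bootstrap resample size 100 with 5,000
#' repetitions, DEG selection at p < 0.05.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param simulate_reads If `TRUE`, go through FASTQ simulation and UMI
#'   demultiplexing; otherwise the simulated count matrix is used
#'   directly.
#' @param ... Overrides for any config entry.
#' @return Named list (class `run_config`).
#' @export
default_config <- function(out_dir = tempfile("oodosage_run_"), seed = 1L,
                           simulate_reads = TRUE, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate_reads = simulate_reads,
    n_autosomal = 4470, n_x = 450, n_y = 60, n_par = 20, n_spikes = 92,
    replicates = 3,
    rho = 0.5, sdlog_bio = 0.2, sdlog_lib = 0.15,
    meanlog_expr = log(3), sdlog_expr = 2.3,
    spike_fraction = 0.045, batch_effect = 0,
    error_rate = 0.001, untagged_fraction = 0.5, read_length = 150,
    pseudocount = 1, ratio_pseudocount = 0.5,
    alpha = 0.05, lfc_min = 0, k_surrogates = 0,
    n_bins = 6, resample_size = 100, bootstrap_reps = 5000,
    top_n = 500,
    # per-stage seed overrides; NULL derives them from the master seed
    seed_simulate = NULL, seed_reads = NULL, seed_bootstrap = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_arg(sprintf("unknown config entries: %s",
                     paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML path.
#' @param config A `run_config`.
#' @return `read_config()` returns a `run_config`; `write_config()` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

config_hash <- function(config) {
  # identifies the analysis, not its location: output path excluded
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic analysis pipeline
#'
#' Stages, in dependency order: synthetic annotation/truth/counts
#' (optionally through FASTQ and UMI demultiplexing), ERCC normalization
#' with PCA and Spearman-distance QC, differential expression with the
#' 4-list Venn partition (X-linked and autosomal universes separately),
#' and the dosage statistics (X-dosage ratio fit of the red-category
#' genes, binned X:A bootstrap, bin-6 genotype-ratio bootstrap, Y-gene
#' classification, homolog sums). Every artifact is written as TSV/JSON
#' under `config$out_dir` and indexed in `report.json` with the config
#' hash; reruns with an identical config are byte-identical.
#'
#' @param config From [default_config()] or [read_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%6.1fs] %s", proc.time()[["elapsed"]] - t0,
                                sprintf(fmt, ...)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6)
  if (!is.null(config$seed_simulate)) seeds[1:3] <- config$seed_simulate + 0:2
  if (!is.null(config$seed_reads)) seeds[4] <- config$seed_reads
  if (!is.null(config$seed_bootstrap)) seeds[5:6] <- config$seed_bootstrap + 0:1

  say("simulate: annotation, truth, counts")
  ann <- make_annotation(config$n_autosomal, config$n_x, config$n_y,
                         config$n_par, config$n_spikes, seed = seeds[1])
  params <- sim_params(rho = config$rho, sdlog_bio = config$sdlog_bio,
                       sdlog_lib = config$sdlog_lib,
                       meanlog_expr = config$meanlog_expr,
                       sdlog_expr = config$sdlog_expr,
                       spike_fraction = config$spike_fraction,
                       batch_effect = config$batch_effect)
  truth <- simulate_truth(ann, params, seed = seeds[2])
  samples <- make_samples(config$replicates)
  sim <- simulate_counts(truth, samples, params, annotation = ann,
                         seed = seeds[3])
  spikes <- spike_design_from_truth(ann, truth)
  write_annotation(ann, file.path(config$out_dir, "annotation.tsv"))
  utils::write.table(samples, file.path(config$out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(spikes, file.path(config$out_dir, "spikes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (config$simulate_reads) {
    say("simulate: tagged reads (%d molecules)", sum(sim$counts))
    rd <- simulate_reads(sim, tag_pattern(),
                         error_rate = config$error_rate,
                         untagged_fraction = config$untagged_fraction,
                         read_length = config$read_length, seed = seeds[4])
    say("demux: extracting UMIs from %d reads", nrow(rd$reads))
    uc <- count_umis(rd$reads, rd$truth, samples,
                     features = ann$feature_id)
    counts <- uc$counts
    qc_demux <- uc$qc
  } else {
    counts <- sim$counts
    qc_demux <- NULL
  }
  write_counts(counts, file.path(config$out_dir, "counts.tsv"))

  say("normalize: ERCC size factors + QC")
  sf <- size_factors(counts, spikes)
  norm <- normalize_counts(counts, sf, pseudocount = config$pseudocount,
                           samples = samples, annotation = ann)
  top <- top_variable_genes(norm$log2, min(config$top_n, nrow(norm$log2)))
  qc <- list(size_factors = as.list(sf),
             spearman_distance = as.data.frame(spearman_distance(norm$log2, top)),
             pca_variance_explained = pca_qc(norm$log2)$variance_explained)
  write_norm_tsv(norm, file.path(config$out_dir, "normalized.tsv"))

  say("de: linear models + Venn partition")
  gene_rows <- ann$feature_class != "spike"
  lm_mat <- norm$log2[ann$feature_id[gene_rows], , drop = FALSE]
  design0 <- design_matrix(samples)
  sv <- if (config$k_surrogates > 0) {
    estimate_surrogates(lm_mat, design0, config$k_surrogates)
  } else NULL
  design <- design_matrix(samples, sv)
  de <- moderate(fit_models(lm_mat, design))
  write_de_tsv(de, file.path(config$out_dir, "de.tsv"))
  lists <- deg_lists(de, alpha = config$alpha, lfc_min = config$lfc_min)
  x_ids <- ann$feature_id[ann$feature_class %in% c("x_linked", "par_x")]
  a_ids <- ann$feature_id[ann$feature_class == "autosomal"]
  venn_sets <- function(ids) {
    lapply(lists[c("XX>XO", "XX>XY", "XY>XO", "XY<XO")], intersect, x = ids)
  }
  venn_x <- venn_partition(venn_sets(x_ids))
  venn_a <- venn_partition(venn_sets(a_ids))
  write_json_file(list(x_linked = venn_json(venn_x),
                       autosomal = venn_json(venn_a)),
                  file.path(config$out_dir, "venn.json"))

  say("dosage: ratio fit, X:A bootstrap, Y classes, homolog sums")
  red <- venn_x$categories$red
  fit_red <- if (length(red)) {
    ratio_fit(norm, red, "pooled", pseudocount = config$ratio_pseudocount)
  } else NULL
  bins <- assign_bins(xa_universe_means(norm), config$n_bins)
  boot <- xa_bootstrap(norm, bins, config$resample_size,
                       config$bootstrap_reps, seed = seeds[5])
  boot6 <- bin6_genotype_ratio_bootstrap(norm, bins,
                                         resample_size = config$resample_size,
                                         reps = config$bootstrap_reps,
                                         seed = seeds[6])
  ycls <- classify_y_genes(norm, de, pseudocount = config$ratio_pseudocount)
  hom <- homolog_sum(norm, pseudocount = config$ratio_pseudocount)
  utils::write.table(format_num_df(bootstrap_stats(boot)),
                     file.path(config$out_dir, "xa_bootstrap_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format_num_df(bootstrap_stats(boot6)),
                     file.path(config$out_dir, "bin6_bootstrap_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format_num_df(ycls),
                     file.path(config$out_dir, "y_gene_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dosage_json <- list(
    red_ratio_fit = if (is.null(fit_red)) NULL else ratio_fit_json(fit_red),
    homolog_sums = lapply(hom, function(h) as.list(h$sum)))
  write_json_file(dosage_json, file.path(config$out_dir, "dosage.json"))

  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    stage_seeds = as.integer(seeds),
    n_features = nrow(ann),
    demux_qc = qc_demux,
    qc = list(pca_variance_explained = qc$pca_variance_explained,
              size_factors = qc$size_factors),
    deg_counts = lapply(lists, length),
    venn_category_counts = list(
      x_linked = as.list(venn_x$category_counts),
      autosomal = as.list(venn_a$category_counts)),
    artifacts = list.files(config$out_dir))
  write_json_file(report, file.path(config$out_dir, "report.json"))
  say("done")

  invisible(list(annotation = ann, truth = truth, sim = sim,
                 spikes = spikes, counts = counts, norm = norm, qc = qc,
                 de = de, deg_lists = lists, venn_x = venn_x,
                 venn_a = venn_a, ratio_fit_red = fit_red, bins = bins,
                 xa_bootstrap = boot, bin6_bootstrap = boot6,
                 y_classes = ycls, homolog = hom, report = report))
}

validate_config <- function(config) {
  check_prob(config$error_rate, "error_rate", open_hi = TRUE)
  check_prob(config$untagged_fraction, "untagged_fraction", open_hi = TRUE)
  if (config$n_spikes < 8) stop_arg("need >= 8 spike-ins for size factors")
  if (config$rho <= 0 || config$rho > 1) stop_arg("'rho' must be in (0, 1]")
  if (config$n_bins < 1) stop_arg("'n_bins' must be >= 1")
  invisible(TRUE)
}

write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an annotation TSV
#'
#' @param path TSV with the [make_annotation()] columns.
#' @return Annotation `data.frame` (empty `homolog_group` becomes `NA`).
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chromosome = "character"))
  ann$homolog_group[!is.na(ann$homolog_group) & ann$homolog_group == ""] <-
    NA_character_
  ann
}

write_norm_tsv <- function(norm, path) {
  df <- data.frame(feature_id = rownames(norm$normalized),
                   format(norm$normalized, digits = 10, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_de_tsv <- function(de, path) {
  utils::write.table(format_num_df(as.data.frame(de)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Format numeric columns with fixed significant digits so TSV output is
# byte-stable across platforms.
format_num_df <- function(df, digits = 10) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
    }
  }
  df
}

venn_json <- function(v) {
  list(cell_counts = as.list(v$cell_counts),
       category_counts = as.list(v$category_counts),
       categories = v$categories)
}

ratio_fit_json <- function(fit) {
  list(n = fit$n, geometric_mean = fit$geometric_mean, sdlog = fit$sdlog,
       mult_sd_interval = fit$mult_sd_interval, ci_mean = fit$ci_mean,
       numerator = fit$numerator)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
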