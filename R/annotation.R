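# Synthetic gene annotation: chromosomes, positions, truth classes,
# homolog groups. This is the ground-truth backbone every downstream
# stage is tested against.

#' Default truth-class fractions per feature class
#'
#' X-linked genes are split evenly between X-dosage-dependent and
#' dosage-compensated behaviour (the two regimes observed in growing
#' oocytes); Y-linked genes fall into highly transcribed, medium
#' (repetitive-sequence) and silenced groups; autosomes are neutral.
#'
#' @return Named list of named numeric vectors, one per feature class.
#' @export
default_class_fractions <- function() {
  list(
    autosomal = c(neutral = 1),
    x_linked  = c(dosage_dependent = 0.5, compensated = 0.5),
    y_linked  = c(y_high = 0.3, y_medium = 0.4, y_silent = 0.3)
  )
}

#' Generate a synthetic gene annotation table
#'
#' Builds the feature universe used by the simulator: autosomal genes
#' spread over chromosomes 1-19, X-linked genes, Y-linked genes,
#' pseudoautosomal (PAR) gene pairs with one copy on X and one on Y, and
#' ERCC spike-in features. Start positions are strictly increasing within
#' each chromosome and PAR-Y features are placed distal to every Y-linked
#' gene. A subset of X and Y genes is grouped into X/Y homolog pairs for
#' homolog-sum comparisons.
#'
#' @param n_autosomal,n_x,n_y,n_spikes Feature counts per class.
#' @param n_par Total number of PAR features; paired two at a time
#'   (one `par_x` + one `par_y` per PAR gene), with an odd remainder
#'   becoming an unpaired `par_x` feature.
#' @param class_fractions Named list as [default_class_fractions()];
#'   fractions within each feature class must sum to 1.
#' @param n_homolog_pairs Number of X/Y homolog groups to form from
#'   non-PAR X- and Y-linked genes.
#' @param seed Integer seed; the table is deterministic given the seed.
#' @return A `data.frame` with columns `feature_id`, `chromosome`,
#'   `start_bp`, `feature_class`, `truth_class`, `homolog_group`.
#' @export
make_annotation <- function(n_autosomal = 4470, n_x = 450, n_y = 60,
                            n_par = 20, n_spikes = 92,
                            class_fractions = default_class_fractions(),
                            n_homolog_pairs = 3, seed = 1L) {
  n_autosomal <- check_count(n_autosomal, "n_autosomal")
  n_x <- check_count(n_x, "n_x")
  n_y <- check_count(n_y, "n_y")
  n_par <- check_count(n_par, "n_par")
  n_spikes <- check_count(n_spikes, "n_spikes")
  for (cls in names(class_fractions)) {
    fr <- class_fractions[[cls]]
    if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
      stop_arg(sprintf("class fractions for '%s' must be >= 0 and sum to 1", cls))
    }
  }

  with_seed(seed, {
    rows <- list()

    # Autosomes: round-robin over chromosomes 1..19, sorted positions.
    if (n_autosomal > 0) {
      chr <- sort(rep_len(as.character(1:19), n_autosomal))
      pos <- unlist(lapply(split(seq_len(n_autosomal), chr), function(i) {
        sort(sample.int(2e8, length(i)))
      }), use.names = FALSE)
      chr <- unlist(split(chr, chr), use.names = FALSE)
      rows$auto <- data.frame(
        feature_id = sprintf("gA%04d", seq_len(n_autosomal)),
        chromosome = chr, start_bp = pos,
        feature_class = "autosomal",
        truth_class = assign_classes(n_autosomal, class_fractions$autosomal),
        homolog_group = NA_character_, stringsAsFactors = FALSE)
    }

    if (n_x > 0) {
      rows$x <- data.frame(
        feature_id = sprintf("gX%04d", seq_len(n_x)),
        chromosome = "X", start_bp = sort(sample.int(165e6, n_x)),
        feature_class = "x_linked",
        truth_class = assign_classes(n_x, class_fractions$x_linked),
        homolog_group = NA_character_, stringsAsFactors = FALSE)
    }

    # Y: y_linked genes first, PAR-Y strictly distal to all of them.
    y_max <- 0L
    if (n_y > 0) {
      ypos <- sort(sample.int(80e6, n_y))
      y_max <- max(ypos)
      rows$y <- data.frame(
        feature_id = sprintf("gY%04d", seq_len(n_y)),
        chromosome = "Y", start_bp = ypos,
        feature_class = "y_linked",
        truth_class = assign_classes(n_y, class_fractions$y_linked),
        homolog_group = NA_character_, stringsAsFactors = FALSE)
    }

    if (n_par > 0) {
      n_pairs <- n_par %/% 2L
      n_extra_x <- n_par %% 2L
      grp <- if (n_pairs > 0) sprintf("PAR%02d", seq_len(n_pairs)) else character()
      par_x <- data.frame(
        feature_id = sprintf("gPARX%02d", seq_len(n_pairs + n_extra_x)),
        chromosome = "X",
        start_bp = sort(sample.int(3e6, n_pairs + n_extra_x)) + 166e6,
        feature_class = "par_x", truth_class = "par_xy_up",
        homolog_group = c(grp, rep(NA_character_, n_extra_x)),
        stringsAsFactors = FALSE)
      rows$par_x <- par_x
      if (n_pairs > 0) {
        rows$par_y <- data.frame(
          feature_id = sprintf("gPARY%02d", seq_len(n_pairs)),
          chromosome = "Y",
          start_bp = y_max + sort(sample.int(3e6, n_pairs)),
          feature_class = "par_y", truth_class = "par_xy_up",
          homolog_group = grp, stringsAsFactors = FALSE)
      }
    }

    if (n_spikes > 0) {
      rows$spike <- data.frame(
        feature_id = sprintf("ERCC-%05d", seq_len(n_spikes)),
        chromosome = "ERCC", start_bp = seq_len(n_spikes),
        feature_class = "spike", truth_class = "spike",
        homolog_group = NA_character_, stringsAsFactors = FALSE)
    }

    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL

    # X/Y homolog groups (e.g. Kdm5c/Kdm5d-like pairs): one x_linked and
    # one y_linked member each, drawn from expressed classes.
    n_hp <- min(n_homolog_pairs,
                sum(ann$feature_class == "x_linked"),
                sum(ann$truth_class %in% c("y_high", "y_medium")))
    if (n_hp > 0) {
      xi <- sample(which(ann$feature_class == "x_linked"), n_hp)
      yi <- sample(which(ann$truth_class %in% c("y_high", "y_medium")), n_hp)
      grp <- sprintf("HOM%02d", seq_len(n_hp))
      ann$homolog_group[xi] <- grp
      ann$homolog_group[yi] <- grp
    }
    ann
  })
}

# Deterministic class assignment honouring exact fractions: label counts
# are fixed by rounding (largest-remainder), only the placement is random.
assign_classes <- function(n, fractions) {
  if (n == 0L) return(character())
  counts <- floor(fractions * n)
  rem <- fractions * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }
  sample(rep(names(fractions), counts))
}

# Validate annotation invariants; used by tests and the pipeline.
validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  if (anyDuplicated(ann$feature_id)) stop_arg("feature_ids are not unique")
  if (any(ann$feature_class == "spike" & ann$chromosome != "ERCC")) {
    stop_arg("spike features must be on chromosome ERCC")
  }
  ylin <- ann$start_bp[ann$feature_class == "y_linked"]
  pary <- ann$start_bp[ann$feature_class == "par_y"]
  if (length(ylin) && length(pary) && min(pary) <= max(ylin)) {
    stop_arg("par_y features must be distal to all y_linked features")
  }
  invisible(TRUE)
}
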