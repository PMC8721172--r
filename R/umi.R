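# 5' tag detection and UMI counting for modified Smart-seq3 reads.
#
# A tagged read is laid out as
#   [0..max_start_offset junk] anchor (<= allowed mismatches)
#   UMI (umi_length bases, no N) | post-UMI bases (exact) | G-stretch | cDNA
# mirroring a template-switching oligo of the form
# AGATGTGTATAAGAGACAG N(12) ACG rGrGrG. The G-stretch is consumed
# greedily so the reported cDNA offset never starts on template-switch Gs.

#' Describe the 5' tag layout
#'
#' @param anchor Anchor DNA string preceding the UMI.
#' @param umi_length UMI length in bases.
#' @param post_umi Fixed bases between UMI and G-stretch (matched exactly).
#' @param min_g_stretch Minimum number of Gs after `post_umi`.
#' @param max_start_offset Largest allowed anchor start offset (0-based).
#' @param allowed_mismatches_in_anchor Hamming tolerance within the anchor.
#' @return A list of class `tag_pattern`.
#' @export
tag_pattern <- function(anchor = "AGATGTGTATAAGAGACAG", umi_length = 12,
                        post_umi = "ACG", min_g_stretch = 2,
                        max_start_offset = 5,
                        allowed_mismatches_in_anchor = 1) {
  if (!nzchar(anchor)) stop_arg("'anchor' must be non-empty")
  umi_length <- check_count(umi_length, "umi_length", min = 1L)
  max_start_offset <- check_count(max_start_offset, "max_start_offset")
  allowed_mismatches_in_anchor <-
    check_count(allowed_mismatches_in_anchor, "allowed_mismatches_in_anchor")
  structure(list(anchor = anchor, umi_length = umi_length,
                 post_umi = post_umi, min_g_stretch = min_g_stretch,
                 max_start_offset = max_start_offset,
                 allowed_mismatches_in_anchor = allowed_mismatches_in_anchor),
            class = "tag_pattern")
}

#' Extract UMIs from read sequences
#'
#' Vectorized tag matcher. For each sequence, anchors are tried at offsets
#' `0..max_start_offset` (smallest offset wins; at a given offset the
#' match with fewest anchor mismatches is the only candidate). A match is
#' reported only if the anchor is followed by `umi_length` bases without
#' `N`, the exact `post_umi` bases, and at least `min_g_stretch` Gs; the
#' whole G run is consumed and `cdna_start` points at the first base after
#' it (1-based).
#'
#' @param sequences Character vector of reads (A/C/G/T/N only).
#' @param pattern From [tag_pattern()].
#' @return `data.frame` with `matched` (logical), `umi` (`NA` when
#'   unmatched), `cdna_start` (`NA` when unmatched).
#' @export
extract_tag <- function(sequences, pattern = tag_pattern()) {
  stopifnot(inherits(pattern, "tag_pattern"))
  if (length(sequences) == 0L) {
    return(data.frame(matched = logical(), umi = character(),
                      cdna_start = integer(), stringsAsFactors = FALSE))
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop_arg(sprintf("sequence %d contains characters outside ACGTN",
                     which(bad)[1]))
  }
  n <- length(sequences)
  alen <- nchar(pattern$anchor)
  anchor_chars <- strsplit(pattern$anchor, "")[[1]]
  need <- alen + pattern$umi_length + nchar(pattern$post_umi) +
    pattern$min_g_stretch

  umi <- rep(NA_character_, n)
  cdna <- rep(NA_integer_, n)
  matched <- rep(FALSE, n)
  pending <- rep(TRUE, n)

  for (off in 0:pattern$max_start_offset) {
    idx <- which(pending & nchar(sequences) >= off + need)
    if (!length(idx)) next
    # Hamming distance of the anchor window at this offset
    mm <- integer(length(idx))
    for (j in seq_len(alen)) {
      mm <- mm + (substring(sequences[idx], off + j, off + j) != anchor_chars[j])
    }
    hit <- mm <= pattern$allowed_mismatches_in_anchor
    if (!any(hit)) next
    h <- idx[hit]
    u <- substring(sequences[h], off + alen + 1L,
                   off + alen + pattern$umi_length)
    p_start <- off + alen + pattern$umi_length + 1L
    post_ok <- substring(sequences[h], p_start,
                         p_start + nchar(pattern$post_umi) - 1L) == pattern$post_umi
    g_start <- p_start + nchar(pattern$post_umi)
    tail_part <- substring(sequences[h], g_start)
    g_run <- attr(regexpr("^G*", tail_part), "match.length")
    ok <- post_ok & g_run >= pattern$min_g_stretch & !grepl("N", u, fixed = TRUE)
    # smallest fully valid placement wins; a failed layout check at this
    # offset falls through to later offsets
    matched[h[ok]] <- TRUE
    umi[h[ok]] <- u[ok]
    cdna[h[ok]] <- g_start + g_run[ok]
    pending[h[ok]] <- FALSE
  }
  data.frame(matched = matched, umi = umi, cdna_start = cdna,
             stringsAsFactors = FALSE)
}

#' Count deduplicated UMIs per gene and sample
#'
#' Applies [extract_tag()] to every read, joins gene assignments, and
#' counts the number of distinct UMI strings per (gene, sample). The same
#' UMI seen for two genes contributes one count to each; reads failing
#' tag extraction or lacking a gene assignment are tallied in the QC
#' report only.
#'
#' @param reads `data.frame` with `read_id`, `sample_id`, `sequence`.
#' @param assignment `data.frame` with `read_id`, `truth_gene` (or `gene`)
#'   mapping reads to features; unassigned reads may be absent or `NA`.
#' @param samples Sample metadata ([make_samples()]); defines column order.
#' @param features Optional feature universe defining row order; defaults
#'   to the sorted set of assigned genes.
#' @param pattern From [tag_pattern()].
#' @param collapse_hamming1 If `TRUE`, directionally collapse UMIs within
#'   a gene/sample that are Hamming distance 1 from a more frequent UMI
#'   (off by default; plain exact-string dedup otherwise).
#' @return List of class `umi_counts`: integer `counts` matrix
#'   (features x samples), `samples`, and a `qc` list (`reads_in`,
#'   `tag_matched`, `assigned`, `counted`).
#' @export
count_umis <- function(reads, assignment, samples, features = NULL,
                       pattern = tag_pattern(), collapse_hamming1 = FALSE) {
  if (anyDuplicated(reads$read_id)) stop_arg("duplicate read_ids in input")
  gene_col <- if ("gene" %in% names(assignment)) "gene" else "truth_gene"
  ex <- extract_tag(reads$sequence, pattern)
  gene <- assignment[[gene_col]][match(reads$read_id, assignment$read_id)]
  keep <- ex$matched & !is.na(gene)
  qc <- list(reads_in = nrow(reads), tag_matched = sum(ex$matched),
             assigned = sum(!is.na(gene)), counted = sum(keep))

  gk <- gene[keep]; sk <- reads$sample_id[keep]; uk <- ex$umi[keep]
  key <- paste(gk, sk, uk, sep = "\r")
  first <- !duplicated(key)
  gk <- gk[first]; sk <- sk[first]; uk <- uk[first]

  if (collapse_hamming1 && length(uk)) {
    mult <- tabulate(match(key, key[first]), nbins = sum(first))
    keep2 <- directional_collapse(gk, sk, uk, mult)
    gk <- gk[keep2]; sk <- sk[keep2]
  }

  if (is.null(features)) features <- sort(unique(gk))
  counts <- matrix(0L, length(features), nrow(samples),
                   dimnames = list(features, samples$sample_id))
  if (length(gk)) {
    tab <- table(factor(gk, levels = features),
                 factor(sk, levels = samples$sample_id))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, samples = samples, qc = qc),
            class = "umi_counts")
}

# Directional Hamming-1 collapse within each (gene, sample): a UMI is
# absorbed by a neighbour at distance 1 with strictly greater read
# multiplicity. Returns a logical keep vector.
directional_collapse <- function(gene, sample, umi, mult) {
  keep <- rep(TRUE, length(umi))
  grp <- paste(gene, sample, sep = "\r")
  for (g in split(seq_along(umi), grp)) {
    if (length(g) < 2L) next
    u <- umi[g]; m <- mult[g]
    for (i in seq_along(g)) {
      d1 <- which(vapply(u, hamming1, logical(1), b = u[i]) & m > m[i])
      if (length(d1)) keep[g[i]] <- FALSE
    }
  }
  keep
}

hamming1 <- function(a, b) {
  if (a == b) return(FALSE)
  sum(utf8ToInt(a) != utf8ToInt(b)) == 1L
}

#' Write a count matrix to TSV
#'
#' First column `feature_id`, one column per sample.
#' @param counts Integer matrix with feature rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV written by [write_counts()].
#' @return Integer matrix with feature rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix in MatrixMarket coordinate format
#'
#' Emits `<path>` (MTX), `<path>.rows` (feature ids) and `<path>.cols`
#' (sample ids).
#' @param counts Integer matrix.
#' @param path Output MTX path.
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(counts, path) {
  nz <- which(counts != 0, arr.ind = TRUE)
  hdr <- c("%%MatrixMarket matrix coordinate integer general",
           paste(nrow(counts), ncol(counts), nrow(nz)))
  body <- sprintf("%d %d %d", nz[, 1], nz[, 2], counts[nz])
  writeLines(c(hdr, body), path)
  writeLines(rownames(counts), paste0(path, ".rows"))
  writeLines(colnames(counts), paste0(path, ".cols"))
  invisible(path)
}
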