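# Ratio fits, expression bins, bootstrap X:A statistics, Y-gene classes,
# homolog sums.

# normalized matrix with exact per-genotype values (3 replicates each)
exact_norm <- function(values_by_geno, ann = NULL) {
  samples <- make_samples()
  m <- sapply(samples$genotype, function(g) values_by_geno[[g]])
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  dimnames(m) <- list(names(values_by_geno[[1]]), samples$sample_id)
  as_norm(m, annotation = ann, samples = samples)
}

test_that("ratio_fit is exact on constant ratios", {
  vals <- list(XX = c(g1 = 1.5, g2 = 3.5), XO = c(g1 = 0.5, g2 = 1.5),
               XY = c(g1 = 0.5, g2 = 1.5))
  # with pseudocount 0.5: (0.5+0.5)/(1.5+0.5) = 0.5 and 2/4 = 0.5
  nm <- exact_norm(vals)
  fit <- ratio_fit(nm, c("g1", "g2"))
  expect_equal(fit$geometric_mean, 0.5)
  expect_equal(fit$sdlog, 0)
  expect_equal(fit$mult_sd_interval, c(0.5, 0.5))
  expect_equal(fit$n, 4)  # two genes x two numerator genotypes
  expect_error(ratio_fit(nm, character()), "empty")
})

test_that("pooled ratio_fit equals the fit on concatenated log ratios", {
  s <- small_sim()
  dd <- s$ann$feature_id[s$ann$truth_class == "dosage_dependent"]
  pooled <- ratio_fit(s$norm, dd, "pooled")
  xo <- ratio_fit(s$norm, dd, "XO")
  xy <- ratio_fit(s$norm, dd, "XY")
  log_cat <- c(log(xo$ratios$ratio), log(xy$ratios$ratio))
  expect_equal(pooled$geometric_mean, exp(mean(log_cat)))
  expect_equal(pooled$sdlog, sd(log_cat))
  expect_equal(pooled$n, xo$n + xy$n)
})

test_that("ratio_fit recovers a planted dosage ratio of 0.5", {
  ann <- make_annotation(50, 180, 0, 0, 20,
                         class_fractions = list(
                           autosomal = c(neutral = 1),
                           x_linked = c(dosage_dependent = 1),
                           y_linked = c(y_high = 1)),
                         seed = 20)
  samples <- make_samples()
  for (seed in 1:10) {
    params <- sim_params(sdlog_bio = 0.25, meanlog_expr = log(300),
                         sdlog_expr = 0.5)
    truth <- simulate_truth(ann, params, seed = seed)
    sim <- simulate_counts(truth, samples, params, annotation = ann,
                           seed = seed + 50)
    sf <- size_factors(sim$counts, spike_design_from_truth(ann, truth))
    nm <- normalize_counts(sim$counts, sf, samples = samples,
                           annotation = ann)
    dd <- ann$feature_id[ann$truth_class == "dosage_dependent"]
    fit <- ratio_fit(nm, dd)
    expect_gt(fit$geometric_mean, 0.45)
    expect_lt(fit$geometric_mean, 0.55)
  }
})

test_that("ratio table is ordered by chromosome position", {
  s <- small_sim()
  dd <- s$ann$feature_id[s$ann$truth_class == "dosage_dependent"]
  fit <- ratio_fit(s$norm, dd)
  expect_true(all(diff(fit$ratios$start_bp) > 0))
})

test_that("expression bins partition genes into near-equal sizes", {
  mex <- setNames(runif(12), sprintf("g%02d", 1:12))
  bins <- assign_bins(mex, 6)
  expect_equal(as.integer(table(bins)), rep(2L, 6))
  # bin index non-decreasing in expression
  expect_true(all(diff(bins[order(mex, names(mex))]) >= 0))

  set.seed(21)
  big <- setNames(rlnorm(28051, 0, 2), sprintf("g%05d", 1:28051))
  b <- assign_bins(big, 6)
  expect_true(all(sort(unique(unname(table(b)))) %in% c(4675L, 4676L)))
  expect_equal(sum(table(b)), 28051)
  # partition: every gene in exactly one bin
  expect_equal(length(b), 28051)
  expect_true(all(b %in% 1:6))
  expect_error(assign_bins(mex[1:4], 6), "fewer genes")
})

null_xa_setup <- function(n_a = 4000, n_x = 2000, seed = 22,
                          meanlog = log(10), sdlog = 0.8) {
  set.seed(seed)
  ids <- c(sprintf("a%04d", seq_len(n_a)), sprintf("x%04d", seq_len(n_x)))
  cls <- c(rep("autosomal", n_a), rep("x_linked", n_x))
  ann <- bare_annotation(ids, cls)
  samples <- make_samples()
  mu <- rlnorm(n_a + n_x, meanlog, sdlog)
  vals <- matrix(mu, ncol = 1)[, rep(1, 9)] *
    matrix(rlnorm((n_a + n_x) * 9, 0, 0.05), ncol = 9)
  dimnames(vals) <- list(ids, samples$sample_id)
  as_norm(vals, annotation = ann, samples = samples)
}

test_that("X:A bootstrap is centred at 1 under the null", {
  # X and autosomal genes drawn from one expression distribution; within
  # each bin the two strata are exchangeable, so every cell's bootstrap
  # median sits at 1 up to the finite-gene-set wobble of the bin
  nm <- null_xa_setup()
  bins <- assign_bins(xa_universe_means(nm), 6)
  boot <- xa_bootstrap(nm, bins, resample_size = 100, reps = 1000, seed = 1)
  med <- aggregate(ratio ~ bin + genotype, boot, median)
  expect_true(all(abs(med$ratio - 1) < 0.05))
})

test_that("X:A bootstrap is scale-equivariant in the X stratum", {
  nm <- null_xa_setup(seed = 23, n_a = 600, n_x = 300)
  bins <- assign_bins(xa_universe_means(nm), 6)
  base <- xa_bootstrap(nm, bins, resample_size = 50, reps = 300, seed = 2)
  up <- nm
  xg <- grepl("^x", rownames(up$normalized))
  up$normalized[xg, ] <- up$normalized[xg, ] * 1.5
  # same bins, same seed: identical draws, so every ratio scales by 1.5
  boot <- xa_bootstrap(up, bins, resample_size = 50, reps = 300, seed = 2)
  expect_equal(boot$ratio, 1.5 * base$ratio, tolerance = 1e-12)
})

test_that("the bootstrap is seeded and exchangeable across seeds", {
  nm <- null_xa_setup(seed = 24, n_a = 400, n_x = 100)
  bins <- assign_bins(xa_universe_means(nm), 3)
  b1 <- xa_bootstrap(nm, bins, reps = 400, seed = 5)
  b2 <- xa_bootstrap(nm, bins, reps = 400, seed = 5)
  expect_identical(b1$ratio, b2$ratio)
  b3 <- xa_bootstrap(nm, bins, reps = 400, seed = 6)
  expect_false(identical(b1$ratio, b3$ratio))
  cell <- function(b) b$ratio[b$bin == 2 & b$genotype == "XX"]
  expect_gt(suppressWarnings(ks.test(cell(b1), cell(b3))$p.value), 0.01)
})

test_that("empty strata are reported by bin and stratum", {
  ids <- c(sprintf("a%02d", 1:30), sprintf("x%02d", 1:3))
  ann <- bare_annotation(ids, c(rep("autosomal", 30), rep("x_linked", 3)))
  samples <- make_samples()
  vals <- matrix(rlnorm(33 * 9, log(5), 1), 33,
                 dimnames = list(ids, samples$sample_id))
  # force all X genes into the top bin: some bin has no X members
  vals[31:33, ] <- 1e6
  nm <- as_norm(vals, annotation = ann, samples = samples)
  bins <- assign_bins(xa_universe_means(nm), 3)
  expect_error(xa_bootstrap(nm, bins, reps = 10, seed = 1),
               "bin [12]: empty X stratum")
})

test_that("bin-6 genotype ratios are exact without noise", {
  ids <- c(sprintf("x%02d", 1:40), sprintf("a%02d", 1:40))
  ann <- bare_annotation(ids, rep(c("x_linked", "autosomal"), each = 40))
  set.seed(25)
  base <- c(rlnorm(40, log(500), 0.3), rlnorm(40, log(500), 0.3))
  vals <- list(XX = setNames(base, ids),
               XO = setNames(c(base[1:40] * 0.5, base[41:80]), ids),
               XY = setNames(c(base[1:40] * 0.5, base[41:80]), ids))
  nm <- exact_norm(vals, ann = ann)
  bins <- setNames(rep(6L, 80), ids)
  boot <- bin6_genotype_ratio_bootstrap(nm, bins, bin = 6, reps = 200,
                                        seed = 3)
  expect_true(all(boot$ratio == 0.5))
})

test_that("mixed compensated/dosage bin-6 genes give intermediate ratios", {
  ids <- sprintf("x%02d", 1:40)
  ann <- bare_annotation(c(ids, "a1"), c(rep("x_linked", 40), "autosomal"))
  set.seed(26)
  base <- rlnorm(40, log(500), 0.2)
  fac <- rep(c(0.5, 1), each = 20)  # half dosage-dependent, half compensated
  vals <- list(XX = setNames(c(base, 100), c(ids, "a1")),
               XO = setNames(c(base * fac, 100), c(ids, "a1")),
               XY = setNames(c(base * fac, 100), c(ids, "a1")))
  nm <- exact_norm(vals, ann = ann)
  bins <- setNames(rep(6L, 41), c(ids, "a1"))
  boot <- bin6_genotype_ratio_bootstrap(nm, bins, bin = 6,
                                        resample_size = 100, reps = 500,
                                        seed = 4)
  expect_true(all(boot$ratio >= 0.5 - 1e-12 & boot$ratio <= 1 + 1e-12))
  expect_gt(median(boot$ratio), 0.5)
  expect_lt(median(boot$ratio), 1)
})

test_that("Y-gene classes follow the fixed log2FC boundaries", {
  ids <- c("y1", "y2", "y3", "y4", "yb3", "yb1")
  ann <- bare_annotation(ids, rep("y_linked", 6))
  pc <- 0.5
  # engineer exact log2FC values: 3.2, 0.5, 2.0, 0 (0/0), 3.0, 1.0
  lfc <- c(3.2, 0.5, 2.0, NA, 3, 1)
  xy <- ifelse(is.na(lfc), 0, (pc) * 2^lfc - pc)
  vals <- list(XX = setNames(rep(0, 6), ids),
               XO = setNames(rep(0, 6), ids),
               XY = setNames(xy, ids))
  nm <- exact_norm(vals, ann = ann)
  cls <- classify_y_genes(nm, pseudocount = pc)
  expect_equal(cls$class[match(c("y1", "y2", "y3", "y4"), cls$feature_id)],
               c("high", "none", "medium", "none"))
  expect_equal(cls$log2FC[cls$feature_id == "y4"], 0)
  # boundaries are closed/open exactly as specified
  expect_equal(cls$class[cls$feature_id == "yb3"], "high")   # 3.0 -> high
  expect_equal(cls$class[cls$feature_id == "yb1"], "none")   # 1.0 -> none
  eps <- 1e-12
  vals$XY <- setNames(pc * 2^(c(3 - eps, 1 + eps, 3, 1, 3, 1)) - pc, ids)
  cls2 <- classify_y_genes(exact_norm(vals, ann = ann), pseudocount = pc)
  expect_equal(cls2$class[1:2], c("medium", "medium"))
})

test_that("synthetic y_high genes are classed high", {
  s <- small_sim()
  cls <- classify_y_genes(s$norm, pseudocount = 0.5)
  yh <- s$ann$feature_id[s$ann$truth_class == "y_high"]
  xy_cols <- s$samples$sample_id[s$samples$genotype == "XX"]
  obs_xx <- rowMeans(s$norm$normalized[yh, xy_cols])
  obs_xy <- rowMeans(s$norm$normalized[yh,
                       s$samples$sample_id[s$samples$genotype == "XY"]])
  # observed XY mean >= 8 x pseudocount with XX at zero implies
  # log2FC >= log2(9/1) > 3, hence class "high"
  strong <- yh[obs_xy >= 8 * 0.5 & obs_xx == 0]
  expect_gt(length(strong), 0)
  expect_true(all(cls$class[match(strong, cls$feature_id)] == "high"))
})

test_that("homolog sums mirror the X+Y dosage arithmetic", {
  ids <- c("hx", "hy")
  ann <- bare_annotation(ids, c("x_linked", "y_linked"))
  ann$homolog_group <- "HOM01"
  u <- 4
  vals <- list(XX = c(hx = 2 * u, hy = 0), XO = c(hx = u, hy = 0),
               XY = c(hx = u, hy = u))
  nm <- exact_norm(vals, ann = ann)
  hs <- homolog_sum(nm)
  expect_equal(unname(hs$HOM01$sum),
               c(2 * u, u, 2 * u))  # XX, XO, XY
  expect_error(homolog_sum(nm, groups = "nope"), "unknown homolog group")

  # replicate values (2, 8): geometric mean 4, one-SD interval (2, 8)
  samples <- make_samples(2)
  m <- matrix(c(2, 8, 2, 8, 2, 8), 1, 6,
              dimnames = list("hx", samples$sample_id))
  ann1 <- bare_annotation("hx", "x_linked")
  ann1$homolog_group <- "G1"
  nm1 <- as_norm(m, annotation = ann1, samples = samples)
  hs1 <- homolog_sum(nm1, pseudocount = 0)
  mem <- hs1$G1$members
  xx <- mem[mem$genotype == "XX", ]
  expect_equal(xx$geometric_mean, 4)
  expect_equal(xx$sdlog, log(2))
  expect_equal(c(xx$lo, xx$hi), c(2, 8), tolerance = 1e-9)
})
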