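# Linear models, empirical-Bayes moderation, DEG lists, Venn partition.

sim_log_matrix <- function(n_genes, samples, mu = 8, sd = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * nrow(samples), mu, sd), n_genes,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              samples$sample_id))
  m
}

test_that("surrogate estimation finds a planted batch and stays orthogonal", {
  samples <- make_samples()
  samples$batch <- rep(c("b1", "b2"), length.out = 9)
  design <- design_matrix(samples)
  m <- sim_log_matrix(600, samples, seed = 2)
  shift <- samples$batch == "b2"
  hit <- 1:180  # 30% of genes carry the batch shift
  m[hit, shift] <- m[hit, shift] + 1.2

  expect_null(estimate_surrogates(m, design, 0))
  sv <- estimate_surrogates(m, design, 1)
  expect_gt(abs(cor(sv[, 1], as.numeric(shift))), 0.9)
  # orthogonal to the fitted design by construction
  expect_lt(max(abs(crossprod(design, sv))), 1e-8)
  expect_error(estimate_surrogates(m, design, 10), "residual df")

  expect_gte(num_surrogates(m, design, seed = 3), 1)
  m0 <- sim_log_matrix(600, samples, seed = 4)
  expect_equal(num_surrogates(m0, design, seed = 3), 0)
})

test_that("per-gene OLS reproduces group-mean differences", {
  samples <- make_samples()
  m <- sim_log_matrix(50, samples, seed = 5)
  fit <- fit_models(m, design_matrix(samples))
  xx <- rowMeans(m[, samples$genotype == "XX"])
  xo <- rowMeans(m[, samples$genotype == "XO"])
  xy <- rowMeans(m[, samples$genotype == "XY"])
  expect_equal(unname(fit$contrasts[, "XXvsXO"]), unname(xx - xo))
  expect_equal(unname(fit$contrasts[, "XXvsXY"]), unname(xx - xy))
  expect_equal(unname(fit$contrasts[, "XOvsXY"]), unname(xo - xy))
  expect_equal(fit$df_residual, 9 - 3)
  expect_error(fit_models(m, cbind(design_matrix(samples), dup = 1)),
               "rank deficient")
})

test_that("planted log2 fold changes are recovered", {
  samples <- make_samples()
  m <- sim_log_matrix(1000, samples, sd = 0.06, seed = 6)
  m[, samples$genotype == "XX"] <- m[, samples$genotype == "XX"] + 1
  fit <- fit_models(m, design_matrix(samples))
  est <- fit$contrasts[, "XXvsXO"]
  expect_gte(mean(est > 0.9 & est < 1.1), 0.95)
})

test_that("moderation reduces to the ordinary t at d0 = 0 and pools at Inf", {
  samples <- make_samples()
  m <- sim_log_matrix(200, samples, seed = 7)
  fit <- fit_models(m, design_matrix(samples))

  de0 <- moderate(fit, d0 = 0)
  ord_t <- fit$contrasts[, "XXvsXO"] /
    (sqrt(fit$sigma2) * fit$contrast_se_unscaled["XXvsXO"])
  sub <- de0[de0$contrast == "XXvsXO", ]
  expect_equal(sub$t, unname(ord_t), tolerance = 1e-12)
  expect_equal(sub$p, unname(2 * pt(-abs(ord_t), df = fit$df_residual)),
               tolerance = 1e-12)

  deI <- moderate(fit, d0 = Inf)
  tI <- deI$t[deI$contrast == "XXvsXO"]
  # pooled variance: all genes share s0^2, so t is proportional to logFC
  expect_equal(tI / sub$log2FC,
               rep((tI / sub$log2FC)[1], length(tI)), tolerance = 1e-9)
})

test_that("moderation agrees with the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  samples <- make_samples()
  set.seed(8)
  # heterogeneous true variances so the prior actually shrinks
  sds <- sqrt(0.05 * rchisq(300, df = 5) / 5)
  m <- matrix(rnorm(300 * 9, 8, rep(sds, 9)), 300,
              dimnames = list(sprintf("g%03d", 1:300), samples$sample_id))
  design <- design_matrix(samples)
  fit <- fit_models(m, design)
  de <- moderate(fit)

  lf <- limma::lmFit(m, design)
  cm <- matrix(c(0, -1, 0), 3, 1, dimnames = list(colnames(design), "XXvsXO"))
  lf2 <- limma::eBayes(limma::contrasts.fit(lf, cm))
  expect_equal(attr(de, "d0"), lf2$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "s02"), lf2$s2.prior, tolerance = 1e-4)
  sub <- de[de$contrast == "XXvsXO", ]
  expect_equal(sub$t, unname(lf2$t[, 1]), tolerance = 1e-6)
  expect_equal(sub$p, unname(lf2$p.value[, 1]), tolerance = 1e-6)
})

test_that("the moderated test is calibrated under the null", {
  samples <- make_samples()
  m <- sim_log_matrix(4000, samples, seed = 9)
  de <- moderate(fit_models(m, design_matrix(samples)))
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(de$p[de$contrast == "XXvsXO"] < alpha)
    se <- sqrt(alpha * (1 - alpha) / 4000)
    expect_lt(abs(frac - alpha), 3 * se)
  }
})

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(10)
  p <- runif(100)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH keeps empirical FDR at or below nominal", {
  samples <- make_samples()
  m <- sim_log_matrix(2000, samples, sd = 0.25, seed = 11)
  signal <- 1:200  # 10% strong signal
  m[signal, samples$genotype == "XX"] <-
    m[signal, samples$genotype == "XX"] + 2
  de <- moderate(fit_models(m, design_matrix(samples)))
  sub <- de[de$contrast == "XXvsXO", ]
  called <- which(sub$fdr < 0.05)
  fdp <- mean(!(called %in% signal))
  expect_lte(fdp, 0.05 + 2 * sqrt(0.05 * 0.95 / max(length(called), 1)))
})

test_that("directional DEG selection honours p, sign, and lfc thresholds", {
  samples <- make_samples()
  de <- moderate(fit_models(sim_log_matrix(100, samples, seed = 12),
                            design_matrix(samples)))
  fake <- de
  fake$p[1] <- 0.04; fake$log2FC[1] <- 0.5
  expect_false(fake$feature_id[1] %in%
                 select_degs(fake, fake$contrast[1], "over", lfc_min = 1))
  expect_true(fake$feature_id[1] %in%
                select_degs(fake, fake$contrast[1], "over", lfc_min = 0))
  expect_error(select_degs(de, "nope", "over"), "unknown contrast")

  # null symmetry: each directional list captures about 2.5% of genes
  big <- moderate(fit_models(sim_log_matrix(8000, samples, seed = 13),
                             design_matrix(samples)))
  n_over <- length(select_degs(big, "XXvsXO", "over"))
  n_under <- length(select_degs(big, "XXvsXO", "under"))
  expect_lt(abs(n_over / 8000 - 0.025), 0.01)
  expect_lt(abs(n_under / 8000 - 0.025), 0.01)
})

test_that("venn partition equals brute-force membership enumeration", {
  sets <- list("XX>XO" = c("a", "b", "c"), "XX>XY" = c("a", "b"),
               "XY>XO" = c("c"), "XY<XO" = character())
  v <- venn_partition(sets)
  expect_equal(sort(v$categories$red), c("a", "b"))
  expect_equal(v$categories$purple_broken, character(0))
  expect_equal(sum(v$cell_counts), 3)

  empty <- venn_partition(list("XX>XO" = character(), "XX>XY" = character(),
                               "XY>XO" = character(), "XY<XO" = character()))
  expect_true(all(empty$cell_counts == 0))
  expect_error(venn_partition(list(a = "x", b = "y", c = "z", d = "w")),
               "set names")

  set.seed(14)
  for (i in 1:200) {
    universe <- sprintf("g%02d", 1:30)
    sets <- lapply(1:4, function(j) sample(universe, rpois(1, 8)))
    names(sets) <- c("XX>XO", "XX>XY", "XY>XO", "XY<XO")
    v <- venn_partition(sets)
    bf <- bf_venn_cells(sets)
    for (p in names(v$cells)) {
      expect_equal(sort(v$cells[[p]]), sort(unname(bf[[p]])))
    }
    # cells are a partition of the union
    expect_equal(sort(unlist(v$cells, use.names = FALSE)),
                 sort(unique(unlist(sets))))
  }
})

test_that("a planted batch breaks calibration at k=0 and k=1 restores it", {
  samples <- make_samples()
  # batch confounded with nothing, but inflating variance structure:
  # alternate samples across genotypes
  samples$batch <- rep(c("b1", "b2", "b1"), 3)
  set.seed(15)
  m <- sim_log_matrix(3000, samples, sd = 0.2, seed = 15)
  hit <- 1:900
  m[hit, samples$batch == "b2"] <- m[hit, samples$batch == "b2"] + 0.8

  d0mat <- design_matrix(samples)
  de0 <- moderate(fit_models(m, d0mat))
  frac0 <- mean(de0$p[de0$contrast == "XXvsXO"] < 0.05)

  sv <- estimate_surrogates(m, d0mat, 1)
  de1 <- moderate(fit_models(m, design_matrix(samples, sv)))
  frac1 <- mean(de1$p[de1$contrast == "XXvsXO"] < 0.05)

  se <- sqrt(0.05 * 0.95 / 3000)
  expect_gt(abs(frac0 - 0.05), 4 * se)   # visibly miscalibrated
  expect_lt(abs(frac1 - 0.05), 4 * se)   # restored by one surrogate
})
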