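test_that("sim_config validates its fields with informative messages", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(alpha = 1.5), "alpha")
  expect_error(sim_config(h2 = 1), "h2")
  expect_error(sim_config(shared_snps = 10, snps_per_gene = 10), "shared_snps")
  expect_error(sim_config(causal_ratio = 0), "causal")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
})

test_that("genotypes are standardized, reproducible, with the stated LD structure", {
  cfg <- small_config(rho_ld = 0.6)
  g1 <- withr::with_seed(1, simulate_genotypes(cfg))
  g2 <- withr::with_seed(1, simulate_genotypes(cfg))
  expect_identical(g1$genotypes, g2$genotypes)

  expect_lt(max(abs(colMeans(g1$genotypes))), 1e-12)
  expect_equal(
    apply(g1$genotypes[, 1:5], 2, var), rep(1, 5),
    ignore_attr = TRUE
  )
  # rho_ld = 0: off-diagonal LD vanishes within MC tolerance
  g0 <- withr::with_seed(2, simulate_genotypes(small_config(rho_ld = 0)))
  offs <- abs(g0$ld[[1]]$matrix[upper.tri(g0$ld[[1]]$matrix)])
  expect_lt(max(offs), 4 / sqrt(cfg$n))
  # positive rho_ld: adjacent SNPs clearly correlated
  adj <- g1$ld[[1]]$matrix[cbind(1:5, 2:6)]
  expect_gt(mean(adj), 0.25)
  # shared SNPs appear in both adjacent genes
  expect_length(
    intersect(g1$ld[[1]]$snp_ids, g1$ld[[2]]$snp_ids),
    cfg$shared_snps
  )
})

test_that("no gene overlap and no LD makes the gene correlation near-diagonal", {
  cfg <- sim_config(
    n = 4000, n_genes = 20, snps_per_gene = 5, shared_snps = 0, rho_ld = 0
  )
  st <- simulate_study(cfg, 5)
  sig <- correlation_from_expression(st$expression)$sigma
  expect_lt(max(abs(sig[upper.tri(sig)])), 4 / sqrt(cfg$n))
})

test_that("weights are sparse and predicted expression equals its construction", {
  cfg <- small_config()
  st <- simulate_study(cfg, 3)
  expect_equal(nrow(st$weights), cfg$n_genes * cfg$nonzero_weights)
  # reconstruct one gene's predicted expression from genotypes and weights
  g <- "gene005"
  wg <- st$weights[st$weights$gene_id == g, ]
  x <- st$genotypes[, wg$snp_id, drop = FALSE] %*% wg$weight
  expect_equal(drop(x), st$expression[, g], ignore_attr = TRUE)
  expect_equal(var(st$expression[, g]), 1, tolerance = 1e-12)
})

test_that("phenotype heritability matches h2 and null effects are exactly zero", {
  cfg <- sim_config(
    n = 20000, n_genes = 50, snps_per_gene = 5, shared_snps = 1, h2 = 0.2,
    causal_ratio = 0.5
  )
  st <- simulate_study(cfg, 9)
  expect_equal(sum(st$truth$causal), 25)
  expect_true(all(st$truth$beta[!st$truth$causal] == 0))
  # the realized genetic variance fluctuates around h2 with the chi^2
  # spread of the k effect draws; average over studies to pin it down
  ratios <- vapply(9:12, function(s) {
    sti <- simulate_study(cfg, s)
    genetic <- drop(sti$expression %*% sti$truth$beta)
    var(genetic) / var(sti$y)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.2), 0.05)
  expect_equal(var(st$y), 1, tolerance = 0.05)

  # h2 = 0 boundary: pure-noise phenotype, all effects zero
  st0 <- simulate_study(small_config(h2 = 0), 4)
  expect_true(all(st0$truth$beta == 0))
})

test_that("marginal GWAS matches the closed-form slope and moment se", {
  cfg <- small_config()
  st <- simulate_study(cfg, 12)
  j <- 7
  gj <- st$genotypes[, j]
  slope <- cov(gj, st$y) / var(gj)
  expect_equal(st$sumstats$beta[j], slope, tolerance = 1e-10)
  expect_equal(
    st$sumstats$se[j],
    snp_se_from_moments(slope, 1, st$sigma2_y, cfg$n)
  )
  # under a pure-noise phenotype every slope is near zero
  st0 <- simulate_study(small_config(h2 = 0), 13)
  expect_lt(stats::quantile(abs(st0$sumstats$beta), 0.95), 3 / sqrt(cfg$n))
})

test_that("simulated studies are reproducible and exportable through the readers", {
  cfg <- small_config()
  s1 <- simulate_study(cfg, 21)
  s2 <- simulate_study(cfg, 21)
  expect_identical(s1$sumstats, s2$sumstats)
  expect_identical(s1$truth, s2$truth)

  dir <- withr::local_tempdir()
  export_study(s1, dir)
  ss <- read_sumstats(file.path(dir, "sumstats.tsv"))
  expect_equal(nrow(ss), ncol(s1$genotypes))
  expect_equal(ss$beta, s1$sumstats$beta, tolerance = 1e-12)
  w <- read_weights(file.path(dir, "weights.tsv"))
  expect_equal(nrow(w), nrow(s1$weights))
  blk <- read_ld(file.path(dir, "ld", "gene001.ld.tsv"), gene_id = "gene001")
  expect_equal(blk$matrix, s1$ld[["gene001"]]$matrix, tolerance = 1e-10)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(unname(expr[, 1]), unname(s1$expression[, 1]), tolerance = 1e-6)
})

test_that("run_replicate returns both methods and sensible bookkeeping", {
  res <- run_replicate(small_config(h2 = 0.3, causal_ratio = 0.1), seed = 31)
  expect_setequal(res$method, c("knockoff", "spredixcan_bh"))
  expect_true(all(res$n_false + res$n_true == res$n_selected))
  expect_true(all(res$mfdr >= 0 & res$mfdr <= 1))

  # near-null world: essentially nothing selected
  res0 <- run_replicate(small_config(h2 = 0), seed = 32)
  expect_lte(sum(res0$n_selected), 1)
})

test_that("run_study and run_scenarios aggregate replicates deterministically", {
  cfg <- small_config(h2 = 0.3, causal_ratio = 0.1)
  s1 <- run_study(cfg, replicates = 3, seed = 7)
  s2 <- run_study(cfg, replicates = 3, seed = 7)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_equal(s1$replicates, c(3, 3))
  expect_true(all(c("mfdr", "mfdr_se", "tpp", "tpp_se") %in% names(s1)))
  expect_false(anyNA(s1$mfdr_se))

  grid <- tidyr::crossing(h2 = c(0.1, 0.3), causal_ratio = 0.1)
  out <- run_scenarios(cfg, grid, replicates = 2, seed = 8)
  expect_equal(nrow(out), 4) # 2 scenarios x 2 methods
  expect_s3_class(autoplot(out), "ggplot")
  expect_s3_class(autoplot(s1), "ggplot")
})
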