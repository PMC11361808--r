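#' Configuration of a synthetic TWAS study
#'
#' Captures the generative world of the replicated experiments: a cohort of
#' `n` individuals, `n_genes` candidate genes each with `snps_per_gene`
#' variants, block-correlated genotypes (latent Gaussian AR(1) with
#' parameter `rho_ld`, thresholded to Binomial(2, MAF) allele counts with
#' MAF drawn uniformly from `maf_range`), adjacent genes sharing
#' `shared_snps` variants (which, together with cross-gene LD, induces the
#' gene-gene correlation), sparse imputation weights
#' (`nonzero_weights` standard-normal entries per gene), causal genes at
#' ratio `causal_ratio` with effects `beta_g ~ N(0, h2 / k)` for
#' `k = ceiling(causal_ratio * n_genes)`, and phenotype noise
#' `N(0, 1 - h2)` so the trait has unit variance.
#'
#' @param n Cohort size (default 5000; a desk-scale stand-in for
#'   biobank-size GWAS).
#' @param n_genes Number of candidate genes D (default 200).
#' @param snps_per_gene Variants per gene (default 10).
#' @param shared_snps Variants shared with the next gene (default 2, i.e.
#'   20 percent of each gene's variants).
#' @param maf_range Minor-allele-frequency range (default 0.05-0.5).
#' @param rho_ld Latent AR(1) LD decay within the SNP sequence
#'   (default 0.5).
#' @param nonzero_weights Nonzero imputation weights per gene (default 3).
#' @param h2 Trait heritability explained by the simulated genes, in
#'   `[0, 1)` (default 0.1).
#' @param causal_ratio Fraction of genes that are causal, in (0, 1]
#'   (default 0.05).
#' @param M Number of knockoff copies (default 5).
#' @param alpha Nominal modified-FDR level for the knockoff filter
#'   (default 0.05).
#' @param alpha_adj BH significance level for the baseline (default 0.05).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n = 5000, n_genes = 200, snps_per_gene = 10,
                       shared_snps = 2, maf_range = c(0.05, 0.5),
                       rho_ld = 0.5, nonzero_weights = 3, h2 = 0.1,
                       causal_ratio = 0.05, M = 5, alpha = 0.05,
                       alpha_adj = 0.05) {
  cfg <- list(
    n = as.integer(n), n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene),
    shared_snps = as.integer(shared_snps), maf_range = maf_range,
    rho_ld = rho_ld, nonzero_weights = as.integer(nonzero_weights),
    h2 = h2, causal_ratio = causal_ratio, M = check_m(M), alpha = alpha,
    alpha_adj = alpha_adj
  )
  bad <- character()
  if (cfg$n < 10) bad <- c(bad, "n must be at least 10")
  if (cfg$n_genes < 2) bad <- c(bad, "n_genes must be at least 2")
  if (cfg$snps_per_gene < 1) bad <- c(bad, "snps_per_gene must be >= 1")
  if (cfg$shared_snps < 0 || cfg$shared_snps >= cfg$snps_per_gene) {
    bad <- c(bad, "shared_snps must be in [0, snps_per_gene)")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
    maf_range[1] > maf_range[2]) {
    bad <- c(bad, "maf_range must be increasing within (0, 0.5]")
  }
  if (abs(rho_ld) >= 1) bad <- c(bad, "rho_ld must lie in (-1, 1)")
  if (cfg$nonzero_weights < 1 || cfg$nonzero_weights > cfg$snps_per_gene) {
    bad <- c(bad, "nonzero_weights must be in [1, snps_per_gene]")
  }
  if (h2 < 0 || h2 >= 1) bad <- c(bad, "h2 must lie in [0, 1)")
  if (causal_ratio <= 0 || causal_ratio > 1 ||
    ceiling(causal_ratio * cfg$n_genes) < 1) {
    bad <- c(bad, "causal_ratio must give at least one causal gene")
  }
  if (alpha <= 0 || alpha >= 1) bad <- c(bad, "alpha must lie in (0, 1)")
  if (alpha_adj <= 0 || alpha_adj >= 1) {
    bad <- c(bad, "alpha_adj must lie in (0, 1)")
  }
  if (length(bad) > 0) {
    abort(paste0(
      "invalid sim_config: ", paste(bad, collapse = "; "), "."
    ))
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n = %d, D = %d genes x %d SNPs (%d shared), h2 = %g, causal ratio = %g, M = %d\n",
    x$n, x$n_genes, x$snps_per_gene, x$shared_snps, x$h2, x$causal_ratio, x$M
  ))
  invisible(x)
}

gene_ids_for <- function(cfg) sprintf("gene%03d", seq_len(cfg$n_genes))


#' Simulate block-correlated standardized genotypes
#'
#' Generates the genotype matrix of a [sim_config()] world: a latent
#' Gaussian AR(1) chain (parameter `rho_ld`) runs across the SNP sequence
#' and is thresholded per SNP at the two Hardy-Weinberg cutpoints
#' `qnorm((1 - maf)^2)` and `qnorm(1 - maf^2)`, so each allele count has
#' exact Binomial(2, MAF) margins while inheriting the AR(1) copula as
#' LD. Columns are standardized to mean 0, unit variance. Adjacent genes
#' overlap in `shared_snps` variants, and the chain runs across gene
#' boundaries, so nearby genes are in LD.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` (n x J standardized matrix, SNP ids as
#'   column names), `gene_index` (named list of column indices per gene),
#'   `ld` (named list of per-gene [ld_block()] sample correlations) and
#'   `maf`.
#' @export
simulate_genotypes <- function(config) {
  stride <- config$snps_per_gene - config$shared_snps
  j_total <- stride * (config$n_genes - 1L) + config$snps_per_gene
  snp_ids <- sprintf("snp%05d", seq_len(j_total))
  maf <- runif(j_total, config$maf_range[1], config$maf_range[2])
  c1 <- stats::qnorm((1 - maf)^2)
  c2 <- stats::qnorm(1 - maf^2)
  n <- config$n
  e <- rnorm(n * j_total)
  dim(e) <- c(n, j_total)
  g <- matrix(0, n, j_total, dimnames = list(NULL, snp_ids))
  rho <- config$rho_ld
  sfac <- sqrt(1 - rho^2)
  # one pass per SNP: AR(1) latent update, Hardy-Weinberg thresholding,
  # standardization -- avoids materializing intermediate n x J copies
  prev <- e[, 1L]
  for (j in seq_len(j_total)) {
    if (j > 1L) prev <- rho * prev + sfac * e[, j]
    x <- (prev > c1[j]) + (prev > c2[j])
    mu <- mean(x)
    sdv <- sqrt((sum(x * x) - n * mu^2) / (n - 1))
    if (sdv == 0) abort("degenerate SNP: constant genotype column.")
    g[, j] <- (x - mu) / sdv
  }
  genes <- gene_ids_for(config)
  gene_index <- lapply(seq_len(config$n_genes), function(i) {
    (i - 1L) * stride + seq_len(config$snps_per_gene)
  })
  names(gene_index) <- genes
  ld <- lapply(genes, function(gid) {
    idx <- gene_index[[gid]]
    m <- crossprod(g[, idx, drop = FALSE]) / (config$n - 1)
    diag(m) <- 1
    ld_block(gid, snp_ids[idx], m, dialect = "correlation")
  })
  names(ld) <- genes
  list(genotypes = g, gene_index = gene_index, ld = ld, maf = maf)
}

#' Simulate sparse imputation weights and predicted expression
#'
#' Draws `nonzero_weights` standard-normal weights per gene at random SNP
#' positions and forms the predicted expression `Xhat_g = G_g w_g`. Weights
#' are rescaled so each predicted-expression column has unit sample
#' variance (expression is exactly its genetic prediction; no residual
#' expression noise is added).
#'
#' @param geno Output of [simulate_genotypes()].
#' @param config A [sim_config()].
#' @return A list with `weights` (tibble gene_id, snp_id, effect_allele,
#'   other_allele, weight) and `expression` (n x D matrix of predicted
#'   expression).
#' @export
simulate_weights_and_expression <- function(geno, config) {
  genes <- names(geno$gene_index)
  n <- nrow(geno$genotypes)
  k <- config$nonzero_weights
  xhat <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  snp_col <- character(k * length(genes))
  w_col <- numeric(k * length(genes))
  for (i in seq_along(genes)) {
    idx <- geno$gene_index[[i]]
    pos <- sort(sample.int(length(idx), k))
    w <- rnorm(k)
    x <- geno$genotypes[, idx[pos], drop = FALSE] %*% w
    s <- sqrt(drop(var(x)))
    at <- (i - 1L) * k + seq_len(k)
    snp_col[at] <- colnames(geno$genotypes)[idx[pos]]
    w_col[at] <- w / s
    xhat[, i] <- x / s
  }
  weights <- tibble::tibble(
    gene_id = rep(genes, each = k), snp_id = snp_col,
    effect_allele = "A", other_allele = "G", weight = w_col
  )
  list(weights = weights, expression = xhat)
}

#' Simulate the phenotype from predicted expression
#'
#' Chooses `k = ceiling(causal_ratio * n_genes)` causal genes uniformly,
#' draws their effects `beta_g ~ N(0, h2 / k)`, sets all other effects to
#' zero exactly, and forms `Y = Xhat beta + eps` with
#' `eps ~ N(0, 1 - h2)`.
#'
#' @param xhat n x D matrix of (standardized) predicted expression.
#' @param config A [sim_config()].
#' @return A list with `y` (length-n phenotype) and `truth` (tibble
#'   gene_id, beta, causal).
#' @export
simulate_phenotype <- function(xhat, config) {
  d <- ncol(xhat)
  k <- ceiling(config$causal_ratio * d)
  causal_idx <- sample.int(d, k)
  beta <- numeric(d)
  if (config$h2 > 0) {
    beta[causal_idx] <- rnorm(k, 0, sqrt(config$h2 / k))
  }
  y <- drop(xhat %*% beta) + rnorm(nrow(xhat), 0, sqrt(1 - config$h2))
  list(
    y = y,
    truth = tibble::tibble(
      gene_id = colnames(xhat), beta = beta,
      causal = seq_len(d) %in% causal_idx
    )
  )
}

#' Marginal GWAS on standardized genotypes
#'
#' Per SNP, the simple-regression slope of the phenotype on the
#' standardized genotype, `gamma_j = cov(G_j, Y) / var(G_j)`, with the
#' moment-based standard error of [snp_se_from_moments()].
#'
#' @param genotypes n x J standardized genotype matrix with SNP ids as
#'   column names.
#' @param y Phenotype vector.
#' @return A tibble of summary statistics (`snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `n`) with the trait variance as the
#'   `sigma2_y` attribute.
#' @export
marginal_gwas <- function(genotypes, y) {
  n <- nrow(genotypes)
  yc <- y - mean(y)
  gamma <- as.vector(crossprod(genotypes, yc)) / (n - 1)
  sigma2_y <- sum(yc^2) / (n - 1)
  se <- snp_se_from_moments(gamma, 1, sigma2_y, n)
  out <- tibble::tibble(
    snp_id = colnames(genotypes), effect_allele = "A", other_allele = "G",
    beta = gamma, se = se, n = n
  )
  attr(out, "sigma2_y") <- sigma2_y
  out
}

#' Simulate a complete synthetic TWAS study
#'
#' Runs the four generation steps of the stated world -- genotypes,
#' weights and predicted expression, phenotype, marginal GWAS summary
#' statistics -- under one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return An object of class `simulated_study`: `config`, `seed`,
#'   `genotypes`, `gene_index`, `ld`, `weights`, `expression`, `y`,
#'   `truth`, `sumstats`, `sigma2_y`.
#' @export
simulate_study <- function(config, seed = 1L) {
  withr::with_seed(seed, {
    geno <- simulate_genotypes(config)
    wx <- simulate_weights_and_expression(geno, config)
    ph <- simulate_phenotype(wx$expression, config)
    ss <- marginal_gwas(geno$genotypes, ph$y)
  })
  structure(
    list(
      config = config, seed = seed, genotypes = geno$genotypes,
      gene_index = geno$gene_index, ld = geno$ld, weights = wx$weights,
      expression = wx$expression, y = ph$y, truth = ph$truth,
      sumstats = ss, sigma2_y = attr(ss, "sigma2_y")
    ),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> seed %d: n = %d, D = %d genes, %d SNPs, %d causal\n",
    x$seed, x$config$n, x$config$n_genes, ncol(x$genotypes),
    sum(x$truth$causal)
  ))
  invisible(x)
}

#' Aligned per-gene data from a simulated study
#'
#' Assembles the [gene_data()] list a selection method consumes, directly
#' from the in-memory study (the simulator writes allele-consistent files,
#' so no sign flips arise; [export_study()] + the readers exercise the
#' harmonization path).
#'
#' @param study A [simulate_study()] result.
#' @return Named list of [gene_data()] objects in canonical gene order.
#' @export
study_gene_data <- function(study) {
  ss <- study$sumstats
  by_gene <- split(
    study$weights[, c("snp_id", "weight")],
    study$weights$gene_id
  )
  genes <- names(study$gene_index)
  out <- lapply(genes, function(gid) {
    wg <- by_gene[[gid]]
    ld <- study$ld[[gid]]
    keep <- match(intersect(ld$snp_ids, wg$snp_id), ld$snp_ids)
    sidx <- match(ld$snp_ids[keep], ss$snp_id)
    widx <- match(ld$snp_ids[keep], wg$snp_id)
    snps <- tibble::new_tibble(
      list(
        snp_id = ld$snp_ids[keep], weight = wg$weight[widx],
        beta = ss$beta[sidx], se = ss$se[sidx], n = ss$n[sidx]
      ),
      nrow = length(keep)
    )
    gene_data(gid, snps, ld$matrix[keep, keep, drop = FALSE],
      dialect = ld$dialect
    )
  })
  names(out) <- genes
  out
}

#' Export a simulated study as the package's standard input files
#'
#' Writes `sumstats.tsv`, `weights.tsv`, `expression.tsv`, `truth.tsv` and
#' one `ld/<gene_id>.ld.tsv` matrix per gene, in the formats the
#' [read_sumstats()] family consumes.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_study <- function(study, dir) {
  dir.create(file.path(dir, "ld"), recursive = TRUE, showWarnings = FALSE)
  ss <- study$sumstats
  readr::write_tsv(
    tibble::tibble(
      snp = ss$snp_id, a1 = ss$effect_allele, a2 = ss$other_allele,
      beta = ss$beta, se = ss$se, n = ss$n
    ),
    file.path(dir, "sumstats.tsv")
  )
  readr::write_tsv(
    tibble::tibble(
      gene_id = study$weights$gene_id, snp_id = study$weights$snp_id,
      a1 = study$weights$effect_allele, a2 = study$weights$other_allele,
      weight = study$weights$weight
    ),
    file.path(dir, "weights.tsv")
  )
  expr <- tibble::as_tibble(study$expression)
  expr <- dplyr::mutate(expr,
    sample = sprintf("s%05d", seq_len(nrow(expr))),
    .before = 1L
  )
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  for (gid in names(study$ld)) {
    blk <- study$ld[[gid]]
    df <- tibble::as_tibble(blk$matrix)
    readr::write_tsv(df, file.path(dir, "ld", paste0(gid, ".ld.tsv")))
  }
  invisible(dir)
}

#' Run one simulated replicate of both selection methods
#'
#' Generates a study, runs the knockoff pipeline (gene Z-scores, gene
#' correlation from predicted expression, M ghost knockoff copies, the
#' GReX-feature-statistic filter) and the S-PrediXcan + BH baseline, and
#' scores both against the generating truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the replicate.
#' @param s_method `"sdp"` or `"equi"` knockoff diagonal.
#' @param baseline Also run the S-PrediXcan + BH baseline?
#' @return A tibble with one row per method: `method`, `n_selected`,
#'   `n_false`, `n_true`, `mfdr`, `tpp`, `threshold`.
#' @export
run_replicate <- function(config, seed = 1L, s_method = "sdp",
                          baseline = TRUE) {
  study <- simulate_study(config, seed)
  genes <- study_gene_data(study)
  causal <- study$truth$gene_id[study$truth$causal]
  # distinct stream for the knockoff draw; modular shift avoids integer
  # overflow for seeds near .Machine$integer.max
  knock_seed <- as.integer((as.numeric(seed) + 500003) %% 2147483647)
  withr::with_seed(knock_seed, {
    zs <- gene_zscores(genes, sigma2_y = study$sigma2_y)
    sigma <- regularize_correlation(
      correlation_from_expression(study$expression, genes = zs$gene_id)
    )
    model <- knockoff_model(sigma, M = config$M, s = s_method)
    draw <- sample_knockoffs(model, stats::setNames(zs$z, zs$gene_id))
    sel <- knockoff_select(
      knockoff_stats(draw),
      alpha = config$alpha, M = config$M
    )
  })
  out <- dplyr::mutate(
    evaluate_selection(sel, causal, alpha = config$alpha),
    method = "knockoff", threshold = sel$threshold, .before = 1L
  )
  if (baseline) {
    bres <- bh_select(
      spredixcan(genes, sigma2_y = study$sigma2_y, n = config$n),
      alpha_adj = config$alpha_adj
    )
    out <- dplyr::bind_rows(
      out,
      dplyr::mutate(
        evaluate_selection(
          bres$gene_id[bres$selected], causal,
          alpha = config$alpha
        ),
        method = "spredixcan_bh", threshold = NA_real_, .before = 1L
      )
    )
  }
  out
}

#' Replicated study of mFDR and power
#'
#' Runs [run_replicate()] `replicates` times with seeds derived from a
#' master seed by a fixed counter scheme (identical results regardless of
#' execution order) and averages the modified FDR and true positive
#' proportion per method.
#'
#' @inheritParams run_replicate
#' @param replicates Number of replicates (default 50).
#' @param seed Master seed.
#' @return A tibble of class `gkf_study` with one row per method:
#'   `method`, `mfdr`, `mfdr_se`, `tpp`, `tpp_se`, `n_selected`,
#'   `replicates`, plus the scenario parameters `n`, `h2`, `causal_ratio`,
#'   `alpha`, `M`. Per-replicate rows are attached as the `replicates`
#'   attribute.
#' @export
run_study <- function(config, replicates = 50, seed = 1L, s_method = "sdp",
                      baseline = TRUE) {
  rep_seeds <- withr::with_seed(
    seed, sample.int(2147483646L, replicates)
  )
  rows <- purrr::map2(seq_len(replicates), rep_seeds, function(i, s) {
    res <- try(
      run_replicate(config, s, s_method = s_method, baseline = baseline),
      silent = TRUE
    )
    if (inherits(res, "try-error")) {
      warn(sprintf("replicate %d (seed %d) failed and was excluded: %s",
        i, s, attr(res, "condition")$message %||% "unknown error"))
      return(NULL)
    }
    dplyr::mutate(res, replicate = i)
  }) |> dplyr::bind_rows()
  summary <- rows |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mfdr_se = sd(.data$mfdr) / sqrt(dplyr::n()),
      tpp_se = sd(.data$tpp) / sqrt(dplyr::n()),
      mfdr = mean(.data$mfdr),
      tpp = mean(.data$tpp),
      n_selected = mean(.data$n_selected),
      replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::relocate("mfdr", "mfdr_se", "tpp", "tpp_se", .after = "method") |>
    dplyr::mutate(
      n = config$n, h2 = config$h2, causal_ratio = config$causal_ratio,
      alpha = config$alpha, M = config$M
    )
  attr(summary, "replicates") <- rows
  class(summary) <- c("gkf_study", class(summary))
  summary
}

#' Run a grid of simulation scenarios
#'
#' Maps [run_study()] over a scenario grid (a tibble whose columns are
#' [sim_config()] fields to override, e.g. `h2` and `causal_ratio`),
#' mirroring the layout of a scenario-by-method results table.
#'
#' @inheritParams run_study
#' @param scenarios Tibble of config overrides, one row per scenario.
#' @return A tibble of class `gkf_study_grid`: one row per scenario and
#'   method with `mfdr`, `mfdr_se`, `tpp`, `tpp_se`.
#' @export
run_scenarios <- function(config, scenarios, replicates = 50, seed = 1L,
                          s_method = "sdp", baseline = TRUE) {
  scen_seeds <- withr::with_seed(
    seed, sample.int(2147483646L, nrow(scenarios))
  )
  out <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    over <- as.list(scenarios[i, , drop = FALSE])
    cfg <- do.call(sim_config, utils::modifyList(unclass(config), over))
    run_study(cfg, replicates = replicates, seed = scen_seeds[i],
      s_method = s_method, baseline = baseline)
  }) |> dplyr::bind_rows()
  class(out) <- c("gkf_study_grid", class(out))
  out
}

#' @export
autoplot.gkf_study_grid <- function(object, metric = c("mfdr", "tpp"), ...) {
  metric <- match.arg(metric)
  alpha <- unique(object$alpha)
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$h2, y = .data[[metric]], colour = .data$method,
      group = .data$method
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$causal_ratio),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "heritability h2", y = metric) +
    ggplot2::theme_minimal()
  if (metric == "mfdr" && length(alpha) == 1) {
    p <- p + ggplot2::geom_hline(yintercept = alpha, linetype = "dashed")
  }
  p
}

#' @rdname autoplot.gkf_study_grid
#' @export
autoplot.gkf_study <- function(object, metric = c("mfdr", "tpp"), ...) {
  reps <- attr(object, "replicates")
  metric <- match.arg(metric)
  p <- ggplot2::ggplot(
    reps, ggplot2::aes(x = .data$method, y = .data[[metric]])
  ) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_minimal()
  if (metric == "mfdr") {
    p <- p + ggplot2::geom_hline(
      yintercept = unique(object$alpha), linetype = "dashed"
    )
  }
  p
}
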