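#' Variance of predicted gene expression
#'
#' Computes `t(w) %*% R %*% w`, the variance of the genetically predicted
#' expression of a gene whose imputation weights are `w` and whose SNPs
#' have LD matrix `R`.
#'
#' @param weights Numeric weight vector.
#' @param ld Square symmetric LD matrix, conformable with `weights`.
#' @return A single non-negative number.
#' @examples
#' gene_variance(c(1, 1), matrix(c(1, 0.5, 0.5, 1), 2)) # 3
#' @export
gene_variance <- function(weights, ld) {
  ld <- as.matrix(ld)
  if (length(weights) != nrow(ld) || nrow(ld) != ncol(ld)) {
    abort(sprintf(
      "non-conformable: %d weights vs %d x %d LD matrix.",
      length(weights), nrow(ld), ncol(ld)
    ))
  }
  drop(crossprod(weights, ld %*% weights))
}

#' Standard error of a marginal SNP effect from moments
#'
#' Recovers `se(gamma_hat)` for a marginal regression of the trait on a
#' single SNP from summary moments:
#' `sqrt((sigma2_y - gamma_hat^2 * rho2) / (n * rho2))`, where `rho2` is
#' the SNP variance (the LD diagonal) and `sigma2_y` the trait variance.
#' Used by the simulator and as a fallback when a summary-statistics file
#' lacks a standard-error column.
#'
#' @param gamma_hat Marginal effect estimate(s).
#' @param rho2 SNP variance(s), positive.
#' @param sigma2_y Trait variance.
#' @param n GWAS sample size.
#' @return Standard error(s), vectorized over the inputs.
#' @export
snp_se_from_moments <- function(gamma_hat, rho2, sigma2_y, n) {
  if (any(n <= 1)) abort("`n` must exceed 1.")
  if (any(rho2 <= 0)) abort("`rho2` must be positive.")
  num <- sigma2_y - gamma_hat^2 * rho2
  if (any(num <= 0)) {
    abort("degenerate SNP: sigma2_y - gamma_hat^2 * rho2 must be positive.")
  }
  sqrt(num / (n * rho2))
}

#' Gene-level Z-score from summary statistics
#'
#' Computes the gene association Z-score
#' `Z_g = sum_j w_j * rho_j / sigma_g * (gamma_j / se(gamma_j))`,
#' where `rho_j` is the SNP standard deviation (square root of the LD
#' diagonal) and `sigma_g = sqrt(t(W) R W)` the standard deviation of the
#' predicted expression. This is the summary-statistics form of the ratio
#' of the gene effect estimate to its standard error.
#'
#' @param data A [gene_data()] object.
#' @param sigma2_y Trait variance used when per-SNP `se` is missing
#'   (default 1, standardized phenotype).
#' @param sigma2_floor Genes whose predicted-expression variance falls at or
#'   below this floor are degenerate and reported as excluded.
#' @return A one-row tibble with `gene_id`, `z`, `sigma2`, `n_snps` and
#'   `reason` (`NA` for a usable gene; for a degenerate or unusable gene,
#'   `z` is `NA` and `reason` says why).
#' @export
gene_zscore <- function(data, sigma2_y = 1, sigma2_floor = 1e-8) {
  core <- gene_zscore_core(data, sigma2_y, sigma2_floor)
  tibble::tibble(
    gene_id = data$gene_id, z = core$z, sigma2 = core$sigma2,
    n_snps = nrow(data$snps), reason = core$reason
  )
}

gene_zscore_core <- function(data, sigma2_y, sigma2_floor) {
  if (!data$usable || nrow(data$snps) == 0) {
    return(list(z = NA_real_, sigma2 = NA_real_, reason = "no aligned SNPs"))
  }
  w <- data$snps$weight
  rho <- sqrt(diag(data$ld))
  sigma2 <- gene_variance(w, data$ld)
  if (!is.finite(sigma2) || sigma2 <= sigma2_floor) {
    return(list(
      z = NA_real_, sigma2 = sigma2,
      reason = "degenerate predicted-expression variance"
    ))
  }
  se <- data$snps$se
  if (anyNA(se)) {
    miss <- is.na(se)
    se[miss] <- snp_se_from_moments(
      data$snps$beta[miss], rho[miss]^2, sigma2_y, data$snps$n[miss]
    )
  }
  z <- sum(w * rho / sqrt(sigma2) * data$snps$beta / se)
  list(z = z, sigma2 = sigma2, reason = NA_character_)
}

#' Gene-level Z-scores for a study
#'
#' Applies [gene_zscore()] over a list of harmonized genes. The row order
#' of the result is the canonical gene order used by the gene correlation
#' matrix and the knockoff filter downstream.
#'
#' @param genes List of [gene_data()] objects (e.g. from
#'   [harmonize_study()]`$genes`).
#' @inheritParams gene_zscore
#' @return A tibble with one row per usable gene (`gene_id`, `z`, `sigma2`,
#'   `n_snps`); excluded genes and reasons are attached as the `excluded`
#'   attribute (a tibble).
#' @export
gene_zscores <- function(genes, sigma2_y = 1, sigma2_floor = 1e-8) {
  cores <- purrr::map(genes, gene_zscore_core,
    sigma2_y = sigma2_y, sigma2_floor = sigma2_floor
  )
  all <- tibble::tibble(
    gene_id = purrr::map_chr(genes, "gene_id"),
    z = purrr::map_dbl(cores, "z"),
    sigma2 = purrr::map_dbl(cores, "sigma2"),
    n_snps = purrr::map_int(genes, ~ nrow(.x$snps)),
    reason = purrr::map_chr(cores, "reason")
  )
  out <- dplyr::select(
    dplyr::filter(all, is.na(.data$reason)), -"reason"
  )
  attr(out, "excluded") <- dplyr::select(
    dplyr::filter(all, !is.na(.data$reason)), "gene_id", "reason"
  )
  out
}
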