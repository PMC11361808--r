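#' S-PrediXcan gene association test from summary statistics
#'
#' For each gene, the effect of predicted expression on the trait and its
#' standard error are recovered from SNP-level summary statistics:
#' `beta_g = sum_j w_j gamma_j rho_j^2 / sigma_g^2` and
#' `se^2(beta_g) = (sigma_y^2 - beta_g^2 sigma_g^2) / (n sigma_g^2)`, with
#' `sigma_g^2 = t(W) R W` the predicted-expression variance and `rho_j^2`
#' the SNP variance (LD diagonal). The Z statistic `beta_g / se` is
#' referred to a standard normal (two-sided), matching the large-n
#' summary-statistics regime.
#'
#' @param genes A [gene_data()] or list of them.
#' @param sigma2_y Trait variance (default 1, standardized phenotype).
#' @param n GWAS sample size; defaults to the per-gene median of the
#'   summary-statistics `n` column.
#' @param sigma2_floor Degeneracy floor for the predicted-expression
#'   variance.
#' @return A tibble with one row per gene: `gene_id`, `beta_hat`,
#'   `se_beta`, `z`, `p`. Genes violating the variance ordering
#'   `sigma2_y > beta_hat^2 * sigma_g^2` (or degenerate) get `NA` results.
#' @export
spredixcan <- function(genes, sigma2_y = 1, n = NULL, sigma2_floor = 1e-8) {
  if (inherits(genes, "gene_data")) genes <- list(genes)
  cores <- purrr::map(genes, spredixcan_core,
    sigma2_y = sigma2_y, n = n, sigma2_floor = sigma2_floor
  )
  tibble::tibble(
    gene_id = purrr::map_chr(genes, "gene_id"),
    beta_hat = purrr::map_dbl(cores, "beta_hat"),
    se_beta = purrr::map_dbl(cores, "se_beta"),
    z = purrr::map_dbl(cores, "z"),
    p = purrr::map_dbl(cores, "p")
  )
}

spredixcan_core <- function(data, sigma2_y, n, sigma2_floor) {
  na_row <- list(
    beta_hat = NA_real_, se_beta = NA_real_, z = NA_real_, p = NA_real_
  )
  if (!data$usable || nrow(data$snps) == 0) {
    return(na_row)
  }
  w <- data$snps$weight
  rho2 <- diag(data$ld)
  sigma2_g <- gene_variance(w, data$ld)
  if (!is.finite(sigma2_g) || sigma2_g <= sigma2_floor) {
    return(na_row)
  }
  n_g <- n %||% median(data$snps$n)
  beta_hat <- sum(w * data$snps$beta * rho2) / sigma2_g
  num <- sigma2_y - beta_hat^2 * sigma2_g
  if (num <= 0) {
    na_row$beta_hat <- beta_hat
    return(na_row)
  }
  se_beta <- sqrt(num / (n_g * sigma2_g))
  z <- beta_hat / se_beta
  list(
    beta_hat = beta_hat, se_beta = se_beta, z = z, p = 2 * pnorm(-abs(z))
  )
}

#' Benjamini-Hochberg selection
#'
#' Standard step-up BH adjustment with selection at `p_adj < alpha_adj`.
#' Missing p-values are excluded from the ranking and never selected.
#'
#' @param x A tibble with a `p` column (e.g. from [spredixcan()]), or a
#'   bare numeric vector of p-values.
#' @param alpha_adj Significance level applied to the adjusted p-values.
#' @return `x` with columns `p_adj` and `selected` added (for a bare
#'   vector, a tibble with `p`, `p_adj`, `selected`).
#' @examples
#' bh_select(c(0.001, 0.012, 0.03, 0.2), 0.05) # selects the first three
#' @export
bh_select <- function(x, alpha_adj = 0.05) {
  check_alpha(alpha_adj, "alpha_adj")
  if (is.numeric(x)) x <- tibble::tibble(p = x)
  if (!"p" %in% names(x)) abort("`x` must contain a `p` column.")
  if (any(x$p < 0 | x$p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p_adj <- rep(NA_real_, nrow(x))
  ok <- !is.na(x$p)
  p_adj[ok] <- p.adjust(x$p[ok], method = "BH")
  dplyr::mutate(x,
    p_adj = p_adj,
    selected = !is.na(p_adj) & p_adj < alpha_adj
  )
}
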