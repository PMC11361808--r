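#' Gene-gene correlation matrix
#'
#' Container for the D x D correlation matrix of (predicted) gene
#' expression used to generate knockoff copies of the gene Z-scores. Its
#' gene order must equal the order of the Z-score vector everywhere
#' downstream; [knockoff_model()] enforces this by id.
#'
#' @param sigma Symmetric matrix with unit diagonal.
#' @param genes Character vector of gene ids in matrix order.
#' @param provenance How the matrix was obtained: `"expression"`,
#'   `"weights-ld"` or `"hybrid"`.
#' @param shrink Shrinkage weight toward the identity already applied
#'   (see [regularize_correlation()]).
#' @return An object of class `gene_correlation`.
#' @export
gene_correlation <- function(sigma, genes,
                             provenance = c("expression", "weights-ld", "hybrid"),
                             shrink = 0) {
  sigma <- as.matrix(sigma)
  provenance <- match.arg(provenance)
  if (nrow(sigma) != length(genes) || ncol(sigma) != length(genes)) {
    abort("`sigma` dimensions must match the number of genes.")
  }
  if (max(abs(sigma - t(sigma))) > 1e-8) {
    abort("`sigma` must be symmetric.")
  }
  sigma <- (sigma + t(sigma)) / 2
  if (max(abs(diag(sigma) - 1)) > 1e-10) {
    abort("`sigma` must have unit diagonal; standardize or use cov2cor().")
  }
  dimnames(sigma) <- list(genes, genes)
  structure(
    list(
      sigma = sigma, genes = as.character(genes),
      provenance = provenance, shrink = shrink
    ),
    class = "gene_correlation"
  )
}

#' @export
print.gene_correlation <- function(x, ...) {
  cat(sprintf(
    "<gene_correlation> %d genes (%s%s)\n", length(x$genes), x$provenance,
    if (x$shrink > 0) sprintf(", shrink %.3g", x$shrink) else ""
  ))
  invisible(x)
}

#' Gene correlation from an expression matrix
#'
#' Sample Pearson correlation of expression columns, reordered to the
#' canonical gene order.
#'
#' @param expr Samples x genes numeric matrix with gene ids as column
#'   names.
#' @param genes Canonical gene order (default: the matrix columns).
#' @return A [gene_correlation()] with provenance `"expression"`.
#' @export
correlation_from_expression <- function(expr, genes = colnames(expr)) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) abort("need at least 3 samples to estimate correlations.")
  missing <- setdiff(genes, colnames(expr))
  if (length(missing) > 0) {
    abort(sprintf(
      "expression matrix lacks gene(s): %s.",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  expr <- expr[, genes, drop = FALSE]
  sds <- apply(expr, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "constant expression for gene(s) %s; exclude them upstream.",
      paste(head(genes[sds == 0], 5), collapse = ", ")
    ))
  }
  gene_correlation(cor(expr), genes, provenance = "expression")
}

#' Gene correlation from weights and cross-gene LD
#'
#' Correlation of the genetically predicted expressions:
#' `Sigma[g, h] = t(W_g) R[g, h] W_h / (sigma_g * sigma_h)`, where `R` is
#' the SNP LD matrix over the union of the genes' variants. Gene pairs
#' whose cross-LD is absent from `ld` contribute 0 (with a warning when
#' weighted SNPs are missing entirely).
#'
#' @param weights Tibble of weights for all genes (columns `gene_id`,
#'   `snp_id`, `weight`).
#' @param ld An [ld_block()] spanning the union of SNPs (cross-gene
#'   entries included as available).
#' @param genes Canonical gene order (default: genes present in `weights`).
#' @return A [gene_correlation()] with provenance `"weights-ld"`.
#' @export
correlation_from_weights_ld <- function(weights, ld,
                                        genes = unique(weights$gene_id)) {
  snp_ids <- ld$snp_ids
  wmat <- matrix(0, nrow = length(snp_ids), ncol = length(genes),
    dimnames = list(snp_ids, genes)
  )
  missing_any <- character()
  for (g in genes) {
    wg <- weights[weights$gene_id == g, , drop = FALSE]
    idx <- match(wg$snp_id, snp_ids)
    if (anyNA(idx)) {
      missing_any <- c(missing_any, g)
      wg <- wg[!is.na(idx), , drop = FALSE]
      idx <- idx[!is.na(idx)]
    }
    if (length(idx) == 0) {
      abort(sprintf("gene '%s' has no weighted SNP in the LD matrix.", g))
    }
    wmat[idx, g] <- wg$weight
  }
  if (length(missing_any) > 0) {
    warn(sprintf(
      "correlation_from_weights_ld: %d gene(s) have weighted SNPs absent from the LD matrix; those SNPs contribute 0.",
      length(missing_any)
    ))
  }
  v <- crossprod(wmat, ld$matrix %*% wmat)
  sdg <- sqrt(diag(v))
  if (any(sdg <= 0)) {
    abort("degenerate predicted-expression variance; exclude such genes upstream.")
  }
  sigma <- v / tcrossprod(sdg)
  diag(sigma) <- 1
  gene_correlation(sigma, genes, provenance = "weights-ld")
}

#' Regularize a gene correlation matrix
#'
#' Guarantees the conditioning the knockoff construction needs. When the
#' smallest eigenvalue of `Sigma` falls below `eig_floor`, the matrix is
#' shrunk linearly toward the identity, `Sigma <- (1 - lambda) * Sigma +
#' lambda * I`, with the smallest `lambda` achieving `eig_floor` (the unit
#' diagonal is preserved by the blend). Linear shrinkage preserves the
#' ordering of correlations, which eigenvalue clipping does not.
#'
#' @param x A [gene_correlation()] (or plain correlation matrix).
#' @param eig_floor Target lower bound for the smallest eigenvalue.
#' @return The regularized [gene_correlation()]; `$shrink` records the
#'   total blend weight applied.
#' @export
regularize_correlation <- function(x, eig_floor = 1e-3) {
  if (!inherits(x, "gene_correlation")) {
    x <- gene_correlation(x, colnames(x) %||% paste0("g", seq_len(ncol(x))))
  }
  lam_min <- min_eigval(x$sigma)
  if (lam_min >= eig_floor) {
    return(x)
  }
  lambda <- (eig_floor - lam_min) / (1 - lam_min)
  sigma <- (1 - lambda) * x$sigma + lambda * diag(nrow(x$sigma))
  gene_correlation(sigma, x$genes,
    provenance = x$provenance,
    shrink = 1 - (1 - x$shrink) * (1 - lambda)
  )
}

#' Write / read a gene correlation matrix as delimited text
#'
#' @param x A [gene_correlation()].
#' @param path Output (input) path; tab-delimited with a gene-id header.
#' @return `write_correlation()` returns `x` invisibly; `read_correlation()`
#'   returns a [gene_correlation()].
#' @export
write_correlation <- function(x, path) {
  df <- tibble::as_tibble(x$sigma)
  readr::write_tsv(df, path)
  invisible(x)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  df <- read_delim_auto(path)
  if (is.character(df[[1]])) df <- df[, -1, drop = FALSE]
  m <- as.matrix(df)
  gene_correlation(m, colnames(df))
}
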