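#' End-to-end knockoff gene selection from summary statistics
#'
#' The full selection workflow on already-read inputs: harmonize weights,
#' summary statistics and LD per gene; compute gene-level Z-scores; build
#' the gene-gene correlation matrix (from an expression matrix, from
#' weights plus a union LD matrix, or supplied directly) and regularize
#' it; generate M ghost knockoff copies of the Z-score vector; and run the
#' knockoff filter at level `alpha`. The S-PrediXcan + BH baseline is
#' computed alongside by default so the two selections can be compared on
#' identical harmonized data.
#'
#' @param sumstats Tibble from [read_sumstats()].
#' @param weights Tibble from [read_weights()].
#' @param ld Named list of per-gene [ld_block()]s.
#' @param expression Optional samples x genes matrix for the gene
#'   correlation (see [correlation_from_expression()]).
#' @param sigma Optional [gene_correlation()] (or matrix with gene-id
#'   dimnames); used as-is when supplied. Exactly one of `expression`,
#'   `sigma`, or `union_ld` must be given.
#' @param union_ld Optional [ld_block()] over the union of SNPs for the
#'   weights-LD correlation estimator
#'   (see [correlation_from_weights_ld()]).
#' @param alpha Target modified-FDR level (default 0.05).
#' @param M Number of knockoff copies (default 5).
#' @param seed Seed for the knockoff draw (selection is reproducible from
#'   it).
#' @param strand_policy See [harmonize()].
#' @param sigma2_y Trait variance (default 1).
#' @param s_method `"sdp"` or `"equi"`.
#' @param alpha_adj BH level of the baseline (default `alpha`).
#' @param baseline Also compute the S-PrediXcan + BH baseline?
#' @param eig_floor Eigenvalue floor for [regularize_correlation()].
#' @return An object of class `twas_gkf` with fields `results` (per-gene
#'   tibble), `excluded` (tibble of excluded genes and reasons),
#'   `selection` (the [knockoff_select()] object), `model`, `threshold`,
#'   `alpha`, `M`, `seed`.
#' @export
twas_gkf <- function(sumstats, weights, ld, expression = NULL, sigma = NULL,
                     union_ld = NULL, alpha = 0.05, M = 5, seed = NULL,
                     strand_policy = c("drop-ambiguous", "keep"),
                     sigma2_y = 1, s_method = c("sdp", "equi"),
                     alpha_adj = alpha, baseline = TRUE, eig_floor = 1e-3) {
  check_alpha(alpha)
  M <- check_m(M)
  s_method <- match.arg(s_method)
  harm <- harmonize_study(weights, sumstats, ld,
    strand_policy = match.arg(strand_policy)
  )
  zs <- gene_zscores(harm$genes, sigma2_y = sigma2_y)
  excluded <- dplyr::bind_rows(harm$excluded, attr(zs, "excluded"))
  if (nrow(zs) < 2) {
    abort("fewer than two usable genes after harmonization and Z-scoring.")
  }
  if (is.null(sigma)) {
    if (!is.null(expression)) {
      sigma <- correlation_from_expression(expression, genes = zs$gene_id)
    } else if (!is.null(union_ld)) {
      sigma <- correlation_from_weights_ld(weights, union_ld,
        genes = zs$gene_id
      )
    } else {
      abort("supply one of `expression`, `sigma` or `union_ld` for the gene correlation.")
    }
  } else if (!inherits(sigma, "gene_correlation")) {
    sigma <- gene_correlation(sigma, colnames(sigma))
  }
  if (!identical(sigma$genes, zs$gene_id)) {
    missing <- setdiff(zs$gene_id, sigma$genes)
    if (length(missing) > 0) {
      abort(sprintf(
        "gene correlation lacks gene(s): %s.",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
    idx <- match(zs$gene_id, sigma$genes)
    sigma <- gene_correlation(
      sigma$sigma[idx, idx, drop = FALSE], zs$gene_id,
      provenance = sigma$provenance, shrink = sigma$shrink
    )
  }
  sigma <- regularize_correlation(sigma, eig_floor = eig_floor)
  model <- knockoff_model(sigma, M = M, s = s_method)
  draw <- sample_knockoffs(
    model, stats::setNames(zs$z, zs$gene_id),
    seed = seed
  )
  sel <- knockoff_select(knockoff_stats(draw), alpha = alpha, M = M)
  results <- dplyr::left_join(
    zs, sel$stats[, c("gene_id", "t_obs", "kappa", "tau", "delta", "selected")],
    by = "gene_id"
  )
  if (baseline) {
    base <- bh_select(
      spredixcan(harm$genes[zs$gene_id], sigma2_y = sigma2_y),
      alpha_adj = alpha_adj
    )
    names(base) <- c(
      "gene_id", "beta_hat", "se_beta", "z_spredixcan", "p",
      "p_adj", "selected_bh"
    )
    results <- dplyr::left_join(results, base, by = "gene_id")
  }
  structure(
    list(
      results = results, excluded = excluded, selection = sel,
      model = model, threshold = sel$threshold, alpha = alpha, M = M,
      seed = seed
    ),
    class = "twas_gkf"
  )
}

#' @export
print.twas_gkf <- function(x, ...) {
  cat(sprintf(
    "<twas_gkf> %d genes, %d selected at alpha = %g (M = %d, threshold = %s)\n",
    nrow(x$results), sum(x$results$selected), x$alpha, x$M,
    format(x$threshold, digits = 4)
  ))
  if (nrow(x$excluded) > 0) {
    cat(sprintf("  %d gene(s) excluded.\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' @export
tidy.twas_gkf <- function(x, ...) x$results

#' @export
glance.twas_gkf <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_excluded = nrow(x$excluded),
    n_selected = sum(x$results$selected),
    n_selected_bh = if ("selected_bh" %in% names(x$results)) {
      sum(x$results$selected_bh, na.rm = TRUE)
    } else {
      NA_integer_
    },
    threshold = x$threshold,
    alpha = x$alpha,
    M = x$M,
    seed = x$seed %||% NA_integer_
  )
}

#' @export
autoplot.twas_gkf <- function(object, ...) {
  autoplot(object$selection, ...)
}

#' Write the selection report of a fit
#'
#' Emits the per-gene selection table as tab-delimited text, preceded by
#' commented run-metadata lines (alpha, M, seed, threshold), plus the
#' excluded-gene table alongside.
#'
#' @param x A [twas_gkf()] fit.
#' @param path Output path for the report; the excluded table goes to
#'   `<path>.excluded.tsv`.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(x, path) {
  meta <- c(
    sprintf("# twasknock selection report"),
    sprintf("# alpha=%g M=%d seed=%s threshold=%s", x$alpha, x$M,
      x$seed %||% "NULL", format(x$threshold, digits = 8)),
    sprintf("# generated=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  writeLines(meta, path)
  readr::write_tsv(x$results, path, append = TRUE, col_names = TRUE)
  if (nrow(x$excluded) > 0) {
    readr::write_tsv(x$excluded, paste0(path, ".excluded.tsv"))
  }
  invisible(path)
}
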