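#' Knockoff statistics per gene
#'
#' Computes the importance scores `T_g = Z_g^2` and `Ttilde_g^m =
#' (Ztilde_g^m)^2`, then per gene:
#' * `kappa`: the index (0 = original, 1..M = knockoff copy) attaining the
#'   largest importance score; ties are resolved toward a knockoff index,
#'   the conservative direction.
#' * `tau`: the difference between the largest of the M + 1 importance
#'   scores and the median of the remaining M (for even M, the mean of
#'   the two middle order statistics). `tau` is a symmetric function of
#'   the copies, which is what makes the count-based false discovery
#'   proportion estimate of [knockoff_threshold()] valid; for genes with
#'   `kappa == 0` it equals `T_g - median_m(Ttilde_g^m)`, and for M = 1
#'   the filter reduces exactly to the model-X knockoff filter.
#' * `delta`: the GReX feature statistic,
#'   `(T_g - median_m(Ttilde_g^m))` when the original attains the
#'   maximum (`kappa == 0`) and 0 otherwise; on selectable genes it
#'   coincides with `tau`.
#'
#' @param z Numeric vector of gene Z-scores, or a [sample_knockoffs()]
#'   draw (in which case `z_knock` is taken from it).
#' @param z_knock D x M matrix of knockoff Z-scores.
#' @param genes Optional gene ids (default: names of `z` or g1..gD).
#' @return A tibble of class `knockoff_stats` with columns `gene_id`,
#'   `z`, `t_obs`, `kappa`, `tau`, `delta`; the M knockoff importance
#'   scores are attached as the `t_knock` attribute (D x M matrix).
#' @export
knockoff_stats <- function(z, z_knock = NULL, genes = NULL) {
  if (inherits(z, "knockoff_draw")) {
    z_knock <- z$z_knock
    z <- z$z
  }
  z_knock <- as.matrix(z_knock)
  if (length(z) != nrow(z_knock)) {
    abort("`z` and `z_knock` must cover the same genes.")
  }
  genes <- genes %||% names(z) %||% rownames(z_knock) %||%
    paste0("g", seq_along(z))
  t_obs <- z^2
  t_knock <- z_knock^2
  scores <- cbind(t_obs, t_knock)
  # ties.method = "last" sends exact ties to the highest (knockoff) index
  kappa <- max.col(scores, ties.method = "last") - 1L
  tau <- apply(scores, 1L, function(r) {
    srt <- sort(r, decreasing = TRUE)
    srt[1L] - median(srt[-1L])
  })
  delta <- ifelse(kappa == 0L, t_obs - apply(t_knock, 1L, median), 0)
  out <- tibble::tibble(
    gene_id = genes, z = as.numeric(z), t_obs = t_obs,
    kappa = kappa, tau = tau, delta = delta
  )
  attr(out, "t_knock") <- t_knock
  class(out) <- c("knockoff_stats", class(out))
  out
}

#' Data-dependent selection threshold
#'
#' The smallest candidate threshold `t` (over the observed positive `tau`
#' values) at which the estimated false discovery proportion
#' `(1/M + #\{kappa >= 1, tau >= t\} / M) / max(1, #\{kappa == 0, tau >= t\})`
#' does not exceed `alpha`. Returns `Inf` when no candidate qualifies
#' (empty selection). The denominator guard `max(1, .)` avoids the
#' division by zero the bare formula allows.
#'
#' @param stats A [knockoff_stats()] tibble (columns `kappa`, `tau`).
#' @param alpha Target modified-FDR level in (0, 1).
#' @param M Number of knockoff copies the statistics were computed with.
#' @return A single number: the threshold, or `Inf`.
#' @export
knockoff_threshold <- function(stats, alpha, M) {
  check_alpha(alpha)
  M <- check_m(M)
  if (nrow(stats) == 0) abort("`stats` is empty.")
  kappa <- stats$kappa
  tau <- stats$tau
  candidates <- sort(unique(tau[tau > 0]))
  for (t in candidates) {
    fdp <- (1 / M + sum(kappa >= 1L & tau >= t) / M) /
      max(1, sum(kappa == 0L & tau >= t))
    if (fdp <= alpha) {
      return(t)
    }
  }
  Inf
}

#' Select genes with the knockoff filter
#'
#' Applies [knockoff_threshold()] and selects the genes whose GReX feature
#' statistic reaches it: `delta >= t_hat`, equivalently `kappa == 0` and
#' `tau >= t_hat`.
#'
#' @inheritParams knockoff_threshold
#' @return An object of class `knockoff_selection`: the stats tibble with
#'   a logical `selected` column, plus fields `threshold`, `alpha`, `M`
#'   and `fdp_est` (the estimated FDP at the threshold).
#' @export
knockoff_select <- function(stats, alpha = 0.05, M) {
  t_hat <- knockoff_threshold(stats, alpha, M)
  res <- dplyr::mutate(
    tibble::as_tibble(stats),
    selected = .data$delta >= t_hat & .data$kappa == 0L
  )
  fdp_est <- if (is.finite(t_hat)) {
    (1 / M + sum(stats$kappa >= 1L & stats$tau >= t_hat) / M) /
      max(1, sum(stats$kappa == 0L & stats$tau >= t_hat))
  } else {
    0
  }
  structure(
    list(
      stats = res, threshold = t_hat, alpha = alpha, M = as.integer(M),
      fdp_est = fdp_est
    ),
    class = "knockoff_selection"
  )
}

#' @export
print.knockoff_selection <- function(x, ...) {
  cat(sprintf(
    "<knockoff_selection> %d of %d genes selected (alpha = %g, M = %d, threshold = %s)\n",
    sum(x$stats$selected), nrow(x$stats), x$alpha, x$M,
    format(x$threshold, digits = 4)
  ))
  invisible(x)
}

#' @export
tidy.knockoff_selection <- function(x, ...) x$stats

#' @export
glance.knockoff_selection <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$stats), n_selected = sum(x$stats$selected),
    threshold = x$threshold, fdp_est = x$fdp_est, alpha = x$alpha, M = x$M
  )
}

#' @export
autoplot.knockoff_selection <- function(object, ...) {
  df <- dplyr::mutate(object$stats, index = dplyr::row_number())
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$index, y = .data$delta, colour = .data$selected)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#D55E00")) +
    ggplot2::labs(
      x = "gene index", y = "GReX feature statistic",
      colour = "selected",
      title = sprintf(
        "Knockoff selection (alpha = %g, M = %d)", object$alpha, object$M
      )
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = object$threshold, linetype = "dashed"
    )
  }
  p
}

#' Evaluate a selection against simulation truth
#'
#' Computes the per-replicate contributions to the modified false
#' discovery rate, `#false / (#selected + 1/alpha)`, and the true positive
#' proportion, `#true / #causal`. Study-level mFDR and TPP are means of
#' these over replicates.
#'
#' @param selection A [knockoff_select()] result, or a character vector of
#'   selected gene ids.
#' @param causal Character vector of truly causal gene ids (H1).
#' @param alpha The nominal level entering the mFDR denominator.
#' @return A one-row tibble: `n_selected`, `n_false`, `n_true`, `mfdr`,
#'   `tpp` (`tpp` is `NA` when `causal` is empty).
#' @export
evaluate_selection <- function(selection, causal, alpha = 0.05) {
  check_alpha(alpha)
  selected <- if (inherits(selection, "knockoff_selection")) {
    selection$stats$gene_id[selection$stats$selected]
  } else {
    as.character(selection)
  }
  n_false <- length(setdiff(selected, causal))
  n_true <- length(intersect(selected, causal))
  tibble::tibble(
    n_selected = length(selected),
    n_false = n_false,
    n_true = n_true,
    mfdr = n_false / (length(selected) + 1 / alpha),
    tpp = if (length(causal) > 0) n_true / length(causal) else NA_real_
  )
}
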