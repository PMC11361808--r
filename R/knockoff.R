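#' Equicorrelated knockoff diagonal
#'
#' Closed-form feasible solution of the multiple-knockoff convex program:
#' all entries of `s` equal `min(1, (M + 1) / M * lambda_min(Sigma))`. It
#' satisfies `((M + 1) / M) Sigma - diag(s) >= 0` and `s >= 0` exactly and
#' serves both as a cheap construction for large problems and as the
#' feasible starting point of [solve_s_sdp()].
#'
#' @param sigma Gene correlation matrix (or [gene_correlation()]).
#' @param M Number of knockoff copies.
#' @return Numeric vector `s` of length D.
#' @export
solve_s_equi <- function(sigma, M = 1) {
  M <- check_m(M)
  sigma <- as_sigma_matrix(sigma)
  lam_min <- min_eigval(sigma)
  if (lam_min <= 0) {
    abort("`sigma` must be positive definite; regularize_correlation() first.")
  }
  rep(min(1, (M + 1) / M * lam_min), nrow(sigma))
}

as_sigma_matrix <- function(sigma) {
  if (inherits(sigma, "gene_correlation")) sigma$sigma else as.matrix(sigma)
}

#' Per-gene knockoff diagonal by coordinate ascent on the SDP
#'
#' Minimizes `sum(|1 - s_g|)` subject to
#' `((M + 1) / M) Sigma - diag(s) >= 0` and `s >= 0`, i.e. pushes every
#' `s_g` as close to 1 as the semidefinite constraint allows. No conic
#' solver is assumed: starting from the feasible equicorrelated solution,
#' each coordinate is raised to the largest value keeping
#' `B = ((M + 1) / M) Sigma - diag(s)` positive definite (the Schur
#' complement bound `1 / B^{-1}[g, g]`), with rank-one inverse updates
#' inside a sweep and a fresh factorization between sweeps. The ascent is
#' monotone, so the objective never exceeds the equicorrelated one. A
#' final eigenvalue check shrinks `s` by a scalar if the constraint is
#' violated numerically.
#'
#' @inheritParams solve_s_equi
#' @param max_sweeps Maximum coordinate sweeps.
#' @param tol Stop when a full sweep improves the objective by less.
#' @param d_max Above this dimension fall back to [solve_s_equi()] (the
#'   guarantee is identical, power lower, runtime bounded).
#' @return Numeric vector `s` of length D.
#' @export
solve_s_sdp <- function(sigma, M = 1, max_sweeps = 25, tol = 1e-5,
                        d_max = 2000) {
  M <- check_m(M)
  sigma <- as_sigma_matrix(sigma)
  d <- nrow(sigma)
  s_equi <- solve_s_equi(sigma, M)
  if (d > d_max) {
    inform(sprintf(
      "solve_s_sdp: D = %d exceeds d_max = %d; using the equicorrelated solution.",
      d, d_max
    ))
    return(s_equi)
  }
  a <- (M + 1) / M * sigma
  # Start from the strictly feasible interior point s = 0. Raising a
  # coordinate all the way to its Schur-complement bound 1 / B^{-1}[g, g]
  # makes B singular and freezes every other coordinate, so each sweep
  # only takes a fixed fraction of the available slack; the iterates stay
  # strictly feasible and converge to a balanced maximal point.
  s <- numeric(d)
  damping <- 0.6
  for (sweep in seq_len(max_sweeps)) {
    ch <- tryCatch(chol(a - diag(s, d)), error = function(e) NULL)
    # the iterates approach the semidefinite boundary; a failed
    # factorization just means the ascent has converged onto it
    if (is.null(ch)) break
    binv <- chol2inv(ch)
    gained <- 0
    for (g in seq_len(d)) {
      slack <- 1 / binv[g, g]
      if (!is.finite(slack) || slack <= 1e-9) next
      delta <- min(1 - s[g], damping * slack)
      if (delta <= 1e-12) next
      s[g] <- s[g] + delta
      u <- binv[, g]
      binv <- binv + (delta / (1 - delta * u[g])) * tcrossprod(u)
      gained <- gained + delta
    }
    if (gained < tol * d) break
  }
  # Numerical PSD repair, then keep whichever of {ascent, equi} is better.
  lam <- min_eigval(a - diag(s, d))
  while (lam < -1e-8) {
    s <- s * (1 - 1e-6)
    lam <- min_eigval(a - diag(s, d))
  }
  if (sum(s) >= sum(s_equi)) s else s_equi
}

#' Knockoff sampling model for gene Z-scores
#'
#' Assembles everything needed to draw M exchangeable Gaussian knockoff
#' copies of the gene Z-score vector: `Theta = I - Phi Sigma^{-1}` (the
#' conditional-mean map `Ztilde_m = Theta Z + Lambda_m`), the noise
#' diagonal block `V = 2 Phi - Phi Sigma^{-1} Phi`, the cross-copy block
#' `C = Phi - Phi Sigma^{-1} Phi`, and square-root factors for sampling.
#' The joint covariance of `(Z, Ztilde_1, ..., Ztilde_M)` has pattern
#' `Cov(Z) = Cov(Ztilde_m) = Sigma` and `Sigma - Phi` on every off block,
#' which is positive semidefinite exactly when
#' `((M + 1) / M) Sigma - Phi >= 0` -- the constraint of the `s` program.
#'
#' @param sigma A [gene_correlation()] or correlation matrix.
#' @param M Number of knockoff copies (default 5).
#' @param s `"sdp"`, `"equi"`, or a numeric feasible vector.
#' @param tol Numerical PSD tolerance for the feasibility checks.
#' @return An object of class `knockoff_model`.
#' @export
knockoff_model <- function(sigma, M = 5, s = c("sdp", "equi"), tol = 1e-8) {
  M <- check_m(M)
  genes <- if (inherits(sigma, "gene_correlation")) {
    sigma$genes
  } else {
    colnames(sigma) %||% paste0("g", seq_len(ncol(sigma)))
  }
  sig <- as_sigma_matrix(sigma)
  if (is.character(s)) {
    s <- switch(match.arg(s),
      sdp = solve_s_sdp(sig, M),
      equi = solve_s_equi(sig, M)
    )
  }
  d <- nrow(sig)
  if (length(s) != d || any(s < 0)) {
    abort("`s` must be a non-negative vector of length D.")
  }
  lam <- min_eigval((M + 1) / M * sig - diag(s, d))
  if (lam < -tol) {
    abort(sprintf(
      "infeasible s: smallest eigenvalue of ((M+1)/M) Sigma - diag(s) is %.3g.",
      lam
    ))
  }
  sig_inv <- chol2inv(chol(sig))
  phi_sinv <- s * sig_inv # Phi %*% Sigma^{-1}
  quad <- phi_sinv %*% diag(s, d) # Phi Sigma^{-1} Phi
  theta <- diag(d) - phi_sinv
  v <- diag(2 * s, d) - quad
  cc <- diag(s, d) - quad
  # Factorization of the joint noise: common part (C + Phi/M) plus
  # per-copy deviations with covariance Phi (I - J/M); valid for any
  # feasible s even when C itself is indefinite.
  sqrt_common <- sqrtm_psd(cc + diag(s / M, d), tol = tol)
  structure(
    list(
      sigma = sig, genes = genes, M = M, s = s, theta = theta,
      v = v, c = cc, sqrt_common = sqrt_common, sqrt_phi = sqrt(s),
      tol = tol
    ),
    class = "knockoff_model"
  )
}

#' @export
print.knockoff_model <- function(x, ...) {
  cat(sprintf(
    "<knockoff_model> D = %d genes, M = %d copies, mean s = %.3f\n",
    length(x$genes), x$M, mean(x$s)
  ))
  invisible(x)
}

#' Joint covariance of the original and knockoff Z-scores
#'
#' Assembles the (M + 1)D x (M + 1)D target covariance of
#' `(Z, Ztilde_1, ..., Ztilde_M)` implied by a [knockoff_model()]; useful
#' for validation.
#'
#' @param model A [knockoff_model()].
#' @return A square matrix of dimension `(M + 1) * D`.
#' @export
knockoff_joint_covariance <- function(model) {
  d <- nrow(model$sigma)
  m1 <- model$M + 1L
  off <- model$sigma - diag(model$s, d)
  out <- matrix(0, m1 * d, m1 * d)
  for (i in seq_len(m1)) {
    for (j in seq_len(m1)) {
      block <- if (i == j) model$sigma else off
      out[(i - 1) * d + seq_len(d), (j - 1) * d + seq_len(d)] <- block
    }
  }
  out
}

#' Sample ghost knockoff copies of a Z-score vector
#'
#' Draws `Ztilde_m = Theta Z + Lambda_m`, m = 1..M, where the stacked
#' noise `(Lambda_1, ..., Lambda_M)` is jointly Gaussian with diagonal
#' blocks `V` and cross blocks `C`. The implementation draws a common
#' component with covariance `C + Phi / M` and per-copy deviations
#' `Phi^{1/2} (eps_m - mean(eps))`, which reproduces the block covariance
#' for any feasible `s`. The knockoffs are a function of `Z` and
#' exogenous noise only, so conditional independence from the phenotype
#' given `Z` holds by construction.
#'
#' @param model A [knockoff_model()].
#' @param z Numeric vector of gene Z-scores (length D), or a matrix with
#'   D columns to sample knockoffs for many Z vectors at once.
#' @param seed Optional integer; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return For vector `z`: an object of class `knockoff_draw` with fields
#'   `z`, `z_knock` (D x M matrix), `seed`. For matrix `z` (n x D): an
#'   n x D x M array.
#' @export
sample_knockoffs <- function(model, z, seed = NULL) {
  draw <- function() {
    if (is.matrix(z)) {
      gk_sample_many(model, z)
    } else {
      zk <- gk_sample_many(model, matrix(z, nrow = 1L))[1L, , , drop = TRUE]
      zk <- matrix(zk, ncol = model$M,
        dimnames = list(model$genes, paste0("knock", seq_len(model$M)))
      )
      structure(list(z = z, z_knock = zk, seed = seed),
        class = "knockoff_draw"
      )
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Vectorized sampler: z is n x D; returns n x D x M.
gk_sample_many <- function(model, z) {
  n <- nrow(z)
  d <- ncol(z)
  if (d != nrow(model$sigma)) {
    abort(sprintf("`z` has %d columns but the model has D = %d.", d,
      nrow(model$sigma)))
  }
  if (any(!is.finite(z))) abort("`z` must be finite.")
  m <- model$M
  mean_part <- z %*% t(model$theta)
  common <- matrix(rnorm(n * d), n, d) %*% model$sqrt_common
  eps <- array(rnorm(n * d * m), dim = c(n, d, m))
  eps_bar <- rowMeans(eps, dims = 2L)
  out <- array(0, dim = c(n, d, m))
  for (k in seq_len(m)) {
    dev <- matrix(eps[, , k], n, d) - eps_bar
    dev <- sweep(dev, 2L, model$sqrt_phi, "*")
    out[, , k] <- mean_part + common + dev
  }
  out
}
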