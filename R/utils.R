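# Internal helpers shared across modules.

# Detect the field separator of a delimited text file from its header line.
guess_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else " "
}

read_delim_auto <- function(path) {
  readr::read_delim(path,
    delim = guess_delim(path), show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
}

check_alpha <- function(alpha, what = "alpha") {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
    alpha <= 0 || alpha >= 1) {
    abort(sprintf("`%s` must be a single number in (0, 1), got %s.", what,
      paste(format(alpha), collapse = ", ")))
  }
  invisible(alpha)
}

check_m <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1 ||
    m != round(m)) {
    abort("`M` must be a single integer >= 1.")
  }
  as.integer(m)
}

# Symmetric PSD matrix square root; eigenvalues in [-tol, 0) are clipped to 0.
sqrtm_psd <- function(x, tol = 1e-8) {
  e <- eigen((x + t(x)) / 2, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -tol)) {
    abort(sprintf(
      "matrix is not positive semidefinite (smallest eigenvalue %.3g).",
      min(lam)
    ))
  }
  lam[lam < 0] <- 0
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

min_eigval <- function(x) {
  min(eigen((x + t(x)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
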