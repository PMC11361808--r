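# Small in-code fixtures shared across test files.

make_sumstats <- function(...) {
  tibble::tibble(...)
}

# Three well-behaved SNPs on two genes, allele coding consistent.
toy_sumstats <- function() {
  tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "A"),
    other_allele = c("G", "G", "C"),
    beta = c(0.2, -0.1, 0.05),
    se = c(0.05, 0.04, 0.05),
    n = 1000
  )
}

toy_weights <- function() {
  tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "A"),
    other_allele = c("G", "G", "C"),
    weight = c(0.5, -0.3, 0.8)
  )
}

toy_ld <- function() {
  list(
    g1 = ld_block("g1", c("rs1", "rs2"),
      matrix(c(1, 0.3, 0.3, 1), 2),
      dialect = "correlation"
    ),
    g2 = ld_block("g2", "rs3", matrix(1), dialect = "correlation")
  )
}

write_tsv_tmp <- function(df, name) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path)
  path
}

# Random positive-definite correlation matrix.
random_corr <- function(d, seed = NULL, strength = 1) {
  draw <- function() {
    a <- matrix(rnorm(d * 2 * d), 2 * d, d) * strength
    cov2cor(crossprod(a) + diag(d))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Tiny simulation world for fast end-to-end tests.
small_config <- function(...) {
  sim_config(
    n = 800, n_genes = 30, snps_per_gene = 6, shared_snps = 1,
    nonzero_weights = 2, ...
  )
}
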