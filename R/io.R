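#' Column mappings for summary-statistic and weight files
#'
#' GWAS summary-statistic dialects vary widely, so every reader takes a
#' column map: a named list whose names are the canonical column names used
#' internally and whose values are the column names found in the file.
#'
#' @param snp_id,effect_allele,other_allele,beta,se,n,gene_id,weight Column
#'   names in the file for each canonical field.
#' @return A named list usable as the `col_map` argument of [read_sumstats()]
#'   or [read_weights()].
#' @examples
#' sumstat_cols(beta = "BETA", se = "SE")
#' @export
sumstat_cols <- function(snp_id = "snp", effect_allele = "a1",
                         other_allele = "a2", beta = "beta", se = "se",
                         n = "n") {
  list(
    snp_id = snp_id, effect_allele = effect_allele,
    other_allele = other_allele, beta = beta, se = se, n = n
  )
}

#' @rdname sumstat_cols
#' @export
weight_cols <- function(gene_id = "gene_id", snp_id = "snp_id",
                        effect_allele = "a1", other_allele = "a2",
                        weight = "weight") {
  list(
    gene_id = gene_id, snp_id = snp_id, effect_allele = effect_allele,
    other_allele = other_allele, weight = weight
  )
}

map_columns <- function(df, col_map, path) {
  missing <- setdiff(unlist(col_map), names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "file '%s' is missing required column(s): %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
  out <- df[, unlist(col_map), drop = FALSE]
  names(out) <- names(col_map)
  tibble::as_tibble(out)
}

VALID_ALLELES <- c("A", "C", "G", "T")

# A lone "T" allele column is parsed as logical by delimited-text readers.
normalize_allele <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "T", "F")
  toupper(as.character(x))
}

#' Read GWAS summary statistics
#'
#' Reads per-SNP marginal association statistics from a tab- or
#' comma-delimited text file with a header. Rows with missing or non-finite
#' required fields, non-positive standard errors, or alleles outside
#' A/C/G/T are dropped; the number of dropped rows is reported and attached
#' as the `n_dropped` attribute.
#'
#' @param path Path to a delimited text file.
#' @param col_map Column mapping, see [sumstat_cols()].
#' @return A tibble with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `beta` (marginal per-allele effect), `se`, `n`.
#' @export
read_sumstats <- function(path, col_map = sumstat_cols()) {
  df <- map_columns(read_delim_auto(path), col_map, path)
  df$effect_allele <- normalize_allele(df$effect_allele)
  df$other_allele <- normalize_allele(df$other_allele)
  keep <- !is.na(df$snp_id) & nzchar(df$snp_id) &
    df$effect_allele %in% VALID_ALLELES &
    df$other_allele %in% VALID_ALLELES &
    is.finite(df$beta) & is.finite(df$se) & df$se > 0 &
    is.finite(df$n) & df$n > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf(
      "read_sumstats: dropped %d of %d rows failing field checks.",
      n_dropped, nrow(df)
    ))
  }
  out <- df[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read per-gene expression-imputation weights
#'
#' Reads SNP-to-expression weights (one row per gene/SNP pair) from
#' delimited text. Covers PredictDB-style exports after conversion to text.
#'
#' @param path Path to a delimited text file.
#' @param col_map Column mapping, see [weight_cols()].
#' @return A tibble with columns `gene_id`, `snp_id`, `effect_allele`,
#'   `other_allele`, `weight`, with the `n_dropped` attribute as in
#'   [read_sumstats()].
#' @export
read_weights <- function(path, col_map = weight_cols()) {
  df <- map_columns(read_delim_auto(path), col_map, path)
  df$effect_allele <- normalize_allele(df$effect_allele)
  df$other_allele <- normalize_allele(df$other_allele)
  keep <- !is.na(df$gene_id) & nzchar(df$gene_id) &
    !is.na(df$snp_id) & nzchar(df$snp_id) &
    df$effect_allele %in% VALID_ALLELES &
    df$other_allele %in% VALID_ALLELES &
    is.finite(df$weight)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf(
      "read_weights: dropped %d of %d rows failing field checks.",
      n_dropped, nrow(df)
    ))
  }
  out <- df[keep, , drop = FALSE]
  dup <- duplicated(out[, c("gene_id", "snp_id")])
  if (any(dup)) {
    warn(sprintf("read_weights: removed %d duplicate (gene, snp) rows.",
      sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-gene linkage-disequilibrium block
#'
#' Constructor for an LD block: the SNP-by-SNP covariance or correlation
#' matrix of a gene's variants in a fixed SNP order. The matrix is
#' symmetrized as `(M + t(M)) / 2`; a warning is issued when the maximum
#' asymmetry exceeds `1e-6`. SNPs with a non-positive diagonal entry are
#' recorded in the `degenerate_snps` field.
#'
#' @param gene_id Gene identifier.
#' @param snp_ids Character vector of SNP identifiers in matrix order.
#' @param matrix Square numeric matrix of LD values.
#' @param dialect `"correlation"` or `"covariance"`; `"auto"` declares the
#'   block a correlation matrix when all diagonal entries are 1 within
#'   `1e-6`, otherwise a covariance matrix.
#' @return An object of class `ld_block` with fields `gene_id`, `snp_ids`,
#'   `matrix`, `dialect`, `degenerate_snps`.
#' @export
ld_block <- function(gene_id, snp_ids, matrix,
                     dialect = c("auto", "correlation", "covariance")) {
  dialect <- match.arg(dialect)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix) || nrow(matrix) != length(snp_ids)) {
    abort("LD matrix dimensions must match the number of SNP ids.")
  }
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-6) {
    warn(sprintf(
      "LD matrix for gene '%s' has asymmetry %.3g; symmetrizing.",
      gene_id, asym
    ))
  }
  matrix <- (matrix + t(matrix)) / 2
  dimnames(matrix) <- list(snp_ids, snp_ids)
  if (dialect == "auto") {
    dialect <- if (all(abs(diag(matrix) - 1) < 1e-6)) "correlation" else "covariance"
  }
  degenerate <- snp_ids[diag(matrix) <= 0]
  structure(
    list(
      gene_id = gene_id, snp_ids = as.character(snp_ids), matrix = matrix,
      dialect = dialect, degenerate_snps = degenerate
    ),
    class = "ld_block"
  )
}

#' @export
print.ld_block <- function(x, ...) {
  cat(sprintf(
    "<ld_block> gene %s: %d SNPs (%s)\n", x$gene_id, length(x$snp_ids),
    x$dialect
  ))
  invisible(x)
}

#' Read a per-gene LD matrix from delimited text
#'
#' The expected layout is a header row of SNP identifiers followed by the
#' square numeric matrix; an optional leading identifier column (matching
#' the header) is accepted and dropped.
#'
#' @param path Path to the delimited matrix file.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @inheritParams ld_block
#' @return An [ld_block()] object.
#' @export
read_ld <- function(path, gene_id = NULL,
                    dialect = c("auto", "correlation", "covariance")) {
  default_id <- sub("\\.(tsv|csv|txt)$", "", basename(path))
  default_id <- sub("\\.ld$", "", default_id)
  gene_id <- gene_id %||% default_id
  df <- read_delim_auto(path)
  if (is.character(df[[1]]) || is.factor(df[[1]])) {
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  ld_block(gene_id, colnames(df), m, dialect = match.arg(dialect))
}

#' Read a samples-by-genes expression matrix
#'
#' Delimited text with a header of gene identifiers; an optional first
#' character column is used as sample identifiers.
#'
#' @param path Path to the delimited file.
#' @return A numeric matrix (samples in rows, genes in columns).
#' @export
read_expression <- function(path) {
  df <- read_delim_auto(path)
  rn <- NULL
  if (is.character(df[[1]]) || is.factor(df[[1]])) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  rownames(m) <- rn
  storage.mode(m) <- "double"
  m
}

#' Aligned per-gene data
#'
#' Container for the harmonized triple a gene-level test needs: weights,
#' SNP summary statistics and the LD block, all in one shared SNP order.
#' Usually produced by [harmonize()]; the constructor is exported so that
#' simulated studies can build it directly.
#'
#' @param gene_id Gene identifier.
#' @param snps Tibble with columns `snp_id`, `weight`, `beta`, `se`, `n`
#'   (`se` may be `NA` when it is to be recovered from moments).
#' @param ld Square LD matrix over the same SNPs in the same order.
#' @param dialect LD dialect, `"correlation"` or `"covariance"`.
#' @return An object of class `gene_data`.
#' @export
gene_data <- function(gene_id, snps, ld, dialect = "correlation") {
  ld <- as.matrix(ld)
  if (nrow(snps) != nrow(ld)) {
    abort("`snps` and `ld` must cover the same SNPs in the same order.")
  }
  structure(
    list(
      gene_id = gene_id, snps = snps, ld = ld, dialect = dialect,
      usable = nrow(snps) > 0
    ),
    class = "gene_data"
  )
}

#' @export
print.gene_data <- function(x, ...) {
  cat(sprintf(
    "<gene_data> gene %s: %d aligned SNPs%s\n", x$gene_id, nrow(x$snps),
    if (x$usable) "" else " (unusable)"
  ))
  invisible(x)
}

#' @export
tidy.gene_data <- function(x, ...) {
  dplyr::mutate(x$snps, gene_id = x$gene_id, .before = 1L)
}

ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_ambiguous_pair <- function(a1, a2) ALLELE_COMPLEMENT[a1] == a2

#' Harmonize weights, summary statistics and LD for one gene
#'
#' Restricts all three inputs to their common SNP set and reconciles allele
#' coding between the weight set and the summary statistics. When the
#' effect/other alleles are swapped (directly or on the opposite strand)
#' the sign of the GWAS effect is flipped; irreconcilable allele pairs are
#' dropped. Strand-ambiguous SNPs (A/T or C/G pairs) are dropped under the
#' default policy because their orientation cannot be inferred from allele
#' labels alone.
#'
#' @param weights Tibble of weights for a single gene (see [read_weights()]).
#' @param sumstats Tibble of summary statistics (see [read_sumstats()]).
#' @param ld [ld_block()] for the gene.
#' @param strand_policy `"drop-ambiguous"` (default) or `"keep"`.
#' @return A [gene_data()] object; when no SNP survives, the object has
#'   zero rows and `usable = FALSE` (callers exclude it, this is not an
#'   error). The number of dropped SNPs by reason is attached as the
#'   `dropped` attribute.
#' @examples
#' w <- tibble::tibble(
#'   gene_id = "g1", snp_id = "rs1", effect_allele = "A",
#'   other_allele = "G", weight = 0.5
#' )
#' ss <- tibble::tibble(
#'   snp_id = "rs1", effect_allele = "G", other_allele = "A",
#'   beta = 0.2, se = 0.05, n = 1000
#' )
#' ld <- ld_block("g1", "rs1", matrix(1))
#' harmonize(w, ss, ld)$snps$beta # sign flipped to -0.2
#' @export
harmonize <- function(weights, sumstats, ld,
                      strand_policy = c("drop-ambiguous", "keep")) {
  strand_policy <- match.arg(strand_policy)
  gene_id <- unique(weights$gene_id)
  if (length(gene_id) > 1) {
    abort("`weights` contains several genes; use harmonize_study().")
  }
  if (length(gene_id) == 0) gene_id <- ld$gene_id

  common <- intersect(intersect(weights$snp_id, sumstats$snp_id), ld$snp_ids)
  dropped <- c(ambiguous = 0L, irreconcilable = 0L)
  w <- weights[match(common, weights$snp_id), , drop = FALSE]
  s <- sumstats[match(common, sumstats$snp_id), , drop = FALSE]

  if (length(common) > 0) {
    amb <- is_ambiguous_pair(w$effect_allele, w$other_allele) |
      is_ambiguous_pair(s$effect_allele, s$other_allele)
    if (strand_policy == "drop-ambiguous" && any(amb)) {
      dropped[["ambiguous"]] <- sum(amb)
      w <- w[!amb, , drop = FALSE]
      s <- s[!amb, , drop = FALSE]
    }
  }

  sign <- rep(NA_real_, nrow(w))
  if (nrow(w) > 0) {
    direct <- s$effect_allele == w$effect_allele &
      s$other_allele == w$other_allele
    swapped <- s$effect_allele == w$other_allele &
      s$other_allele == w$effect_allele
    flip_direct <- ALLELE_COMPLEMENT[s$effect_allele] == w$effect_allele &
      ALLELE_COMPLEMENT[s$other_allele] == w$other_allele
    flip_swapped <- ALLELE_COMPLEMENT[s$effect_allele] == w$other_allele &
      ALLELE_COMPLEMENT[s$other_allele] == w$effect_allele
    sign[direct | flip_direct] <- 1
    sign[(swapped | flip_swapped) & is.na(sign)] <- -1
  }
  ok <- !is.na(sign)
  dropped[["irreconcilable"]] <- sum(!ok)
  if (any(!ok)) {
    inform(sprintf(
      "harmonize: gene %s: dropped %d SNP(s) with irreconcilable alleles.",
      gene_id, sum(!ok)
    ))
  }
  w <- w[ok, , drop = FALSE]
  s <- s[ok, , drop = FALSE]
  sign <- sign[ok]

  snps <- tibble::tibble(
    snp_id = w$snp_id,
    weight = w$weight,
    beta = sign * s$beta,
    se = s$se,
    n = s$n
  )
  idx <- match(snps$snp_id, ld$snp_ids)
  out <- gene_data(gene_id, snps, ld$matrix[idx, idx, drop = FALSE],
    dialect = ld$dialect
  )
  attr(out, "dropped") <- dropped
  out
}

#' Harmonize a whole study
#'
#' Applies [harmonize()] gene by gene over a multi-gene weight table and a
#' named list of LD blocks.
#'
#' @inheritParams harmonize
#' @param weights Tibble of weights for all genes.
#' @param ld_list Named list of [ld_block()]s, names matching `gene_id`s.
#' @return A list with `genes` (named list of usable [gene_data()]) and
#'   `excluded` (tibble of gene ids with exclusion reasons).
#' @export
harmonize_study <- function(weights, sumstats, ld_list,
                            strand_policy = c("drop-ambiguous", "keep")) {
  strand_policy <- match.arg(strand_policy)
  by_gene <- split(weights, weights$gene_id)
  genes <- list()
  excluded <- list()
  for (g in names(by_gene)) {
    ld <- ld_list[[g]]
    if (is.null(ld)) {
      excluded[[g]] <- "no LD block"
      next
    }
    gd <- harmonize(by_gene[[g]], sumstats, ld, strand_policy = strand_policy)
    if (!gd$usable) {
      excluded[[g]] <- "empty SNP intersection after harmonization"
    } else {
      genes[[g]] <- gd
    }
  }
  list(
    genes = genes,
    excluded = tibble::tibble(
      gene_id = names(excluded),
      reason = unlist(excluded) %||% character()
    )
  )
}
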