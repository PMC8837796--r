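# Expression preprocessing: transcript filtering, log2 + quantile
# normalization, and latent-factor residualization producing the eQTL
# phenotype.

#' Filter transcripts by expression and variability
#'
#' Retains transcripts expressed (TPM > `tpm_min`) in at least
#' `min_lines` accessions whose TPM standard deviation exceeds `sd_min`.
#'
#' @param e An [expression_matrix].
#' @param tpm_min,min_lines,sd_min Thresholds.
#' @return Filtered [expression_matrix].
#' @export
filter_transcripts <- function(e, tpm_min = 0.5, min_lines = 3,
                               sd_min = 0.5) {
  stopifnot(is_expression_matrix(e))
  n_expr <- rowSums(e$tpm > tpm_min, na.rm = TRUE)
  sds <- apply(e$tpm, 1, sd, na.rm = TRUE)
  keep <- n_expr >= min_lines & sds > sd_min
  expression_matrix(e$tpm[keep, , drop = FALSE],
                    gene_id = unname(e$genes[keep]))
}

#' Log2 transform and quantile-normalize expression across accessions
#'
#' Values become log2(1 + TPM); each accession's sorted values are then
#' replaced by the cross-accession mean of the order statistics (standard
#' quantile normalization; ties receive the mean of the quantiles they
#' span, via limma).
#'
#' @param e An [expression_matrix].
#' @return [expression_matrix] of normalized log2 values (no longer TPM;
#'   the non-negativity of the container still holds since log2(1+x) >= 0
#'   for x >= 0).
#' @export
normalize_expression <- function(e) {
  stopifnot(is_expression_matrix(e))
  m <- log2(1 + e$tpm)
  m <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(m) <- dimnames(e$tpm)
  expression_matrix(m, gene_id = unname(e$genes))
}

#' Remove hidden expression factors by PCA residualization
#'
#' Latent-factor residualization of the normalized expression matrix: each
#' transcript is regressed on the top-k principal factors of the
#' accession-by-transcript matrix and replaced by its residual. This is
#' the package's deterministic latent-factor correction (the role PEER
#' plays in population transcriptomics pipelines); k = 0 returns the
#' mean-centered input.
#'
#' @param e An [expression_matrix] of normalized values, or a plain
#'   transcript x accession matrix.
#' @param k Number of hidden factors to remove (0 <= k < n accessions).
#' @return A `residual_matrix`: transcript x accession matrix with
#'   per-transcript mean 0, orthogonal to all removed factors; attribute
#'   `"factors"` holds the accession factor scores.
#' @export
remove_hidden_factors <- function(e, k = 15) {
  m <- if (is_expression_matrix(e)) e$tpm else e
  stopifnot(is.matrix(m))
  n <- ncol(m)
  if (k < 0) stop("k must be >= 0")
  if (k >= n) stop("k must be smaller than the number of accessions")
  centered <- m - rowMeans(m)
  if (k == 0) {
    out <- centered
    attr(out, "factors") <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    M <- t(centered)                       # accessions x transcripts, col-mean 0
    sv <- svd(M, nu = k, nv = 0)
    U <- sv$u[, seq_len(k), drop = FALSE]  # orthonormal accession factors
    out <- t(M - U %*% crossprod(U, M))
    attr(out, "factors") <- U
  }
  dimnames(out) <- dimnames(m)
  class(out) <- c("residual_matrix", class(out))
  out
}
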