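# Domain containers. Deliberately light-weight: a variant table is a list of
# a SNP metadata data.table plus a dosage matrix (SNP x accession); the other
# containers are data.tables or plain matrices with row/column names.

#' Construct a variant table
#'
#' @param dosage Numeric matrix, SNPs in rows (rownames = SNP ids),
#'   accessions in columns (colnames = accession ids); entries in
#'   \{0, 1, 2, NA\} (inbred panels are coded 0/2 with rare residual 1s).
#' @param chrom Chromosome name per SNP.
#' @param pos 1-based physical position per SNP.
#' @param genome_regex Regex with one capture group extracting the
#'   subgenome label from the chromosome name. The default captures a
#'   trailing A/B/D as in wheat chromosome names ("chr3B" -> "B").
#' @return An object of class `variant_table`: `list(snps, dosage)` where
#'   `snps` has columns snp_id, chrom, genome, pos, maf. The minor allele
#'   frequency is always recomputed from the dosages.
#' @export
variant_table <- function(dosage, chrom, pos,
                          genome_regex = "([ABD])$") {
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)),
            length(chrom) == nrow(dosage), length(pos) == nrow(dosage))
  if (is.null(rownames(dosage))) {
    if (nrow(dosage) > 0) stop("dosage matrix needs SNP ids as rownames")
    rownames(dosage) <- character(0)
  }
  if (any(pos < 1)) stop("positions must be >= 1")
  if (anyDuplicated(colnames(dosage)))
    stop("duplicated accession id in genotype data")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  snps <- data.table(
    snp_id = rownames(dosage),
    chrom = as.character(chrom),
    genome = genome_from_chrom(chrom, genome_regex),
    pos = as.integer(pos),
    maf = compute_maf(dosage)
  )
  structure(list(snps = snps, dosage = dosage), class = "variant_table")
}

#' @rdname variant_table
#' @param x Object to test.
#' @export
is_variant_table <- function(x) inherits(x, "variant_table")

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d SNPs x %d accessions\n",
              nrow(x$dosage), ncol(x$dosage)))
  print(head(x$snps, 5))
  invisible(x)
}

compute_maf <- function(dosage) {
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  pmin(af, 1 - af)
}

#' Derive subgenome labels from chromosome names
#'
#' @param chrom Character vector of chromosome names.
#' @param genome_regex Regex with one capture group giving the label.
#' @return Character vector of labels; `NA` where the regex does not match.
#' @export
genome_from_chrom <- function(chrom, genome_regex = "([ABD])$") {
  chrom <- as.character(chrom)
  hit <- grepl(genome_regex, chrom)
  out <- rep(NA_character_, length(chrom))
  out[hit] <- sub(paste0(".*", genome_regex, ".*"), "\\1", chrom[hit])
  out
}

#' Subset a variant table by SNP index or id, or by accession
#'
#' @param v A [variant_table].
#' @param snps SNP row indices or snp_id values (NULL keeps all).
#' @param accessions Accession ids, in the desired order (NULL keeps all).
#' @return A [variant_table] with MAF recomputed over the kept accessions.
#' @export
subset_variants <- function(v, snps = NULL, accessions = NULL) {
  stopifnot(is_variant_table(v))
  idx <- if (is.null(snps)) seq_len(nrow(v$dosage))
         else if (is.character(snps)) match(snps, v$snps$snp_id)
         else snps
  if (anyNA(idx)) stop("unknown snp_id in subset")
  d <- v$dosage[idx, , drop = FALSE]
  if (!is.null(accessions)) {
    j <- match(accessions, colnames(d))
    if (anyNA(j)) stop("unknown accession in subset")
    d <- d[, j, drop = FALSE]
  }
  s <- v$snps[idx]
  variant_table(d, s$chrom, s$pos,
                genome_regex = attr(v, "genome_regex") %||% "([ABD])$")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an expression matrix
#'
#' @param tpm Non-negative matrix, transcripts in rows (rownames =
#'   transcript ids), accessions in columns.
#' @param gene_id Gene id per transcript (defaults to the transcript id,
#'   the one-transcript-per-gene case).
#' @return An `expression_matrix`: `list(tpm, genes)` with `genes` a named
#'   character vector transcript_id -> gene_id.
#' @export
expression_matrix <- function(tpm, gene_id = rownames(tpm)) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)),
            length(gene_id) == nrow(tpm))
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  if (anyDuplicated(colnames(tpm)))
    stop("duplicated accession id in expression data")
  structure(list(tpm = tpm, genes = setNames(as.character(gene_id),
                                             rownames(tpm))),
            class = "expression_matrix")
}

#' @rdname expression_matrix
#' @param x Object to test.
#' @export
is_expression_matrix <- function(x) inherits(x, "expression_matrix")

#' Gene-level TPM matrix (transcript TPMs summed per gene)
#'
#' @param e An [expression_matrix].
#' @return Matrix genes x accessions.
#' @export
gene_tpm <- function(e) {
  stopifnot(is_expression_matrix(e))
  g <- e$genes
  if (!anyDuplicated(g)) {
    m <- e$tpm
    rownames(m) <- unname(g)
    return(m)
  }
  out <- rowsum(e$tpm, group = g)
  out[order(rownames(out)), , drop = FALSE]
}

#' Construct a gene model table
#'
#' @param gene_id,chrom,start,end,strand Vectors of equal length; `start`
#'   and `end` are 1-based inclusive; `strand` in "+", "-", ".".
#' @param genome_regex Passed to [genome_from_chrom].
#' @return data.table with columns gene_id, chrom, genome, start, end,
#'   strand, class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand = ".",
                        genome_regex = "([ABD])$") {
  if (any(start < 1)) stop("start must be >= 1")
  if (any(end < start)) stop("end < start")
  stopifnot(all(strand %in% c("+", "-", ".")))
  g <- data.table(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  genome = genome_from_chrom(chrom, genome_regex),
                  start = as.integer(start), end = as.integer(end),
                  strand = rep_len(as.character(strand), length(gene_id)))
  setattr(g, "class", c("gene_models", class(g)))
  g
}

#' Construct a homoeolog triplet map
#'
#' @param triplet_id Identifier per homoeolog group.
#' @param gene_A,gene_B,gene_D Member gene ids per subgenome (`NA` when the
#'   copy is absent).
#' @return data.table with class label in \{triplet, duplet, singleton\}
#'   derived from the member count; class `triplet_map`.
#' @export
triplet_map <- function(triplet_id, gene_A = NA, gene_B = NA, gene_D = NA) {
  t <- data.table(triplet_id = as.character(triplet_id),
                  gene_A = as.character(gene_A),
                  gene_B = as.character(gene_B),
                  gene_D = as.character(gene_D))
  n <- rowSums(!is.na(t[, .(gene_A, gene_B, gene_D)]))
  if (any(n == 0)) stop("triplet with no members")
  t$class <- c("singleton", "duplet", "triplet")[n]
  genes <- unlist(t[, .(gene_A, gene_B, gene_D)])
  genes <- genes[!is.na(genes)]
  if (anyDuplicated(genes)) stop("a gene may belong to at most one triplet")
  setattr(t, "class", c("triplet_map", class(t)))
  t
}

#' Member genes of a triplet map, keyed by subgenome
#' @param t A [triplet_map].
#' @return data.table (triplet_id, genome, gene_id), absent members dropped.
#' @export
triplet_members <- function(t) {
  long <- melt(as.data.table(t)[, .(triplet_id, gene_A, gene_B, gene_D)],
               id.vars = "triplet_id", variable.name = "genome",
               value.name = "gene_id", variable.factor = FALSE)
  long <- long[!is.na(gene_id)]
  long[, genome := sub("gene_", "", genome)]
  long[]
}
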