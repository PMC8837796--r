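# File readers for the standard formats the pipeline consumes, plus the
# accession-harmonization step every analysis starts from.

#' Read biallelic SNP dosages from a VCF
#'
#' Parses genotypes with vcfR and converts them to dosages: 0/0 -> 0,
#' heterozygote -> 1, 1/1 -> 2, missing -> NA. Sites with more than one ALT
#' allele are dropped. Heterozygotes in an inbred panel count as dosage 1
#' (and toward the het-rate filter in [filter_variants]).
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @param genome_regex Passed to [variant_table].
#' @return A [variant_table].
#' @export
read_vcf_dosage <- function(path, genome_regex = "([ABD])$") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(fix[, "ID"], names(gt)))
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  alleles <- function(x) {
    x <- sub("\\:.*", "", x)
    strsplit(x, "[/|]")
  }
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) {
    al <- alleles(gt[, j])
    dos[, j] <- vapply(seq_along(al), function(i) {
      a <- al[[i]]
      if (any(a == ".") || is.na(gt[i, j])) return(NA_real_)
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a) || any(a > 1))
        stop(sprintf("unparseable genotype at record %s (%s)",
                     rownames(gt)[i], gt[i, j]))
      sum(a)
    }, numeric(1))
  }
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  rownames(dos) <- ids
  variant_table(dos, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                genome_regex = genome_regex)
}

#' Read a transcript x accession TPM matrix from TSV
#'
#' Expected columns: `transcript_id`, optional `gene_id`, then one column
#' per accession.
#'
#' @param path TSV file.
#' @return An [expression_matrix].
#' @export
read_expression_tsv <- function(path) {
  x <- fread(path)
  stopifnot("transcript_id" %in% names(x))
  gene <- if ("gene_id" %in% names(x)) x$gene_id else x$transcript_id
  keep <- setdiff(names(x), c("transcript_id", "gene_id"))
  m <- as.matrix(x[, ..keep])
  rownames(m) <- x$transcript_id
  expression_matrix(m, gene_id = gene)
}

#' Read gene models from BED or GFF3
#'
#' BED intervals (0-based half-open) are converted to the package's
#' 1-based inclusive convention on read; GFF3 files are filtered to
#' `type == "gene"` records when a type column is present.
#'
#' @param path File ending in .bed, .gff, .gff3 or .gtf.
#' @param genome_regex Passed to [gene_models].
#' @return A [gene_models] table.
#' @export
read_gene_models <- function(path, genome_regex = "([ABD])$") {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  id <- if (!is.null(df$name)) df$name
        else if (!is.null(df$ID)) df$ID
        else if (!is.null(df$gene_id)) df$gene_id
        else stop("no gene identifier column in ", path)
  strand <- as.character(df$strand)
  strand[strand == "*"] <- "."
  gene_models(id, df$seqnames, df$start, df$end, strand,
              genome_regex = genome_regex)
}

#' Read a homoeolog triplet map from TSV
#'
#' Columns triplet_id, gene_A, gene_B, gene_D; empty cells mark absent
#' copies.
#' @param path TSV file.
#' @return A [triplet_map].
#' @export
read_triplet_map <- function(path) {
  x <- fread(path, na.strings = c("", "NA"))
  triplet_map(x$triplet_id, x$gene_A, x$gene_B, x$gene_D)
}

#' Read a long-format trait table from TSV
#'
#' Columns accession, trait, value.
#' @param path TSV file.
#' @return data.table with class `trait_table`.
#' @export
read_traits <- function(path) {
  x <- fread(path, na.strings = c("", "NA"))
  stopifnot(all(c("accession", "trait", "value") %in% names(x)))
  setattr(x, "class", c("trait_table", class(x)))
  x
}

#' Read SNP functional-class annotations
#'
#' TSV with columns snp_id, class.
#' @param path TSV file.
#' @return data.table (snp_id, class).
#' @export
read_annotation <- function(path) {
  x <- fread(path)
  stopifnot(all(c("snp_id", "class") %in% names(x)))
  x
}

#' Read a binned chromatin-contact table
#'
#' TSV with columns chromA, binA_start, chromB, binB_start, count; bins
#' are identified by their start coordinate at `bin_size` resolution.
#'
#' @param path TSV file.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return A `contact_matrix` (data.table + bin_size attribute) storing
#'   each unordered bin pair once, canonically ordered.
#' @export
read_contacts <- function(path, bin_size = 1e6) {
  x <- fread(path)
  setnames(x, c("binA_start", "binB_start"), c("binA", "binB"),
           skip_absent = TRUE)
  contact_matrix(x, bin_size = bin_size)
}

#' Construct a contact matrix
#'
#' @param x data.table with columns chromA, binA, chromB, binB, count.
#' @param bin_size Bin width in bp.
#' @return `contact_matrix` object; pairs stored once in canonical
#'   (lexicographic) order, symmetric on lookup.
#' @export
contact_matrix <- function(x, bin_size = 1e6) {
  x <- as.data.table(x)[, .(chromA, binA, chromB, binB, count)]
  if (any(x$count < 0)) stop("contact counts must be >= 0")
  flip <- x$chromB < x$chromA | (x$chromA == x$chromB & x$binB < x$binA)
  x[flip, `:=`(chromA = chromB, binA = binB, chromB = chromA, binB = binA)]
  x <- x[, .(count = sum(count)), by = .(chromA, binA, chromB, binB)]
  setattr(x, "bin_size", bin_size)
  setattr(x, "class", c("contact_matrix", class(x)))
  x
}

#' Genomic position to contact bin start
#' @param pos Position in bp (1-based).
#' @param bin_size Bin width in bp.
#' @return Bin start coordinate (0-based multiples of bin_size).
#' @export
contact_bin <- function(pos, bin_size = 1e6) (pos %/% bin_size) * bin_size

#' Look up contact counts for bin pairs (symmetric)
#' @param cm A `contact_matrix`.
#' @param chromA,binA,chromB,binB Vectors describing bin pairs.
#' @return Counts; 0 (with a warning) for pairs absent from the table.
#' @export
contact_lookup <- function(cm, chromA, binA, chromB, binB) {
  q <- data.table(chromA = as.character(chromA), binA = as.numeric(binA),
                  chromB = as.character(chromB), binB = as.numeric(binB))
  flip <- q$chromB < q$chromA | (q$chromA == q$chromB & q$binB < q$binA)
  q[flip, `:=`(chromA = chromB, binA = binB, chromB = chromA, binB = binA)]
  res <- cm[q, on = c("chromA", "binA", "chromB", "binB")]
  if (anyNA(res$count)) {
    warning(sum(is.na(res$count)), " bin pairs absent from contact table; counted 0")
    res[is.na(count), count := 0]
  }
  res$count
}

#' Load all inputs and harmonize accessions
#'
#' Reads the five standard inputs and restricts genotype, expression and
#' trait tables to the intersection of their accession ids, in one
#' canonical (sorted) order.
#'
#' @param vcf,expr,genes,triplets,traits File paths; `genes`, `triplets`
#'   and `traits` may be NULL.
#' @param genome_regex Passed to the genotype and gene-model readers.
#' @return list(variants, expression, genes, triplets, traits, accessions).
#' @export
load_and_harmonize <- function(vcf, expr, genes = NULL, triplets = NULL,
                               traits = NULL, genome_regex = "([ABD])$") {
  v <- read_vcf_dosage(vcf, genome_regex)
  e <- read_expression_tsv(expr)
  harmonize_cohort(
    v, e,
    genes = if (!is.null(genes)) read_gene_models(genes, genome_regex),
    triplets = if (!is.null(triplets)) read_triplet_map(triplets),
    traits = if (!is.null(traits)) read_traits(traits)
  )
}

#' Harmonize already-loaded tables to shared accessions
#'
#' @param v A [variant_table].
#' @param e An [expression_matrix].
#' @param genes,triplets,traits Optional tables passed through unchanged
#'   apart from trait-accession restriction.
#' @return list(variants, expression, genes, triplets, traits, accessions).
#' @export
harmonize_cohort <- function(v, e, genes = NULL, triplets = NULL,
                             traits = NULL) {
  stopifnot(is_variant_table(v), is_expression_matrix(e))
  acc <- sort(intersect(colnames(v$dosage), colnames(e$tpm)))
  if (!is.null(traits)) {
    # traits restricted to, but not required to cover, the shared set
    traits <- as.data.table(traits)[accession %in% acc]
    setattr(traits, "class", c("trait_table", "data.table", "data.frame"))
  }
  if (length(acc) < 2) stop("fewer than 2 shared accessions after harmonization")
  v <- subset_variants(v, accessions = acc)
  tpm <- e$tpm[, acc, drop = FALSE]
  e <- expression_matrix(tpm, gene_id = unname(e$genes))
  list(variants = v, expression = e, genes = genes, triplets = triplets,
       traits = traits, accessions = acc)
}
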