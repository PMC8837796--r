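#' Spearman correlation coefficient (SCC)
#'
#' Rank correlation used throughout the package for homoeolog expression
#' comparisons: the Pearson correlation of mid-ranks (ties receive the
#' average of the ranks they span). Pairs with a missing value in either
#' vector are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A correlation in \[-1, 1\], or `NA` if fewer than 3 complete
#'   pairs remain or either vector is constant over the complete pairs.
#' @export
spearman_scc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete pairs; SCC undefined")
    return(NA_real_)
  }
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(rank(x), rank(y))
}

#' Linkage disequilibrium as squared dosage correlation
#'
#' r-squared between two dosage vectors over pairwise-complete accessions.
#' Symmetric and invariant to allele flips (x -> 2 - x).
#'
#' @param g1,g2 Dosage vectors in \{0, 1, 2, NA\}.
#' @return r-squared in \[0, 1\], or `NA` when fewer than 3 complete pairs
#'   remain or either vector is constant.
#' @export
ld_r2 <- function(g1, g2) {
  r <- ld_r(g1, g2)
  if (is.na(r)) NA_real_ else r * r
}

#' Signed LD correlation between two dosage vectors
#'
#' @inheritParams ld_r2
#' @return Pearson correlation of dosages over pairwise-complete
#'   accessions, or `NA` if undefined.
#' @export
ld_r <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- is.finite(g1) & is.finite(g2)
  if (sum(ok) < 3) return(NA_real_)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (sd(g1) == 0 || sd(g2) == 0) return(NA_real_)
  cor(g1, g2)
}

#' Windowed nucleotide diversity
#'
#' Per-window nucleotide diversity for an inbred panel (each accession is
#' treated as a single haplotype). Every SNP contributes the unbiased
#' per-site heterozygosity (n/(n-1)) * 2p(1-p), where n is the number of
#' callable haplotypes at the site; the window value is the sum over SNPs
#' divided by the window length in bp, i.e. diversity per base pair.
#'
#' @param v A [variant_table].
#' @param windows A data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return `windows` with an added `diversity` column. Windows with no
#'   SNPs score 0; windows whose SNPs are all uncallable score `NA`.
#' @export
nucleotide_diversity <- function(v, windows) {
  stopifnot(is_variant_table(v))
  windows <- as.data.table(windows)
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)))
  if (any(windows$end < windows$start)) stop("window end < start")
  windows$diversity <- vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i]
    idx <- which(v$snps$chrom == w$chrom & v$snps$pos >= w$start &
                 v$snps$pos <= w$end)
    len <- w$end - w$start + 1
    if (!length(idx)) return(0)
    per_site <- vapply(idx, function(j) {
      d <- v$dosage[j, ]
      d <- d[is.finite(d)]
      n <- length(d)                      # haplotypes (inbred convention)
      if (n < 2) return(NA_real_)
      p <- mean(d) / 2
      (n / (n - 1)) * 2 * p * (1 - p)
    }, numeric(1))
    if (all(is.na(per_site))) return(NA_real_)
    sum(per_site, na.rm = TRUE) / len
  }, numeric(1))
  windows[]
}

#' Genotype QC filter
#'
#' Retains biallelic SNPs with minor allele frequency at or above
#' `maf_min`, missing-call fraction at or below `miss_max`, and
#' heterozygote fraction at or below `het_max` (the inbred-panel residual
#' heterozygosity filter). Each removed SNP is attributed to the first
#' rule it violates, in the order maf, missing, het, so the retained set
#' and the removal report partition the input exactly.
#'
#' @param v A [variant_table].
#' @param maf_min,miss_max,het_max Thresholds in \[0, 1\].
#' @return The filtered [variant_table]; attribute `"removal_report"`
#'   carries a named vector of removal counts per rule.
#' @export
filter_variants <- function(v, maf_min = 0.05, miss_max = 0.5, het_max = 0.03) {
  stopifnot(is_variant_table(v),
            maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1,
            het_max >= 0, het_max <= 1)
  d <- v$dosage
  n <- ncol(d)
  miss <- rowMeans(!is.finite(d))
  het <- rowMeans(d == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  maf <- v$snps$maf
  fail_maf <- is.na(maf) | maf < maf_min
  fail_miss <- !fail_maf & miss > miss_max
  fail_het <- !fail_maf & !fail_miss & het > het_max
  keep <- !(fail_maf | fail_miss | fail_het)
  if (!any(keep)) warning("no SNPs pass the filters")
  out <- subset_variants(v, which(keep))
  attr(out, "removal_report") <- c(
    maf = sum(fail_maf), missing = sum(fail_miss), het = sum(fail_het),
    retained = sum(keep)
  )
  out
}

#' Benjamini-Hochberg threshold helper used by the permutation analyses
#' @noRd
bh_q <- function(p) p.adjust(p, method = "BH")
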