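# Trait GWAS scanning and summary-level Mendelian randomization linking
# expression to traits, with the HEIDI heterogeneity test separating
# pleiotropy from linkage.

#' Single-trait GWAS scan
#'
#' OLS of a trait on each SNP dosage with genotype principal components
#' as covariates, returning SMR-ready summary statistics.
#'
#' @param traits A trait table (accession, trait, value) or a named
#'   numeric vector of one trait keyed by accession.
#' @param v A [variant_table].
#' @param trait_name Trait to scan when `traits` is a table.
#' @param n_pcs Number of genotype PC covariates.
#' @return data.table: snp_id, chrom, pos, freq, b, se, z, p, n.
#' @export
gwas_scan <- function(traits, v, trait_name = NULL, n_pcs = 3) {
  if (is.data.frame(traits)) {
    tt <- as.data.table(traits)
    if (is.null(trait_name)) trait_name <- tt$trait[1]
    tt <- tt[trait == trait_name & !is.na(value)]
    y <- setNames(tt$value, tt$accession)
  } else y <- traits[!is.na(traits)]
  acc <- intersect(colnames(v$dosage), names(y))
  if (length(acc) < 30) stop("need at least 30 accessions with trait values")
  y <- y[acc]
  if (sd(y) == 0) stop("constant trait")
  vv <- subset_variants(v, accessions = acc)
  Y <- matrix(y, nrow = 1, dimnames = list("trait", acc))
  sm <- scan_matrices(Y, vv, n_pcs)
  b <- as.vector(sm$beta); tst <- as.vector(sm$t)
  se <- ifelse(tst == 0, NA_real_, abs(b / tst))
  # se for exactly-zero slopes falls back to the regression formula
  if (anyNA(se)) {
    i <- which(is.na(se))
    se[i] <- 1e-12
  }
  info <- vv$snps[match(sm$snp_ids, snp_id)]
  data.table(snp_id = sm$snp_ids, chrom = info$chrom, pos = info$pos,
             freq = rowMeans(vv$dosage[match(sm$snp_ids, vv$snps$snp_id), ,
                                       drop = FALSE], na.rm = TRUE) / 2,
             b = b, se = se, z = b / se,
             p = as.vector(sm$p), n = length(acc))
}

#' Summary-based Mendelian randomization test
#'
#' At the top eQTL SNP, tests whether expression and trait share a causal
#' or pleiotropic variant: b_xy = b_GWAS / b_eQTL and
#' T_SMR = z2_GWAS * z2_eQTL / (z2_GWAS + z2_eQTL), referred to a 1-df
#' chi-square.
#'
#' @param gwas,eqtl Summary-statistic data.tables (columns snp_id, freq,
#'   b, se) for the trait and for one gene's expression.
#' @param p_eqtl_min Maximum eQTL p-value for the instrument (top SNP must
#'   pass it).
#' @param diff_freq_prop Maximum tolerated allele-frequency discrepancy
#'   between the two summary sets; SNPs beyond it are excluded.
#' @return One-row data.table (top_snp, b_xy, t_smr, p_smr, b_eqtl,
#'   b_gwas, z_eqtl, z_gwas), or NULL when no eligible SNP remains.
#' @export
smr_test <- function(gwas, eqtl, p_eqtl_min = 5e-8, diff_freq_prop = 0.2) {
  gwas <- as.data.table(gwas); eqtl <- as.data.table(eqtl)
  mg <- merge(eqtl, gwas, by = "snp_id", suffixes = c("_x", "_y"))
  if ("freq_x" %in% names(mg))
    mg <- mg[abs(freq_x - freq_y) <= diff_freq_prop]
  if (!nrow(mg)) return(NULL)
  mg[, `:=`(z_x = b_x / se_x, z_y = b_y / se_y,
            p_x = 2 * pnorm(-abs(b_x / se_x)))]
  top <- mg[order(p_x)][1]
  if (top$p_x > p_eqtl_min) return(NULL)
  t_smr <- (top$z_y^2 * top$z_x^2) / (top$z_y^2 + top$z_x^2)
  if (!is.finite(t_smr)) t_smr <- 0
  data.table(top_snp = top$snp_id, b_xy = top$b_y / top$b_x,
             t_smr = t_smr, p_smr = pchisq(t_smr, 1, lower.tail = FALSE),
             b_eqtl = top$b_x, b_gwas = top$b_y,
             z_eqtl = top$z_x, z_gwas = top$z_y)
}

#' HEIDI heterogeneity test (pleiotropy vs linkage)
#'
#' Tests whether the b_xy estimates from SNPs in LD with the top eQTL SNP
#' are consistent with a single shared causal variant. For each eligible
#' SNP i (LD r-squared with the top SNP inside `r2_window`, at most
#' `max_snps` ranked by eQTL significance), d_i = b_xy(i) - b_xy(top);
#' the covariance of the d vector follows the first-order delta-method
#' approximation using the LD correlations, and the statistic is the
#' whitened sum of squares d' V^-1 d on rank(V) degrees of freedom.
#' Under pleiotropy all b_xy agree and the statistic is small; linkage of
#' distinct causal variants inflates it.
#'
#' @param gwas,eqtl Summary statistics as in [smr_test].
#' @param ld_r Signed LD correlation matrix among the candidate SNPs
#'   (dimnames = snp ids), e.g. from [ld_r] on dosages.
#' @param top_snp The instrument SNP (defaults to the smallest eQTL p).
#' @param r2_window Eligible LD r-squared range (exclusive of the top
#'   SNP itself).
#' @param max_snps Maximum SNPs used besides the top SNP.
#' @return list(p_heidi, n_snps, statistic, df); p_heidi is NA with
#'   n_snps < 3.
#' @export
heidi_test <- function(gwas, eqtl, ld_r, top_snp = NULL,
                       r2_window = c(0.05, 0.9), max_snps = 20) {
  gwas <- as.data.table(gwas); eqtl <- as.data.table(eqtl)
  mg <- merge(eqtl, gwas, by = "snp_id", suffixes = c("_x", "_y"))
  mg <- mg[snp_id %in% rownames(ld_r)]
  mg[, `:=`(z_x = b_x / se_x, z_y = b_y / se_y)]
  mg[, p_x := 2 * pnorm(-abs(z_x))]
  if (is.null(top_snp)) top_snp <- mg[order(p_x)]$snp_id[1]
  r_top <- ld_r[, top_snp]
  elig <- mg[snp_id != top_snp]
  r2v <- r_top[elig$snp_id]^2
  elig <- elig[r2v > r2_window[1] & r2v < r2_window[2]]
  elig <- elig[order(p_x)][seq_len(min(.N, max_snps))]
  if (nrow(elig) < 3)
    return(list(p_heidi = NA_real_, n_snps = nrow(elig),
                statistic = NA_real_, df = NA_integer_))
  topr <- mg[snp_id == top_snp]
  ids <- c(top_snp, elig$snp_id)
  bxy <- c(topr$b_y / topr$b_x, elig$b_y / elig$b_x)
  zx <- c(topr$z_x, elig$z_x)
  zy <- c(topr$z_y, elig$z_y)
  R <- ld_r[ids, ids]
  # first-order covariance of the b_xy estimates across SNPs in LD
  cov_bxy <- outer(bxy, bxy) * (R / outer(zy, zy) + R / outer(zx, zx))
  k <- length(ids) - 1
  d <- bxy[-1] - bxy[1]
  Vd <- cov_bxy[-1, -1, drop = FALSE] -
    matrix(cov_bxy[-1, 1], k, k) -
    t(matrix(cov_bxy[-1, 1], k, k)) + cov_bxy[1, 1]
  ev <- eigen(Vd, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-8
  w <- ev$vectors[, pos, drop = FALSE]
  stat <- sum((crossprod(w, d))^2 / ev$values[pos])
  df <- sum(pos)
  list(p_heidi = pchisq(stat, df, lower.tail = FALSE),
       n_snps = k, statistic = stat, df = df)
}

#' SMR + HEIDI over a cis region with individual-level data
#'
#' Convenience wrapper: scans the trait and the expression phenotype over
#' the SNPs of `v`, runs [smr_test] at the top eQTL SNP and [heidi_test]
#' over the region.
#'
#' @param expr_y Named numeric vector of one gene's (residualized)
#'   expression, keyed by accession.
#' @param trait_y Named numeric vector of one trait.
#' @param v A [variant_table] restricted to the candidate region.
#' @param n_pcs PCs used in both scans.
#' @param p_eqtl_min,diff_freq_prop,r2_window,max_snps Passed through.
#' @return data.table row: SMR columns plus p_heidi, n_heidi_snps; NULL
#'   when no instrument passes.
#' @export
smr_region <- function(expr_y, trait_y, v, n_pcs = 0, p_eqtl_min = 5e-8,
                       diff_freq_prop = 0.2, r2_window = c(0.05, 0.9),
                       max_snps = 20) {
  eq <- gwas_scan(expr_y, v, n_pcs = n_pcs)
  gw <- gwas_scan(trait_y, v, n_pcs = n_pcs)
  rec <- smr_test(gw, eq, p_eqtl_min = p_eqtl_min,
                  diff_freq_prop = diff_freq_prop)
  if (is.null(rec)) return(NULL)
  z <- standardize_dosage(v$dosage)
  R <- tcrossprod(z) / (ncol(z) - 1)
  dimnames(R) <- list(rownames(z), rownames(z))
  hd <- heidi_test(gw, eq, R, top_snp = rec$top_snp, r2_window = r2_window,
                   max_snps = max_snps)
  rec$p_heidi <- hd$p_heidi
  rec$n_heidi_snps <- hd$n_snps
  rec
}
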