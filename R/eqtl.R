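# Per-gene association scanning, permutation FDR calibration, LD-based
# merging of significant SNPs into eQTL intervals, cis/trans
# classification, and eQTL-level downstream analyses.

# genotype principal components from the mean-imputed standardized dosages
#' Genotype principal components
#' @param v A [variant_table].
#' @param n_pcs Number of components.
#' @return Accession x n_pcs matrix of PC scores.
#' @export
genotype_pcs <- function(v, n_pcs = 3) {
  z <- standardize_dosage(v$dosage)
  K <- crossprod(z) / nrow(z)
  ev <- eigen(K, symmetric = TRUE)
  pcs <- ev$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(n_pcs)], 0)), n_pcs)
  rownames(pcs) <- colnames(v$dosage)
  pcs
}

# core scan: OLS of each residual row on each dosage row with covariates
# projected out (Frisch-Waugh); returns beta/t/p matrices (gene x SNP)
scan_matrices <- function(resid, v, n_pcs = 3, covariates = NULL) {
  Y <- if (is_expression_matrix(resid)) resid$tpm else unclass(resid)
  stopifnot(is.matrix(Y), identical(colnames(Y), colnames(v$dosage)))
  n <- ncol(Y)
  stopifnot(n >= n_pcs + 10)
  D <- v$dosage
  mu <- rowMeans(D, na.rm = TRUE)
  D[is.na(D)] <- matrix(mu, nrow(D), ncol(D))[is.na(D)]
  poly <- apply(D, 1, sd) > 0
  D <- D[poly, , drop = FALSE]
  C <- cbind(rep(1, n), if (n_pcs > 0) genotype_pcs(v, n_pcs), covariates)
  Q <- qr.Q(qr(C))
  Yr <- Y - (Y %*% Q) %*% t(Q)
  Gr <- D - (D %*% Q) %*% t(Q)
  ssy <- rowSums(Yr^2)
  ssg <- rowSums(Gr^2)
  num <- Yr %*% t(Gr)                           # gene x SNP cross-products
  beta <- sweep(num, 2, ssg, "/")
  r <- num / sqrt(outer(ssy, ssg))
  df <- n - ncol(Q) - 1
  r2 <- pmin(r * r, 1 - 1e-15)
  tst <- r * sqrt(df / (1 - r2))
  p <- 2 * pt(-abs(tst), df)
  list(beta = beta, t = tst, p = p, df = df,
       snp_ids = rownames(D), gene_ids = rownames(Y))
}

#' Per-gene association scan
#'
#' Ordinary least squares of each residual expression trait on each SNP
#' dosage with the top genotype principal components as covariates.
#' Benjamini-Hochberg q-values are computed jointly over the full
#' transcript x SNP scan.
#'
#' @param resid Residual expression matrix (transcript x accession) or an
#'   [expression_matrix].
#' @param v A [variant_table] over the same accessions, in the same order.
#' @param n_pcs Number of genotype PCs used as covariates.
#' @param p_max Optional p-value cutoff applied to the returned records
#'   (q is computed before filtering).
#' @return data.table: transcript_id, snp_id, beta, tstat, p, q. SNPs
#'   constant after missing-value imputation are skipped.
#' @export
association_scan <- function(resid, v, n_pcs = 3, p_max = NULL) {
  sm <- scan_matrices(resid, v, n_pcs)
  out <- data.table(
    transcript_id = rep(sm$gene_ids, times = length(sm$snp_ids)),
    snp_id = rep(sm$snp_ids, each = length(sm$gene_ids)),
    beta = as.vector(sm$beta), tstat = as.vector(sm$t),
    p = as.vector(sm$p))
  out[, q := bh_q(p)]
  if (!is.null(p_max)) out <- out[p <= p_max]
  out[]
}

#' Merge significant SNPs into eQTL intervals by LD and distance
#'
#' Single-linkage clustering per transcript and chromosome: two
#' significant SNPs join the same interval iff their LD r-squared exceeds
#' `r2_min` AND their distance is below `gap_bp`; clusters are the
#' transitive closure. The SNP with the smallest p-value becomes the eQTL
#' lead (ties broken by smaller position, then snp_id).
#'
#' @param sig data.table of significant associations (transcript_id,
#'   snp_id, beta, p and optionally q), e.g. `association_scan(...)[q < 1e-5]`.
#' @param v The [variant_table] (for positions and LD).
#' @param r2_min,gap_bp Linkage thresholds.
#' @return data.table of eQTL records: transcript_id, chrom, start, end,
#'   lead_snp, lead_pos, lead_p, lead_beta, n_snps.
#' @export
merge_to_eqtl <- function(sig, v, r2_min = 0.2, gap_bp = 1e5) {
  sig <- as.data.table(sig)
  if (!nrow(sig)) return(data.table(
    transcript_id = character(), chrom = character(), start = integer(),
    end = integer(), lead_snp = character(), lead_pos = integer(),
    lead_p = numeric(), lead_beta = numeric(), n_snps = integer()))
  info <- v$snps[match(sig$snp_id, snp_id)]
  sig <- cbind(sig, info[, .(chrom, pos)])
  rbindlist(lapply(split(sig, by = c("transcript_id", "chrom")), function(s) {
    s <- s[order(pos)]
    m <- nrow(s)
    comp <- as.numeric(seq_len(m))
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    if (m > 1) {
      for (i in seq_len(m - 1)) {
        j <- i + 1
        while (j <= m && s$pos[j] - s$pos[i] < gap_bp) {
          r2 <- ld_r2(v$dosage[match(s$snp_id[i], v$snps$snp_id), ],
                      v$dosage[match(s$snp_id[j], v$snps$snp_id), ])
          if (!is.na(r2) && r2 > r2_min) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
          }
          j <- j + 1
        }
      }
      comp <- vapply(seq_len(m), find, numeric(1))
    }
    s$cluster <- comp
    s[, {
      o <- order(p, pos, snp_id)
      .(chrom = chrom[1], start = min(pos), end = max(pos),
        lead_snp = snp_id[o[1]], lead_pos = pos[o[1]], lead_p = p[o[1]],
        lead_beta = beta[o[1]], n_snps = .N)
    }, by = .(transcript_id, cluster)][, cluster := NULL][]
  }), use.names = TRUE)
}

#' Classify eQTL as cis, trans or other
#'
#' cis if the lead SNP lies within +/-`cis_bp` of the target gene's
#' interval; trans if it lies on a different chromosome (the conservative
#' definition); "other" for same-chromosome leads beyond the cis window.
#'
#' @param eqtl data.table from [merge_to_eqtl].
#' @param genes A [gene_models] table.
#' @param gene_map Named character vector transcript_id -> gene_id
#'   (defaults to identity).
#' @param cis_bp Half-width of the cis window.
#' @return `eqtl` with an added `class` column.
#' @export
classify_eqtl <- function(eqtl, genes, gene_map = NULL, cis_bp = 1e6) {
  e <- as.data.table(eqtl)
  gtab <- as.data.table(genes)
  gid <- if (is.null(gene_map)) e$transcript_id else
    unname(gene_map[e$transcript_id])
  gi <- match(gid, gtab$gene_id)
  if (anyNA(gi)) stop("eQTL transcript(s) without a gene model")
  dist <- pmax(gtab$start[gi] - e$lead_pos, e$lead_pos - gtab$end[gi], 0)
  e$class <- fifelse(e$chrom != gtab$chrom[gi], "trans",
                     fifelse(dist <= cis_bp, "cis", "other"))
  e[]
}

#' False-positive proportion from observed and permuted association counts
#'
#' The proportion of significant associations expected to be false, given
#' the mean number detected in permuted (expression shuffled relative to
#' genotypes) datasets and the number detected in the observed data.
#'
#' @param observed Count of significant associations in the real data.
#' @param mean_permuted Mean count over permuted replicates.
#' @return mean_permuted / observed, or NA if `observed` is 0.
#' @export
false_positive_proportion <- function(observed, mean_permuted) {
  if (observed == 0) return(NA_real_)
  mean_permuted / observed
}

#' Permutation-based FDR calibration of the association scan
#'
#' Accession labels of the residual matrix are permuted jointly across
#' transcripts (breaking the genotype-expression link while keeping the
#' expression correlation structure) and the scan is repeated; the
#' false-positive proportion is the mean permuted count of associations
#' passing `p_threshold`, divided by the observed count.
#'
#' @param resid Residual expression matrix.
#' @param v A [variant_table].
#' @param n_perm Number of permutation replicates (>= 1).
#' @param p_threshold p-value significance threshold.
#' @param n_pcs Genotype PCs used as scan covariates.
#' @param seed RNG seed for the permutations.
#' @return list(observed, mean_permuted, fp_proportion, permuted_counts).
#' @export
permutation_fdr <- function(resid, v, n_perm, p_threshold, n_pcs = 3,
                            seed = 1) {
  stopifnot(n_perm >= 1)
  Y <- if (is_expression_matrix(resid)) resid$tpm else unclass(resid)
  obs <- sum(scan_matrices(Y, v, n_pcs)$p <= p_threshold)
  set.seed(seed)
  perm_counts <- vapply(seq_len(n_perm), function(i) {
    Yp <- Y[, sample(ncol(Y)), drop = FALSE]
    colnames(Yp) <- colnames(Y)
    sum(scan_matrices(Yp, v, n_pcs)$p <= p_threshold)
  }, numeric(1))
  list(observed = obs, mean_permuted = mean(perm_counts),
       fp_proportion = false_positive_proportion(obs, mean(perm_counts)),
       permuted_counts = perm_counts)
}

#' Genomic inflation factor
#'
#' Median of the 1-df chi-square quantiles of the p-values, divided by
#' the null median 0.4549.
#'
#' @param pvals Vector of p-values for one gene's scan.
#' @return GIF (1 for well-calibrated tests).
#' @export
genomic_inflation_factor <- function(pvals) {
  stopifnot(length(pvals) >= 1)
  median(qchisq(pvals, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Shared eQTL and regulatory configuration of homoeolog pairs
#'
#' A pair of homoeologs shares an eQTL iff the lead SNPs are identical or
#' the merged intervals overlap on the same chromosome. Configurations:
#' "no-eQTL" (neither gene has any), "cis-as-trans" (a shared variant is
#' cis for one gene and trans for the other), "cis-each" (each gene has
#' its own cis-eQTL), "shared-trans-only" (a shared trans-eQTL and no
#' cis-eQTL on either side), otherwise "unclassified".
#'
#' @param eqtl Classified eQTL table ([classify_eqtl] output).
#' @param triplets A [triplet_map].
#' @param gene_map Optional transcript -> gene map for the eQTL table.
#' @return data.table per cross-genome pair: gene1, gene2, pair (AB/AD/BD),
#'   shared flag, configuration.
#' @export
shared_eqtl_and_configuration <- function(eqtl, triplets, gene_map = NULL) {
  e <- as.data.table(eqtl)
  e$gene <- if (is.null(gene_map)) e$transcript_id else
    unname(gene_map[e$transcript_id])
  mem <- triplet_members(triplets)
  pairs <- mem[, {
    if (.N >= 2) {
      cmb <- utils::combn(seq_len(.N), 2)
      .(gene1 = gene_id[cmb[1, ]], gene2 = gene_id[cmb[2, ]],
        pair = paste0(pmin(genome[cmb[1, ]], genome[cmb[2, ]]),
                      pmax(genome[cmb[1, ]], genome[cmb[2, ]])))
    }
  }, by = triplet_id]
  if (!nrow(pairs)) return(data.table())
  by_gene <- split(e, by = "gene")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    e1 <- by_gene[[pairs$gene1[i]]]
    e2 <- by_gene[[pairs$gene2[i]]]
    n1 <- if (is.null(e1)) 0 else nrow(e1)
    n2 <- if (is.null(e2)) 0 else nrow(e2)
    if (n1 == 0 && n2 == 0)
      return(list(shared = FALSE, configuration = "no-eQTL"))
    shared_mat <- if (n1 && n2)
      outer(seq_len(n1), seq_len(n2), function(a, b)
        e1$lead_snp[a] == e2$lead_snp[b] |
        (e1$chrom[a] == e2$chrom[b] & e1$start[a] <= e2$end[b] &
         e2$start[b] <= e1$end[a]))
    else matrix(FALSE, 0, 0)
    shared <- any(shared_mat)
    cis_as_trans <- FALSE
    if (shared) {
      idx <- which(shared_mat, arr.ind = TRUE)
      cls <- cbind(e1$class[idx[, 1]], e2$class[idx[, 2]])
      cis_as_trans <- any((cls[, 1] == "cis" & cls[, 2] == "trans") |
                          (cls[, 1] == "trans" & cls[, 2] == "cis"))
    }
    has_cis1 <- n1 > 0 && any(e1$class == "cis")
    has_cis2 <- n2 > 0 && any(e2$class == "cis")
    shared_trans <- shared && any(shared_mat &
      outer(seq_len(n1), seq_len(n2), function(a, b)
        e1$class[a] == "trans" & e2$class[b] == "trans"))
    configuration <-
      if (cis_as_trans) "cis-as-trans"
      else if (has_cis1 && has_cis2) "cis-each"
      else if (shared_trans && !has_cis1 && !has_cis2) "shared-trans-only"
      else "unclassified"
    list(shared = shared, configuration = configuration)
  })
  pairs$shared <- vapply(res, `[[`, logical(1), "shared")
  pairs$configuration <- vapply(res, `[[`, character(1), "configuration")
  pairs[]
}

#' MAF versus effect-size correlation, compared between gene sets
#'
#' Spearman correlation between lead-SNP minor allele frequency and
#' absolute slope within each set, with a Fisher z-test for the
#' difference between the two correlations.
#'
#' @param homoeolog,singleton data.tables with columns `maf` and `beta`
#'   (cis-eQTL of homoeologous and singleton genes).
#' @return list(scc_h, scc_s, n_h, n_s, fisher_z, p).
#' @export
maf_effect_analysis <- function(homoeolog, singleton) {
  h <- as.data.table(homoeolog); s <- as.data.table(singleton)
  if (nrow(h) <= 3 || nrow(s) <= 3) stop("need more than 3 eQTL per set")
  if (nrow(h) < 10 || nrow(s) < 10)
    warning("fewer than 10 eQTL in a set; correlations will be unstable")
  r1 <- spearman_scc(h$maf, abs(h$beta))
  r2 <- spearman_scc(s$maf, abs(s$beta))
  z <- (atanh(r1) - atanh(r2)) /
    sqrt(1 / (nrow(h) - 3) + 1 / (nrow(s) - 3))
  list(scc_h = r1, scc_s = r2, n_h = nrow(h), n_s = nrow(s),
       fisher_z = z, p = 2 * pnorm(-abs(z)))
}

#' Functional-class enrichment of eQTL lead SNPs
#'
#' Per annotation class, log2 of the fraction of eQTL leads inside the
#' class relative to the mean fraction over random SNP samples of equal
#' size; the CI comes from the resampling quantiles.
#'
#' @param leads Character vector of lead snp_ids.
#' @param all_snps Character vector of the SNP universe.
#' @param tracks data.table (snp_id, class) of annotation memberships.
#' @param n_random Number of random samples.
#' @param seed RNG seed.
#' @return data.table: class, obs_fraction, null_fraction, log2_enrichment,
#'   ci_lo, ci_hi. Classes with no member SNPs give NA.
#' @export
functional_enrichment <- function(leads, all_snps, tracks, n_random = 100,
                                  seed = 1) {
  tracks <- as.data.table(tracks)
  set.seed(seed)
  samples <- replicate(n_random, sample(all_snps, length(leads)),
                       simplify = FALSE)
  rbindlist(lapply(split(tracks, by = "class"), function(tr) {
    cls <- tr$class[1]
    members <- unique(tr$snp_id)
    if (!length(members))
      return(data.table(class = cls, obs_fraction = NA_real_,
                        null_fraction = NA_real_, log2_enrichment = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    obs <- mean(leads %in% members)
    null <- vapply(samples, function(s) mean(s %in% members), numeric(1))
    enr <- log2(obs / mean(null))
    qs <- quantile(null, c(0.975, 0.025))
    data.table(class = cls, obs_fraction = obs, null_fraction = mean(null),
               log2_enrichment = enr,
               ci_lo = log2(obs / qs[1]), ci_hi = log2(obs / qs[2]))
  }))
}

#' Chromatin-contact enrichment of trans eQTL-gene pairs
#'
#' Compares the mean log10(1 + contact count) over the 1-Mb bin pairs of
#' observed eQTL-gene pairs against a null in which each target gene is
#' replaced by a random gene.
#'
#' @param pairs data.table with columns eqtl_chrom, eqtl_pos, gene_chrom,
#'   gene_pos, and optionally `p` (association p-value).
#' @param contacts A `contact_matrix`.
#' @param genes A [gene_models] table providing the random-gene universe.
#' @param n_random Number of null replicates.
#' @param seed RNG seed.
#' @param n_p_bins Number of p-value bins for the contact-vs-significance
#'   trace (used when `pairs$p` exists).
#' @return list(observed_mean, null_means, percentile, p_trace).
#' @export
hic_contact_enrichment <- function(pairs, contacts, genes, n_random = 100,
                                   seed = 1, n_p_bins = 5) {
  pairs <- as.data.table(pairs)
  bs <- attr(contacts, "bin_size")
  obs_counts <- contact_lookup(contacts,
                               pairs$eqtl_chrom, contact_bin(pairs$eqtl_pos, bs),
                               pairs$gene_chrom, contact_bin(pairs$gene_pos, bs))
  observed_mean <- mean(log10(1 + obs_counts))
  gtab <- as.data.table(genes)
  set.seed(seed)
  null_means <- vapply(seq_len(n_random), function(i) {
    gi <- sample(nrow(gtab), nrow(pairs), replace = TRUE)
    cnt <- suppressWarnings(contact_lookup(
      contacts, pairs$eqtl_chrom, contact_bin(pairs$eqtl_pos, bs),
      gtab$chrom[gi], contact_bin(gtab$start[gi], bs)))
    mean(log10(1 + cnt))
  }, numeric(1))
  p_trace <- NULL
  if ("p" %in% names(pairs) && nrow(pairs) >= n_p_bins) {
    bin <- cut(rank(pairs$p, ties.method = "first"), n_p_bins,
               labels = FALSE)
    p_trace <- data.table(p_bin = seq_len(n_p_bins))[
      , .(mean_p = tapply(pairs$p, bin, mean)[p_bin],
          mean_log10_contact = tapply(log10(1 + obs_counts), bin,
                                      mean)[p_bin]), by = p_bin]
  }
  list(observed_mean = observed_mean, null_means = null_means,
       percentile = mean(observed_mean > null_means) * 100,
       p_trace = p_trace)
}

#' Overlap of eQTL leads with marker-trait associations
#'
#' Counts MTAs with at least one eQTL lead within +/-`window_bp`, and the
#' null distribution of the same count using random SNP sets in place of
#' the leads.
#'
#' @param leads data.table (chrom, pos) of eQTL lead SNPs.
#' @param mta data.table (chrom, pos) of marker-trait associations.
#' @param all_snps data.table (chrom, pos) of the SNP universe.
#' @param window_bp Overlap half-width.
#' @param n_random Number of null draws.
#' @param seed RNG seed.
#' @return list(observed, null_counts, percentile).
#' @export
mta_overlap <- function(leads, mta, all_snps, window_bp = 1000,
                        n_random = 100, seed = 1) {
  leads <- as.data.table(leads); mta <- as.data.table(mta)
  all_snps <- as.data.table(all_snps)
  count_overlap <- function(set) {
    sum(vapply(seq_len(nrow(mta)), function(i)
      any(set$chrom == mta$chrom[i] &
          abs(set$pos - mta$pos[i]) <= window_bp), logical(1)))
  }
  obs <- count_overlap(leads)
  set.seed(seed)
  null <- vapply(seq_len(n_random), function(i)
    count_overlap(all_snps[sample(.N, nrow(leads))]), numeric(1))
  list(observed = obs, null_counts = null,
       percentile = mean(obs > null) * 100)
}
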