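# Homoeolog-dosage statistics: pairwise SCC profiling against a
# random-pair null, dosage-compensation analysis, biased-homoeolog
# detection, low-expressing-allele burden and its trait correlation,
# rare-allele load, and inter-locus LD profiling.

#' SCC profile of homoeolog pairs against a random-pair null
#'
#' Spearman correlations for every within-group cross-genome homoeolog
#' pair, plus a null sample of SCCs for randomly drawn cross-genome pairs
#' of non-homoeologous genes.
#'
#' @param e An [expression_matrix] (gene-level rows) or gene x accession
#'   matrix.
#' @param triplets A [triplet_map].
#' @param n_random_pairs Size of the random-pair null sample.
#' @param seed RNG seed for the null draw.
#' @return list(pairs, random_scc): `pairs` is a data.table (triplet_id,
#'   gene1, gene2, pair, scc, n_used); `random_scc` a numeric vector.
#' @export
homoeolog_scc_profile <- function(e, triplets, n_random_pairs = 10000,
                                  seed = 1) {
  m <- if (is_expression_matrix(e)) gene_tpm(e) else e
  stopifnot(ncol(m) >= 3)
  mem <- triplet_members(triplets)
  mem <- mem[gene_id %in% rownames(m)]
  pairs <- mem[, {
    if (.N >= 2) {
      cmb <- utils::combn(seq_len(.N), 2)
      .(gene1 = gene_id[cmb[1, ]], gene2 = gene_id[cmb[2, ]],
        pair = paste0(pmin(genome[cmb[1, ]], genome[cmb[2, ]]),
                      pmax(genome[cmb[1, ]], genome[cmb[2, ]])))
    }
  }, by = triplet_id]
  pairs[, c("scc", "n_used") := {
    sc <- vapply(seq_len(.N), function(i) {
      suppressWarnings(spearman_scc(m[gene1[i], ], m[gene2[i], ]))
    }, numeric(1))
    nu <- vapply(seq_len(.N), function(i)
      sum(is.finite(m[gene1[i], ]) & is.finite(m[gene2[i], ])), integer(1))
    list(sc, nu)
  }]
  # null: cross-genome pairs excluding any within-group pair
  set.seed(seed)
  gg <- mem$genome[match(rownames(m), mem$gene_id)]
  tt <- mem$triplet_id[match(rownames(m), mem$gene_id)]
  idx <- which(!is.na(gg))
  random_scc <- numeric(0)
  if (length(idx) >= 2) {
    draws <- 0
    random_scc <- numeric(n_random_pairs)
    got <- 0
    while (got < n_random_pairs && draws < 50 * n_random_pairs) {
      draws <- draws + 1
      ij <- sample(idx, 2)
      if (gg[ij[1]] == gg[ij[2]] ||
          (!is.na(tt[ij[1]]) && identical(tt[ij[1]], tt[ij[2]]))) next
      got <- got + 1
      random_scc[got] <- suppressWarnings(
        spearman_scc(m[ij[1], ], m[ij[2], ]))
    }
    random_scc <- random_scc[seq_len(got)]
  }
  list(pairs = pairs[], random_scc = random_scc)
}

#' Dosage-compensation analysis of homoeolog triplets
#'
#' A triplet is eligible iff one homoeolog is downregulated
#' (TPM < `down_tpm`) in at least `min_lines` accessions while at least
#' `min_lines` accessions express all three members above `expr_tpm`.
#' Accessions are split into a one-down group (the focal member down,
#' both partners expressed) and an all-expressed group; the compensation
#' ratio is the ratio of the group means of total triplet expression
#' (A+B+D). A ratio of 2/3 marks no compensation, 1 full compensation.
#'
#' @param e Gene-level expression (matrix or [expression_matrix]), TPM.
#' @param triplets A [triplet_map].
#' @param down_tpm,expr_tpm,min_lines Eligibility thresholds.
#' @return list(ratios, n_ineligible): `ratios` per eligible triplet
#'   (triplet_id, down_gene, n_down, n_full, mean_down_total,
#'   mean_full_total, ratio).
#' @export
compensation_analysis <- function(e, triplets, down_tpm = 0.1, expr_tpm = 2,
                                  min_lines = 2) {
  m <- if (is_expression_matrix(e)) gene_tpm(e) else e
  t3 <- as.data.table(triplets)[class == "triplet"]
  out <- list(); n_inelig <- 0L
  for (i in seq_len(nrow(t3))) {
    gs <- unlist(t3[i, .(gene_A, gene_B, gene_D)])
    if (!all(gs %in% rownames(m))) { n_inelig <- n_inelig + 1L; next }
    x <- m[gs, , drop = FALSE]
    full <- colSums(x > expr_tpm) == 3
    down_counts <- rowSums(x < down_tpm)
    focal <- which(down_counts >= min_lines)
    if (!length(focal) || sum(full) < min_lines) {
      n_inelig <- n_inelig + 1L; next
    }
    focal <- focal[order(-down_counts[focal])][1]
    partners <- setdiff(seq_len(3), focal)
    down_grp <- x[focal, ] < down_tpm &
      colSums(x[partners, , drop = FALSE] > expr_tpm) == 2
    if (sum(down_grp) < min_lines) { n_inelig <- n_inelig + 1L; next }
    tot <- colSums(x)
    out[[length(out) + 1L]] <- data.table(
      triplet_id = t3$triplet_id[i], down_gene = gs[focal],
      n_down = sum(down_grp), n_full = sum(full),
      mean_down_total = mean(tot[down_grp]),
      mean_full_total = mean(tot[full]),
      ratio = mean(tot[down_grp]) / mean(tot[full]))
  }
  list(ratios = if (length(out)) rbindlist(out) else data.table(),
       n_ineligible = n_inelig)
}

#' Detect homoeologs with biased (negatively correlated) expression
#'
#' A triplet member is flagged iff its SCC is below `neg_thresh` with
#' both homoeologous partners and below `strong_thresh` with at least
#' one. Duplet members are evaluated against their single partner using
#' the strong threshold only and reported separately.
#'
#' @param pairs Pair SCC table from [homoeolog_scc_profile].
#' @param triplets A [triplet_map].
#' @param neg_thresh,strong_thresh SCC thresholds.
#' @return data.table (gene_id, triplet_id, set in \{triplet, duplet\},
#'   scc_min, scc_max) of flagged genes.
#' @export
detect_biased_homoeologs <- function(pairs, triplets, neg_thresh = 0,
                                     strong_thresh = -0.4) {
  pairs <- as.data.table(pairs)
  cls <- as.data.table(triplets)[, .(triplet_id, class)]
  mem <- triplet_members(triplets)
  flagged <- mem[, {
    g <- gene_id
    res <- lapply(g, function(gene) {
      pp <- pairs[triplet_id == .BY$triplet_id &
                  (gene1 == gene | gene2 == gene)]
      sc <- pp$scc[is.finite(pp$scc)]
      if (!length(sc)) return(NULL)
      k <- cls[triplet_id == .BY$triplet_id, class]
      hit <- if (k == "triplet")
        length(sc) == 2 && all(sc < neg_thresh) && any(sc < strong_thresh)
      else if (k == "duplet") any(sc < strong_thresh)
      else FALSE
      if (!hit) return(NULL)
      data.table(gene_id = gene, set = k, scc_min = min(sc),
                 scc_max = max(sc))
    })
    rbindlist(res)
  }, by = triplet_id]
  flagged[]
}

#' Per-accession count of low-expressing alleles
#'
#' For each gene in `genes`, an accession carries a low-expressing allele
#' iff its TPM is below `tpm_cap` AND below the gene's cross-accession
#' mean minus one sample standard deviation. The burden profile sums
#' these flags per accession over the gene set.
#'
#' @param e Gene-level TPM (matrix or [expression_matrix]).
#' @param genes Character vector of gene ids.
#' @param tpm_cap Absolute TPM cap for a low call.
#' @return Named integer vector (accession -> count), with attribute
#'   `"flags"` carrying the gene x accession logical matrix.
#' @export
count_low_expressing_alleles <- function(e, genes, tpm_cap = 3) {
  m <- if (is_expression_matrix(e)) gene_tpm(e) else e
  stopifnot(ncol(m) >= 3)
  genes <- intersect(genes, rownames(m))
  x <- m[genes, , drop = FALSE]
  thr <- rowMeans(x) - apply(x, 1, sd)
  flags <- x < tpm_cap & x < thr
  burden <- colSums(flags)
  attr(burden, "flags") <- flags
  burden
}

#' Correlation between expression-burden and a trait, with a random-set null
#'
#' SCC between the low-expressing-allele burden of a gene set and each
#' trait, compared with the SCCs obtained from random equal-size gene
#' sets drawn from the homoeologous-gene universe.
#'
#' @param e Gene-level TPM.
#' @param gene_set Genes defining the observed burden.
#' @param traits A trait table (accession, trait, value).
#' @param universe Gene universe for the null draws.
#' @param n_random_sets Number of null sets.
#' @param tpm_cap Low-expression cap passed to
#'   [count_low_expressing_alleles].
#' @param seed RNG seed.
#' @return data.table per trait: trait, scc, percentile (of |scc| in the
#'   null |scc| sample), n_accessions; attribute `"null"` holds the null
#'   SCC matrix (set x trait).
#' @export
burden_trait_correlation <- function(e, gene_set, traits, universe,
                                     n_random_sets = 1000, tpm_cap = 3,
                                     seed = 1) {
  m <- if (is_expression_matrix(e)) gene_tpm(e) else e
  traits <- as.data.table(traits)
  universe <- intersect(universe, rownames(m))
  gene_set <- intersect(gene_set, rownames(m))
  # flag matrix over the whole universe once; burdens are then subset sums
  flags <- attr(count_low_expressing_alleles(m, universe, tpm_cap), "flags")
  burden <- colSums(flags[gene_set, , drop = FALSE])
  set.seed(seed)
  null_sets <- replicate(n_random_sets,
                         sample(universe, length(gene_set)), simplify = FALSE)
  null_burdens <- vapply(null_sets, function(s)
    colSums(flags[s, , drop = FALSE]), numeric(ncol(m)))
  res <- traits[, {
    ok <- !is.na(value) & accession %in% colnames(m)
    acc <- accession[ok]; val <- value[ok]
    if (length(acc) < 10) stop("burden and trait share fewer than 10 accessions")
    b <- burden[acc]
    obs <- suppressWarnings(spearman_scc(b, val))
    nulls <- apply(null_burdens[match(acc, colnames(m)), , drop = FALSE], 2,
                   function(nb) suppressWarnings(spearman_scc(nb, val)))
    pct <- if (is.na(obs)) NA_real_ else
      mean(abs(obs) > abs(nulls), na.rm = TRUE) * 100
    .(scc = obs, percentile = pct, n_accessions = length(acc))
  }, by = trait]
  res[]
}

#' Rare-allele load in upstream regulatory regions, by expression rank
#'
#' Per gene, accessions are ranked by expression; each accession's load
#' is the count of minor alleles at rare (MAF < `maf_rare`) SNPs in the
#' 5-kb (by default) upstream window, oriented by strand. Ranks are
#' binned and the mean load per bin is averaged across genes.
#'
#' @param v A [variant_table].
#' @param genes A [gene_models] table (strand required).
#' @param e Gene-level expression.
#' @param upstream_bp Upstream window size.
#' @param maf_rare MAF threshold defining rare SNPs.
#' @param n_bins Number of expression-rank bins.
#' @return data.table (bin, mean_load); bin 1 = lowest expression.
#' @export
rare_allele_load_profile <- function(v, genes, e, upstream_bp = 5000,
                                     maf_rare = 0.05, n_bins = 5) {
  m <- if (is_expression_matrix(e)) gene_tpm(e) else e
  gtab <- as.data.table(genes)[gene_id %in% rownames(m)]
  if (any(gtab$strand == ".")) stop("strand required for upstream windows")
  rare <- v$snps$maf < maf_rare
  load_by_bin <- matrix(0, nrow(gtab), n_bins)
  n_acc <- ncol(m)
  bin_of <- ceiling(seq_len(n_acc) / n_acc * n_bins)
  for (i in seq_len(nrow(gtab))) {
    g <- gtab[i]
    lo <- if (g$strand == "-") g$end + 1 else g$start - upstream_bp
    hi <- if (g$strand == "-") g$end + upstream_bp else g$start - 1
    idx <- which(rare & v$snps$chrom == g$chrom & v$snps$pos >= lo &
                 v$snps$pos <= hi)
    load <- if (length(idx)) {
      d <- v$dosage[idx, , drop = FALSE]
      af <- rowMeans(d, na.rm = TRUE) / 2
      minor <- ifelse(af <= 0.5, 1, -1)
      cnt <- d
      flip <- which(minor < 0)
      cnt[flip, ] <- 2 - cnt[flip, ]
      colSums(cnt, na.rm = TRUE)
    } else rep(0, n_acc)
    o <- order(m[g$gene_id, ])
    load_by_bin[i, ] <- tapply(load[o], bin_of, mean)
  }
  data.table(bin = seq_len(n_bins), mean_load = colMeans(load_by_bin))
}

#' Inter-locus LD between homoeolog eQTL and partner-proximal SNPs
#'
#' For each flagged homoeolog pair, LD r-squared between the eQTL lead
#' SNP of one homoeolog (cis lead if present, else the strongest trans
#' lead) and every SNP within +/-`window_bp` of the partner gene; values
#' above `r2_min` are binned, the same is done for random homoeolog
#' pairs, and the per-bin count ratio (normalized by the number of pairs
#' in each group) is reported.
#'
#' @param v A [variant_table].
#' @param flagged_pairs data.table (gene1, gene2): gene1 carries the
#'   eQTL, gene2 is the partner.
#' @param eqtl Classified eQTL table with `transcript_id`, `class`,
#'   `lead_snp`, `lead_p`.
#' @param random_pairs data.table (gene1, gene2) of control pairs.
#' @param genes A [gene_models] table.
#' @param window_bp Partner window half-width.
#' @param r2_min Minimum retained LD.
#' @param breaks LD histogram breaks.
#' @return list(flagged, random, ratio, skipped): binned counts per group,
#'   per-bin normalized ratio, and the number of pairs without an eQTL.
#' @export
interlocus_ld_profile <- function(v, flagged_pairs, eqtl, random_pairs,
                                  genes, window_bp = 2e6, r2_min = 0.2,
                                  breaks = seq(0.2, 1, by = 0.1)) {
  eqtl <- as.data.table(eqtl)
  gtab <- as.data.table(genes)
  lead_for <- function(gene) {
    eg <- eqtl[transcript_id == gene]
    if (!nrow(eg)) return(NA_character_)
    eg <- eg[order(class != "cis", lead_p)]
    eg$lead_snp[1]
  }
  collect <- function(pairs) {
    pairs <- as.data.table(pairs)
    vals <- list(); used <- 0L; skipped <- 0L
    for (i in seq_len(nrow(pairs))) {
      lead <- lead_for(pairs$gene1[i])
      gi <- match(pairs$gene2[i], gtab$gene_id)
      if (is.na(lead) || is.na(gi)) { skipped <- skipped + 1L; next }
      mid <- (gtab$start[gi] + gtab$end[gi]) / 2
      idx <- which(v$snps$chrom == gtab$chrom[gi] &
                   abs(v$snps$pos - mid) <= window_bp)
      if (!length(idx)) { used <- used + 1L; next }
      g1 <- v$dosage[match(lead, v$snps$snp_id), ]
      r2 <- vapply(idx, function(j) ld_r2(g1, v$dosage[j, ]), numeric(1))
      r2 <- r2[!is.na(r2) & r2 > r2_min]
      used <- used + 1L
      if (length(r2)) vals[[length(vals) + 1L]] <- r2
    }
    list(r2 = unlist(vals), n_pairs = used, skipped = skipped)
  }
  fl <- collect(flagged_pairs)
  rn <- collect(random_pairs)
  hist_counts <- function(x) {
    if (!length(x)) return(rep(0, length(breaks) - 1))
    graphics::hist(pmin(x, max(breaks)), breaks = breaks,
                   plot = FALSE)$counts
  }
  hf <- hist_counts(fl$r2); hr <- hist_counts(rn$r2)
  ratio <- (hf / max(fl$n_pairs, 1)) / pmax(hr / max(rn$n_pairs, 1), 1e-12)
  ratio[hr == 0] <- NA_real_
  list(flagged = data.table(bin_lo = head(breaks, -1),
                            bin_hi = tail(breaks, -1), count = hf),
       random = data.table(bin_lo = head(breaks, -1),
                           bin_hi = tail(breaks, -1), count = hr),
       ratio = ratio, skipped = fl$skipped + rn$skipped)
}
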