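# Synthetic diploidized-allohexaploid cohort generator. Three subgenomes
# (A/B/D), homoeolog triplets/duplets/singletons, planted cis- and
# trans-acting variants, silencing alleles with partial dosage compensation,
# hidden expression factors, and burden-linked traits. Every planted effect
# is recorded in a truth registry so downstream stages can be scored
# against ground truth.

#' Configuration for the synthetic allopolyploid cohort
#'
#' Defaults describe a modest inbred hexaploid panel: 200 accessions, 200
#' homoeolog triplets across two chromosomes per subgenome, log-normal
#' expression noise, a subset of triplets carrying a near-complete
#' silencing allele, and partial dosage compensation redistributing a
#' fraction `compensation` of a silenced homoeolog's lost expression to
#' its surviving partners.
#'
#' @param n_accessions Number of inbred accessions (>= 10).
#' @param n_triplets,n_duplets,n_singletons Homoeolog group counts.
#' @param chroms_per_genome Chromosomes per subgenome.
#' @param snps_per_chrom SNPs per chromosome, evenly spaced.
#' @param snp_spacing_bp Spacing between SNPs in bp.
#' @param maf_range Allele frequencies drawn uniformly from this range.
#' @param ld_decay_bp Length scale of linkage disequilibrium: haplotypes
#'   come from a latent Gaussian AR(1) process along each chromosome with
#'   correlation exp(-distance/ld_decay_bp), so LD decays over a few
#'   hundred kb as in inbred crop panels. 0 gives independent SNPs.
#' @param cis_prob,cis_beta_sd Per-gene probability of a cis variant within
#'   1 Mb, and the SD of its effect on log2 expression per dosage unit.
#' @param trans_prob,trans_beta_sd,trans_share_prob Per-triplet probability
#'   of a trans variant (different chromosome), its effect-size SD, and the
#'   probability the effect is shared by all members of the group rather
#'   than hitting a single member.
#' @param cross_reg_prob,cross_reg_beta Probability that a triplet receives
#'   a single variant acting in cis (up) on one member and in trans (down,
#'   `-cross_reg_beta`) on another member — the cis-as-trans configuration.
#' @param silencing_prob Fraction of triplets carrying a silencing allele
#'   on one random member.
#' @param silencing_freq Population frequency of the silencing allele.
#' @param silencing_depth Fractional expression of the silenced
#'   (homozygous) allele; 0.02 keeps ~2% of transcript output.
#' @param compensation Compensation coefficient c in \[0, 1\]: fraction of
#'   a silenced homoeolog's lost TPM added to its surviving partners.
#' @param n_hidden,hidden_scale Hidden expression factors (batch-like) and
#'   the SD of their per-gene loadings on log2 expression.
#' @param noise_sd SD of per-gene log2 expression noise.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 TPM, drawn per
#'   homoeolog group (triplet-level): homoeologous copies share ancestral
#'   regulatory context and hence similar abundance.
#' @param baseline_member_sd SD of each member's deviation from its
#'   group's baseline.
#' @param rare_down_prob,rare_down_beta,rare_maf_range Optional rare
#'   regulatory variants planted in the 5-kb upstream window with
#'   (typically negative) effect `rare_down_beta`.
#' @param traits Named list; each element is a list with `burden`
#'   (trait units per low-expressing allele), `pleio_n`/`pleio_sd`
#'   (direct SNP effects) and `noise_sd`.
#' @param structure_pools,structure_fst Optional admixture population
#'   structure: number of ancestral pools (NULL for none) and the
#'   Balding-Nichols differentiation parameter.
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 200, n_triplets = 200, n_duplets = 10,
                       n_singletons = 10, chroms_per_genome = 2,
                       snps_per_chrom = 500, snp_spacing_bp = 10000,
                       maf_range = c(0.05, 0.5), ld_decay_bp = 250000,
                       cis_prob = 0.5, cis_beta_sd = 0.6,
                       trans_prob = 0.3, trans_beta_sd = 0.4,
                       trans_share_prob = 0.5,
                       cross_reg_prob = 0, cross_reg_beta = 0.8,
                       silencing_prob = 0.1, silencing_freq = 0.3,
                       silencing_depth = 0.02, compensation = 0.7,
                       n_hidden = 2, hidden_scale = 0.2, noise_sd = 0.3,
                       baseline_log2_mean = 3, baseline_log2_sd = 1,
                       baseline_member_sd = 0.25,
                       rare_down_prob = 0, rare_down_beta = -1.5,
                       rare_maf_range = c(0.005, 0.045),
                       traits = list(
                         yield = list(burden = -0.3, pleio_n = 2,
                                      pleio_sd = 0.5, noise_sd = 4),
                         height = list(burden = 0, pleio_n = 2,
                                       pleio_sd = 0.5, noise_sd = 4)),
                       structure_pools = NULL, structure_fst = 0.1,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_accessions >= 10,
            cfg$compensation >= 0, cfg$compensation <= 1,
            all(vapply(cfg[c("cis_prob", "trans_prob", "trans_share_prob",
                             "cross_reg_prob", "silencing_prob",
                             "silencing_freq")], function(p)
                             p >= 0 && p <= 1, logical(1))),
            cfg$silencing_depth >= 0, cfg$silencing_depth <= 1)
  structure(cfg, class = "sim_config")
}

# deterministic sub-streams: each generation stage reseeds from the base
# seed so stages stay reproducible if upstream stages change
sub_seed <- function(cfg, k) (cfg$seed * 97 + k * 1009) %% .Machine$integer.max

#' Simulate a synthetic allopolyploid cohort
#'
#' @param cfg A [sim_config].
#' @return list(variants, expression, genes, triplets, traits, truth)
#'   where `truth` registers planted cis/trans effects, silencing alleles
#'   and trait architecture.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  acc <- sprintf("acc%03d", seq_len(cfg$n_accessions))

  ## --- genome layout -------------------------------------------------
  genomes <- c("A", "B", "D")
  chroms <- as.vector(outer(seq_len(cfg$chroms_per_genome), genomes,
                            function(k, g) paste0("chr", k, g)))
  chrom_len <- cfg$snps_per_chrom * cfg$snp_spacing_bp

  ## --- genotypes ------------------------------------------------------
  set.seed(sub_seed(cfg, 1))
  n_snp <- length(chroms) * cfg$snps_per_chrom
  snp_chrom <- rep(chroms, each = cfg$snps_per_chrom)
  snp_pos <- rep.int(as.integer(seq_len(cfg$snps_per_chrom) *
                                cfg$snp_spacing_bp - cfg$snp_spacing_bp / 2),
                     length(chroms))
  snp_id <- paste0(snp_chrom, "_", snp_pos)
  af <- runif(n_snp, cfg$maf_range[1], cfg$maf_range[2])
  # per-accession allele-frequency thresholds (optionally pool-specific)
  if (is.null(cfg$structure_pools)) {
    thr <- matrix(stats::qnorm(af), n_snp, cfg$n_accessions)
  } else {
    k <- cfg$structure_pools
    f <- cfg$structure_fst
    pool_p <- matrix(stats::rbeta(n_snp * k,
                                  rep(af, k) * (1 - f) / f,
                                  rep(1 - af, k) * (1 - f) / f), nrow = n_snp)
    pool_p <- pmin(pmax(pool_p, 1e-4), 1 - 1e-4)
    pool <- sample.int(k, cfg$n_accessions, replace = TRUE)
    thr <- stats::qnorm(pool_p[, pool])
  }
  # latent Gaussian AR(1) along each chromosome gives geometric LD decay;
  # thresholding at qnorm(af) preserves the per-SNP allele frequency
  rho <- if (cfg$ld_decay_bp > 0)
    exp(-cfg$snp_spacing_bp / cfg$ld_decay_bp) else 0
  lat <- matrix(rnorm(n_snp * cfg$n_accessions), n_snp)
  if (rho > 0) {
    sc <- sqrt(1 - rho^2)
    for (ch in seq_along(chroms)) {
      rows <- ((ch - 1) * cfg$snps_per_chrom + 1):(ch * cfg$snps_per_chrom)
      for (s in rows[-1]) lat[s, ] <- rho * lat[s - 1, ] + sc * lat[s, ]
    }
  }
  hap <- (lat < thr) + 0L
  dosage <- 2 * hap
  dimnames(dosage) <- list(snp_id, acc)

  ## --- gene models ----------------------------------------------------
  set.seed(sub_seed(cfg, 2))
  n_groups <- cfg$n_triplets + cfg$n_duplets + cfg$n_singletons
  group_chrom_idx <- ((seq_len(n_groups) - 1) %% cfg$chroms_per_genome) + 1
  slots_per_chrom <- ceiling(n_groups / cfg$chroms_per_genome)
  slot <- ((seq_len(n_groups) - 1) %/% cfg$chroms_per_genome) + 1
  gene_start <- as.integer(round(slot * chrom_len / (slots_per_chrom + 1)))
  gene_len <- 3000L
  group_class <- rep(c("triplet", "duplet", "singleton"),
                     c(cfg$n_triplets, cfg$n_duplets, cfg$n_singletons))
  member_genomes <- lapply(seq_len(n_groups), function(i) {
    switch(group_class[i],
           triplet = genomes,
           duplet = sort(sample(genomes, 2)),
           singleton = sample(genomes, 1))
  })
  gm <- rbindlist(lapply(seq_len(n_groups), function(i) {
    gs <- member_genomes[[i]]
    data.table(gene_id = sprintf("G%04d%s", i, gs),
               triplet_id = sprintf("T%04d", i),
               genome = gs,
               chrom = paste0("chr", group_chrom_idx[i], gs),
               start = gene_start[i], end = gene_start[i] + gene_len - 1L,
               strand = rep(c("+", "-"), length.out = length(gs)))
  }))
  genes <- gene_models(gm$gene_id, gm$chrom, gm$start, gm$end, gm$strand)
  trip_wide <- dcast(gm, triplet_id ~ genome, value.var = "gene_id")
  for (g in genomes) if (!g %in% names(trip_wide)) trip_wide[, (g) := NA_character_]
  triplets <- triplet_map(trip_wide$triplet_id, trip_wide$A, trip_wide$B,
                          trip_wide$D)

  ## --- regulatory architecture ----------------------------------------
  set.seed(sub_seed(cfg, 3))
  snp_dt <- data.table(snp_id = snp_id, chrom = snp_chrom, pos = snp_pos)
  pick_cis_snp <- function(chrom_, pos_, win = 1e6) {
    i <- which(snp_dt$chrom == chrom_ & abs(snp_dt$pos - pos_) <= win)
    if (!length(i)) return(NA_integer_)
    sample(i, 1)
  }
  pick_trans_snp <- function(chrom_) {
    i <- which(snp_dt$chrom != chrom_)
    sample(i, 1)
  }
  cis_truth <- list(); trans_truth <- list(); sil_truth <- list()
  cross_truth <- list()
  effects <- vector("list", nrow(gm))   # per gene: list of (snp index, beta)
  names(effects) <- gm$gene_id
  add_effect <- function(gene, idx, beta) {
    effects[[gene]][[length(effects[[gene]]) + 1]] <<- c(idx, beta)
  }
  for (i in seq_len(nrow(gm))) {
    if (runif(1) < cfg$cis_prob) {
      idx <- pick_cis_snp(gm$chrom[i], gm$start[i])
      if (!is.na(idx)) {
        beta <- rnorm(1, 0, cfg$cis_beta_sd)
        add_effect(gm$gene_id[i], idx, beta)
        cis_truth[[length(cis_truth) + 1]] <-
          data.table(gene_id = gm$gene_id[i], snp_id = snp_id[idx], beta = beta)
      }
    }
  }
  for (t in seq_len(n_groups)) {
    members <- which(gm$triplet_id == sprintf("T%04d", t))
    if (runif(1) < cfg$trans_prob) {
      idx <- pick_trans_snp(gm$chrom[members[1]])
      beta <- rnorm(1, 0, cfg$trans_beta_sd)
      shared <- runif(1) < cfg$trans_share_prob
      hit <- if (shared) members else sample(members, 1)
      for (m in hit) {
        add_effect(gm$gene_id[m], idx, beta)
        trans_truth[[length(trans_truth) + 1]] <-
          data.table(gene_id = gm$gene_id[m], snp_id = snp_id[idx],
                     beta = beta, shared = shared)
      }
    }
    if (length(members) >= 2 && runif(1) < cfg$cross_reg_prob) {
      up <- members[1]; down <- members[2]
      idx <- pick_cis_snp(gm$chrom[up], gm$start[up])
      if (!is.na(idx)) {
        add_effect(gm$gene_id[up], idx, cfg$cross_reg_beta)
        add_effect(gm$gene_id[down], idx, -cfg$cross_reg_beta)
        cross_truth[[length(cross_truth) + 1]] <-
          data.table(triplet_id = sprintf("T%04d", t), snp_id = snp_id[idx],
                     cis_gene = gm$gene_id[up], trans_gene = gm$gene_id[down],
                     beta = cfg$cross_reg_beta)
      }
    }
  }

  ## --- rare regulatory variants in the upstream 5-kb window -----------
  set.seed(sub_seed(cfg, 4))
  if (cfg$rare_down_prob > 0) {
    for (i in seq_len(nrow(gm))) {
      if (runif(1) >= cfg$rare_down_prob) next
      up_lo <- if (gm$strand[i] == "-") gm$end[i] + 1 else gm$start[i] - 5000
      up_hi <- if (gm$strand[i] == "-") gm$end[i] + 5000 else gm$start[i] - 1
      idx <- which(snp_dt$chrom == gm$chrom[i] & snp_dt$pos >= up_lo &
                   snp_dt$pos <= up_hi)
      if (!length(idx)) next
      idx <- sample(idx, 1)
      p_rare <- runif(1, cfg$rare_maf_range[1], cfg$rare_maf_range[2])
      dosage[idx, ] <- 2 * rbinom(cfg$n_accessions, 1, p_rare)
      add_effect(gm$gene_id[i], idx, cfg$rare_down_beta)
      cis_truth[[length(cis_truth) + 1]] <-
        data.table(gene_id = gm$gene_id[i], snp_id = snp_id[idx],
                   beta = cfg$rare_down_beta)
    }
  }

  ## --- silencing alleles ----------------------------------------------
  set.seed(sub_seed(cfg, 5))
  sil_mult <- matrix(1, nrow(gm), cfg$n_accessions,
                     dimnames = list(gm$gene_id, acc))
  for (t in seq_len(n_groups)) {
    if (group_class[t] != "triplet" || runif(1) >= cfg$silencing_prob) next
    members <- which(gm$triplet_id == sprintf("T%04d", t))
    m <- sample(members, 1)
    idx <- pick_cis_snp(gm$chrom[m], gm$start[m])
    if (is.na(idx)) next
    # dedicate the SNP to silencing: regenerate at the requested frequency
    dosage[idx, ] <- 2 * rbinom(cfg$n_accessions, 1, cfg$silencing_freq)
    sil_mult[m, dosage[idx, ] == 2] <- cfg$silencing_depth
    sil_truth[[length(sil_truth) + 1]] <-
      data.table(triplet_id = sprintf("T%04d", t), gene_id = gm$gene_id[m],
                 snp_id = snp_id[idx], freq = cfg$silencing_freq,
                 depth = cfg$silencing_depth)
  }

  ## --- expression ------------------------------------------------------
  set.seed(sub_seed(cfg, 6))
  group_base <- rnorm(n_groups, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  baseline <- group_base[match(gm$triplet_id, sprintf("T%04d", seq_len(n_groups)))] +
    rnorm(nrow(gm), 0, cfg$baseline_member_sd)
  factors <- matrix(rnorm(cfg$n_hidden * cfg$n_accessions),
                    nrow = cfg$n_hidden)
  loadings <- matrix(rnorm(nrow(gm) * cfg$n_hidden, 0, cfg$hidden_scale),
                     nrow = nrow(gm))
  log2x <- matrix(baseline, nrow(gm), cfg$n_accessions) +
    (if (cfg$n_hidden > 0) loadings %*% factors else 0) +
    matrix(rnorm(nrow(gm) * cfg$n_accessions, 0, cfg$noise_sd), nrow(gm))
  for (g in seq_len(nrow(gm))) {
    for (ef in effects[[gm$gene_id[g]]])
      log2x[g, ] <- log2x[g, ] + ef[2] * dosage[ef[1], ]
  }
  tpm_nosil <- 2^log2x
  tpm <- tpm_nosil * sil_mult
  ## partial dosage compensation: a fraction c of each silenced copy's
  ## lost output is redistributed to the surviving members of its group
  lost <- tpm_nosil - tpm
  if (cfg$compensation > 0 && any(lost > 0)) {
    for (t in unique(gm$triplet_id[rowSums(lost) > 0])) {
      members <- which(gm$triplet_id == t)
      if (length(members) < 2) next
      for (j in seq_len(cfg$n_accessions)) {
        li <- lost[members, j]
        if (all(li == 0)) next
        survivors <- members[sil_mult[members, j] == 1]
        if (!length(survivors)) next
        tpm[survivors, j] <- tpm[survivors, j] +
          cfg$compensation * sum(li) / length(survivors)
      }
    }
  }
  dimnames(tpm) <- list(gm$gene_id, acc)
  expr <- expression_matrix(round(tpm, 6), gene_id = gm$gene_id)

  ## --- traits ----------------------------------------------------------
  set.seed(sub_seed(cfg, 7))
  sil_dt <- if (length(sil_truth)) rbindlist(sil_truth) else
    data.table(triplet_id = character(), gene_id = character(),
               snp_id = character(), freq = numeric(), depth = numeric())
  burden_true <- if (nrow(sil_dt))
    colSums(sil_mult[sil_dt$gene_id, , drop = FALSE] < 1) else
    rep(0, cfg$n_accessions)
  trait_rows <- list(); trait_truth <- list()
  for (tn in names(cfg$traits)) {
    ts <- cfg$traits[[tn]]
    pleio <- data.table(snp_id = character(), beta = numeric())
    val <- ts$burden * burden_true
    if (ts$pleio_n > 0) {
      idx <- sample.int(n_snp, ts$pleio_n)
      b <- rnorm(ts$pleio_n, 0, ts$pleio_sd)
      val <- val + as.vector(t(dosage[idx, , drop = FALSE]) %*% b)
      pleio <- data.table(snp_id = snp_id[idx], beta = b)
    }
    val <- val + rnorm(cfg$n_accessions, 0, ts$noise_sd)
    trait_rows[[tn]] <- data.table(accession = acc, trait = tn,
                                   value = round(val, 6))
    trait_truth[[tn]] <- list(burden_coef = ts$burden,
                              burden_genes = sil_dt$gene_id, pleio = pleio)
  }
  traits <- rbindlist(trait_rows)
  setattr(traits, "class", c("trait_table", "data.table", "data.frame"))

  v <- variant_table(dosage, snp_chrom, snp_pos)
  truth <- list(
    cis = if (length(cis_truth)) rbindlist(cis_truth) else
      data.table(gene_id = character(), snp_id = character(), beta = numeric()),
    trans = if (length(trans_truth)) rbindlist(trans_truth) else
      data.table(gene_id = character(), snp_id = character(),
                 beta = numeric(), shared = logical()),
    cross = if (length(cross_truth)) rbindlist(cross_truth) else NULL,
    silencing = sil_dt,
    burden_true = setNames(burden_true, acc),
    traits = trait_truth
  )
  list(variants = v, expression = expr, genes = genes, triplets = triplets,
       traits = traits, truth = truth, config = cfg)
}

#' Write a simulated cohort to disk in the standard formats
#'
#' Emits genotypes.vcf, expression.tsv, genes.bed, triplets.tsv,
#' traits.tsv and truth.json, all readable by the package's loaders.
#'
#' @param sim Output of [simulate_cohort].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- sim$variants
  gtc <- c("0/0", "0/1", "1/1")
  gt <- matrix(gtc[v$dosage + 1], nrow(v$dosage))
  gt[is.na(v$dosage)] <- "./."
  body <- data.table(
    CHROM = v$snps$chrom, POS = v$snps$pos, ID = v$snps$snp_id,
    REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS", INFO = ".",
    FORMAT = "GT")
  body <- cbind(body, as.data.table(gt))
  setnames(body, c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(v$dosage)))
  vcf_path <- file.path(dir, "genotypes.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             vcf_path)
  fwrite(body, vcf_path, sep = "\t", append = TRUE, col.names = TRUE)

  e <- sim$expression
  ed <- data.table(transcript_id = rownames(e$tpm), gene_id = unname(e$genes))
  ed <- cbind(ed, as.data.table(e$tpm))
  fwrite(ed, file.path(dir, "expression.tsv"), sep = "\t")

  g <- sim$genes
  bed <- data.table(chrom = g$chrom, start = g$start - 1L, end = g$end,
                    name = g$gene_id, score = 0L, strand = g$strand)
  fwrite(bed, file.path(dir, "genes.bed"), sep = "\t", col.names = FALSE)

  fwrite(as.data.table(sim$triplets)[, .(triplet_id, gene_A, gene_B, gene_D)],
         file.path(dir, "triplets.tsv"), sep = "\t")
  fwrite(sim$traits, file.path(dir, "traits.tsv"), sep = "\t")
  jsonlite::write_json(
    lapply(sim$truth[c("cis", "trans", "silencing")], as.data.frame),
    file.path(dir, "truth.json"), dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Simulate a binned chromatin-contact table
#'
#' Poisson background counts for every bin pair across the chromosomes
#' spanned by `genes`, with selected pairs elevated by a fold factor.
#'
#' @param genes A [gene_models] table defining the chromosome extents.
#' @param elevated List of `list(chromA, posA, chromB, posB, fold)` entries;
#'   positions are mapped to bins.
#' @param baseline Poisson mean for background bin pairs.
#' @param bin_size Bin width in bp.
#' @param seed RNG seed.
#' @return A `contact_matrix`.
#' @export
simulate_contacts <- function(genes, elevated = list(), baseline = 20,
                              bin_size = 1e6, seed = 1) {
  stopifnot(all(vapply(elevated, function(p) is.null(p$fold) || p$fold >= 1,
                       logical(1))))
  set.seed(seed)
  ext <- as.data.table(genes)[, .(len = max(end)), by = chrom]
  bins <- ext[, .(bin = seq(0, contact_bin(len, bin_size), by = bin_size)),
              by = chrom]
  n <- nrow(bins)
  pairs <- CJ(i = seq_len(n), j = seq_len(n))[i <= j]
  cm <- data.table(chromA = bins$chrom[pairs$i], binA = bins$bin[pairs$i],
                   chromB = bins$chrom[pairs$j], binB = bins$bin[pairs$j])
  lambda <- rep(baseline, nrow(cm))
  for (el in elevated) {
    ba <- contact_bin(el$posA, bin_size); bb <- contact_bin(el$posB, bin_size)
    hit <- (cm$chromA == el$chromA & cm$binA == ba &
            cm$chromB == el$chromB & cm$binB == bb) |
           (cm$chromA == el$chromB & cm$binA == bb &
            cm$chromB == el$chromA & cm$binB == ba)
    lambda[hit] <- lambda[hit] * el$fold
  }
  cm$count <- rpois(nrow(cm), lambda)
  contact_matrix(cm, bin_size = bin_size)
}

#' Simulate an LD region of inbred dosages
#'
#' Haplotypes are generated as a Markov chain along the SNPs: each SNP
#' copies its left neighbour's allele and flips it with probability
#' `flip_rate`, giving geometrically decaying LD. Optional causal pair:
#' SNP `causal2` is regenerated from SNP `causal1` with a flip rate chosen
#' so their allele correlation is `r_causal`.
#'
#' @param n Accessions.
#' @param n_snps SNPs in the region.
#' @param p Allele frequency of the founder SNP (frequencies stay near p).
#' @param flip_rate Per-step allele flip probability.
#' @param causal1,causal2,r_causal Optional indices of a causal SNP pair
#'   and their target allele correlation.
#' @param seed RNG seed.
#' @return Dosage matrix (SNP x accession, 0/2 coding) with SNP ids
#'   `snp01`...; accession ids `acc001`....
#' @export
simulate_ld_region <- function(n = 400, n_snps = 30, p = 0.5,
                               flip_rate = 0.08, causal1 = NULL,
                               causal2 = NULL, r_causal = sqrt(0.5),
                               seed = 1) {
  set.seed(seed)
  hap <- matrix(0L, n_snps, n)
  hap[1, ] <- rbinom(n, 1, p)
  for (s in 2:n_snps) {
    flip <- rbinom(n, 1, flip_rate)
    hap[s, ] <- ifelse(flip == 1, 1L - hap[s - 1, ], hap[s - 1, ])
  }
  if (!is.null(causal1) && !is.null(causal2)) {
    # for p = 0.5, cor(h1, h2) = 1 - 2 * flip probability
    f <- (1 - r_causal) / 2
    flip <- rbinom(n, 1, f)
    hap[causal2, ] <- ifelse(flip == 1, 1L - hap[causal1, ], hap[causal1, ])
  }
  d <- 2 * hap
  dimnames(d) <- list(sprintf("snp%02d", seq_len(n_snps)),
                      sprintf("acc%03d", seq_len(n)))
  d
}

#' Simulate phenotypes with a known variance-component structure
#'
#' Given SNP partitions, draws per-gene phenotypes y = sum_c u_c + e with
#' u_c = Z_c a_c * sigma_c / sqrt(m_c) so that Var(u_c) = sigma2_c * G_c
#' exactly, where Z_c is the standardized dosage matrix of partition c.
#' Used to validate the REML variance partitioner against ground truth.
#'
#' @param v A [variant_table].
#' @param partitions Named list of snp_id vectors.
#' @param fractions Variance fractions per partition (sum < 1); the
#'   residual takes the remainder, total variance 1.
#' @param n_genes Number of phenotype vectors to draw.
#' @param seed RNG seed.
#' @return Matrix n_genes x accessions.
#' @export
simulate_varcomp_phenotypes <- function(v, partitions, fractions, n_genes,
                                        seed = 1) {
  stopifnot(length(partitions) == length(fractions), sum(fractions) < 1)
  set.seed(seed)
  n <- ncol(v$dosage)
  Zs <- lapply(partitions, function(ids) {
    d <- v$dosage[match(ids, v$snps$snp_id), , drop = FALSE]
    standardize_dosage(d)
  })
  y <- matrix(rnorm(n_genes * n, 0, sqrt(1 - sum(fractions))), n_genes, n)
  for (c in seq_along(Zs)) {
    m <- nrow(Zs[[c]])
    a <- matrix(rnorm(n_genes * m), n_genes, m)
    y <- y + sqrt(fractions[c] / m) * (a %*% Zs[[c]])
  }
  colnames(y) <- colnames(v$dosage)
  rownames(y) <- sprintf("gene%04d", seq_len(n_genes))
  y
}
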