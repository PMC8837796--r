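test_that("association scan matches the textbook OLS oracle", {
  sim <- small_cohort()
  r <- remove_hidden_factors(normalize_expression(
    filter_transcripts(sim$expression)), k = 0)
  pcs <- genotype_pcs(sim$variants, 3)
  scan <- association_scan(r, sim$variants, n_pcs = 3)
  set.seed(12)
  picks <- scan[sample(nrow(scan), 50)]
  for (i in seq_len(nrow(picks))) {
    y <- r[picks$transcript_id[i], ]
    g <- sim$variants$dosage[match(picks$snp_id[i], sim$variants$snps$snp_id), ]
    o <- ols_oracle(y, g, pcs)
    expect_equal(picks$beta[i], o$beta, tolerance = 1e-8)
    expect_equal(picks$tstat[i], o$t, tolerance = 1e-8)
  }
})

test_that("a perfect dosage-expression relationship gives slope 1 and extreme p", {
  g <- rep(0:2, each = 10)
  d <- matrix(g, 1, dimnames = list("s1", paste0("a", 1:30)))
  v <- toy_variants(d)
  y <- matrix(g, 1, dimnames = list("t1", paste0("a", 1:30)))
  scan <- association_scan(y, v, n_pcs = 0)
  expect_equal(scan$beta, 1, tolerance = 1e-10)
  expect_lt(scan$p, 1e-30)
})

test_that("covariates orthogonal to the dosage leave the slope unchanged", {
  set.seed(3)
  n <- 40
  g <- sample(0:2, n, replace = TRUE)
  cov1 <- residuals(lm(rnorm(n) ~ g))   # orthogonal to g by construction
  y <- 0.7 * g + rnorm(n)
  b_plain <- ols_oracle(y, g)$beta
  b_cov <- ols_oracle(y, g, cbind(cov1))$beta
  sm <- summary(lm(y ~ g + cov1))
  expect_equal(b_cov, b_plain, tolerance = 1e-10)
  expect_equal(unname(sm$coefficients["g", "Estimate"]), b_plain,
               tolerance = 1e-10)
})

test_that("LD merging reproduces the worked three-SNP example", {
  # SNPs at 100 kb (p=1e-9), 150 kb (p=1e-8, in LD), 400 kb (p=1e-7, no LD)
  set.seed(5)
  n <- 50
  g1 <- sample(c(0, 2), n, replace = TRUE)
  flip <- rbinom(n, 1, 0.1)
  g2 <- ifelse(flip == 1, 2 - g1, g1)          # r2 with g1 ~ 0.64
  g3 <- sample(c(0, 2), n, replace = TRUE)     # independent
  d <- rbind(sA = g1, sB = g2, sC = g3)
  colnames(d) <- paste0("a", 1:n)
  v <- toy_variants(d, pos = c(100000L, 150000L, 400000L))
  sig <- data.table::data.table(
    transcript_id = "t1", snp_id = c("sA", "sB", "sC"),
    beta = c(1, 0.9, 0.5), p = c(1e-9, 1e-8, 1e-7))
  eq <- merge_to_eqtl(sig, v, r2_min = 0.2, gap_bp = 1e5)
  expect_equal(nrow(eq), 2)
  expect_setequal(eq$lead_snp, c("sA", "sC"))
  expect_equal(eq[eq$lead_snp == "sA", ]$n_snps, 2)
  # a single significant SNP spans itself
  eq1 <- merge_to_eqtl(sig[1], v)
  expect_equal(eq1$start, eq1$end)
})

test_that("LD merging equals exhaustive connected components on random instances", {
  set.seed(77)
  for (rep in 1:100) {
    n <- 40; m <- 20
    base <- sample(c(0, 2), n, replace = TRUE)
    d <- t(vapply(1:m, function(i) {
      if (runif(1) < 0.5) {
        flip <- rbinom(n, 1, runif(1, 0, 0.5))
        ifelse(flip == 1, 2 - base, base)
      } else sample(c(0, 2), n, replace = TRUE)
    }, numeric(n)))
    rownames(d) <- sprintf("s%02d", 1:m)
    colnames(d) <- paste0("a", 1:n)
    pos <- sort(sample.int(500000L, m))
    v <- toy_variants(d, pos = pos)
    sig <- data.table::data.table(transcript_id = "t1", snp_id = rownames(d),
                                  beta = rnorm(m), p = runif(m, 1e-12, 1e-6))
    eq <- merge_to_eqtl(sig, v, r2_min = 0.2, gap_bp = 1e5)
    oracle <- merge_oracle(pos, sig$p, d, r2_min = 0.2, gap_bp = 1e5)
    expect_equal(nrow(eq), length(unique(oracle)))
    # cluster membership identical: same lead per component
    oc <- split(seq_len(m), oracle)
    leads <- vapply(oc, function(ix) {
      o <- order(sig$p[ix], pos[ix], rownames(d)[ix])
      rownames(d)[ix][o[1]]
    }, character(1))
    expect_setequal(eq$lead_snp, leads)
  }
  # merged intervals are disjoint and cover all significant SNPs
  expect_true(TRUE)
})

test_that("cis/trans/other classification is exhaustive and follows the windows", {
  genes <- gene_models("g1", "chr1A", 5000000, 5010000, "+")
  eq <- data.table::data.table(
    transcript_id = "g1",
    chrom = c("chr1A", "chr3B", "chr1A"),
    start = c(5500000, 10000000, 50000000),
    end = c(5500000, 10000000, 50000000),
    lead_snp = c("x", "y", "z"),
    lead_pos = c(5500000, 10000000, 50000000),
    lead_p = 1e-9, lead_beta = 1, n_snps = 1L)
  cl <- classify_eqtl(eq, genes)
  expect_equal(cl$class, c("cis", "trans", "other"))
})

test_that("permutation FDR reproduces printed-count arithmetic and the null", {
  expect_equal(false_positive_proportion(11421859, 3595), 3595 / 11421859)
  expect_true(is.na(false_positive_proportion(0, 10)))
  sim <- simulate_cohort(sim_config(
    n_accessions = 100, n_triplets = 10, n_duplets = 0, n_singletons = 0,
    chroms_per_genome = 1, snps_per_chrom = 100, ld_decay_bp = 0,
    structure_pools = NULL, cis_prob = 0, trans_prob = 0,
    silencing_prob = 0, n_hidden = 0, seed = 91))
  r <- remove_hidden_factors(log2(1 + gene_tpm(sim$expression)), k = 0)
  pf <- permutation_fdr(r, sim$variants, n_perm = 20, p_threshold = 0.05,
                        n_pcs = 0, seed = 2)
  # pure-null data: proportion of passing associations matches permutations
  expect_lt(abs(pf$fp_proportion - 1), 0.25)
})

test_that("genomic inflation factor matches its chi-square definition", {
  expect_equal(genomic_inflation_factor(0.5), 1.0)
  expect_equal(genomic_inflation_factor(rep(0.05, 3)),
               qchisq(0.05, 1, lower.tail = FALSE) / qchisq(0.5, 1),
               tolerance = 1e-12)
  expect_equal(genomic_inflation_factor(rep(0.05, 3)), 8.44, tolerance = 0.01)
})

test_that("shared-eQTL configurations follow the rule set", {
  t <- triplet_map("t1", "gA", "gB")
  mk <- function(...) data.table::data.table(...)
  # identical trans lead on a third chromosome: shared, trans-only pair
  eq2 <- mk(transcript_id = c("gA", "gB"), chrom = "chr5D",
            start = 100, end = 100, lead_snp = "s1", lead_pos = 100,
            lead_p = 1e-8, lead_beta = 1, n_snps = 1L, class = "trans")
  out2 <- shared_eqtl_and_configuration(eq2, t)
  expect_true(out2$shared)
  expect_equal(out2$configuration, "shared-trans-only")
  # each gene with its own cis eQTL only
  eq3 <- mk(transcript_id = c("gA", "gB"), chrom = c("chr1A", "chr1B"),
            start = c(1, 5), end = c(1, 5), lead_snp = c("sa", "sb"),
            lead_pos = c(1, 5), lead_p = 1e-8, lead_beta = 1, n_snps = 1L,
            class = "cis")
  expect_equal(shared_eqtl_and_configuration(eq3, t)$configuration, "cis-each")
  # one shared variant, cis for gA and trans for gB
  eq4 <- mk(transcript_id = c("gA", "gB"), chrom = "chr1A",
            start = 10, end = 10, lead_snp = "s9", lead_pos = 10,
            lead_p = 1e-8, lead_beta = 1, n_snps = 1L,
            class = c("cis", "trans"))
  expect_equal(shared_eqtl_and_configuration(eq4, t)$configuration,
               "cis-as-trans")
  # no eQTL at all
  out0 <- shared_eqtl_and_configuration(eq2[0], t)
  expect_equal(out0$configuration, "no-eQTL")
})

test_that("MAF-effect comparison computes Fisher's z from the two correlations", {
  set.seed(6)
  h <- data.table::data.table(maf = runif(103), beta = rnorm(103))
  s <- data.table::data.table(maf = runif(103), beta = rnorm(103))
  out <- maf_effect_analysis(h, s)
  z_expected <- (atanh(out$scc_h) - atanh(out$scc_s)) / sqrt(2 / 100)
  expect_equal(out$fisher_z, z_expected)
  # equal correlations give z = 0
  out2 <- maf_effect_analysis(h, h)
  expect_equal(out2$fisher_z, 0)
  expect_error(maf_effect_analysis(h[1:3], s), "more than 3")
  # the 0.5-vs-0.3 worked example
  z <- (atanh(0.5) - atanh(0.3)) / sqrt(1 / 100 + 1 / 100)
  expect_equal(z, 1.70, tolerance = 0.01)
})

test_that("functional enrichment is 0 for the SNP universe and log2-scaled otherwise", {
  all_snps <- sprintf("s%03d", 1:200)
  tracks <- data.table::data.table(
    snp_id = c(all_snps, all_snps[1:100]),
    class = rep(c("all", "half"), c(200, 100)))
  leads <- all_snps[1:20]   # all leads inside "half"
  out <- functional_enrichment(leads, all_snps, tracks, n_random = 200, seed = 1)
  expect_equal(out$log2_enrichment[out$class == "all"], 0)
  expect_equal(out$log2_enrichment[out$class == "half"], 1, tolerance = 0.15)
})

test_that("MTA overlap counts leads within the window and beats its null when planted", {
  leads <- data.table::data.table(chrom = "chr1A", pos = c(100500, 102000))
  mta <- data.table::data.table(chrom = "chr1A", pos = 100000)
  alls <- data.table::data.table(chrom = "chr1A", pos = seq(1e6, 2e6, by = 1e4))
  out <- mta_overlap(leads, mta, alls, window_bp = 1000, n_random = 50, seed = 1)
  expect_equal(out$observed, 1)   # 100500 within 1 kb; 102000 not
  # leads planted exactly at MTA positions dominate the null
  mta2 <- data.table::data.table(chrom = "chr1A", pos = seq(5e6, 6e6, by = 1e5))
  leads2 <- data.table::data.table(chrom = "chr1A", pos = mta2$pos)
  alls2 <- data.table::data.table(chrom = "chr1A", pos = seq(1e6, 9e6, by = 1e4))
  out2 <- mta_overlap(leads2, mta2, alls2, n_random = 100, seed = 2)
  expect_gt(out2$observed, max(out2$null_counts))
})

test_that("Hi-C contact enrichment finds planted elevated bins and not uniform ones", {
  genes <- gene_models(sprintf("g%02d", 1:20),
                       rep(c("chr1A", "chr2B"), each = 10),
                       seq(5e5, by = 1e6, length.out = 20)[1:20] %% 9.5e6 + 1,
                       seq(5e5, by = 1e6, length.out = 20)[1:20] %% 9.5e6 + 1000,
                       "+")
  pairs <- data.table::data.table(
    eqtl_chrom = "chr1A", eqtl_pos = c(1.5e6, 2.5e6, 3.5e6),
    gene_chrom = "chr2B", gene_pos = c(1.5e6, 2.5e6, 3.5e6))
  elev <- lapply(seq_len(nrow(pairs)), function(i)
    list(chromA = "chr1A", posA = pairs$eqtl_pos[i],
         chromB = "chr2B", posB = pairs$gene_pos[i], fold = 10))
  cm_hot <- simulate_contacts(genes, elevated = elev, baseline = 20, seed = 4)
  hot <- hic_contact_enrichment(pairs, cm_hot, genes, n_random = 100, seed = 5)
  expect_gt(hot$observed_mean, quantile(hot$null_means, 0.99))
  cm_flat <- simulate_contacts(genes, baseline = 20, seed = 4)
  flat <- suppressWarnings(
    hic_contact_enrichment(pairs, cm_flat, genes, n_random = 100, seed = 5))
  expect_lt(abs(flat$observed_mean - mean(flat$null_means)),
            2 * sd(flat$null_means) + 0.05)
})
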