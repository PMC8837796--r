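make_expr <- function(mat) {
  colnames(mat) <- paste0("a", seq_len(ncol(mat)))
  mat
}

test_that("compensation ratio arithmetic matches the group-mean definition", {
  # 4 lines with the A copy down, 4 with all three expressed
  a <- c(rep(0.01, 4), rep(5, 4))
  b <- d <- rep(5, 8)
  m <- make_expr(rbind(gA = a, gB = b, gD = d))
  t <- triplet_map("t1", "gA", "gB", "gD")
  out <- compensation_analysis(m, t, down_tpm = 0.1, expr_tpm = 2, min_lines = 2)
  expect_equal(out$ratios$ratio, (0.01 + 10) / 15, tolerance = 1e-6)
  # full compensation: partners absorb the loss
  m2 <- make_expr(rbind(gA = a, gB = c(rep(7.5, 4), rep(5, 4)),
                        gD = c(rep(7.5, 4), rep(5, 4))))
  out2 <- compensation_analysis(m2, t)
  expect_equal(out2$ratios$ratio, 15.01 / 15, tolerance = 1e-3)
  # ineligible triplet (never down) is excluded and counted
  m3 <- make_expr(rbind(gA = rep(5, 8), gB = rep(5, 8), gD = rep(5, 8)))
  out3 <- compensation_analysis(m3, t)
  expect_equal(nrow(out3$ratios), 0)
  expect_equal(out3$n_ineligible, 1)
})

test_that("biased-homoeolog rules flag the right genes and duplets separately", {
  pairs <- data.table::data.table(
    triplet_id = "t1",
    gene1 = c("gA", "gA", "gB"), gene2 = c("gB", "gD", "gD"),
    pair = c("AB", "AD", "BD"), scc = c(-0.5, -0.1, 0.3))
  t <- triplet_map("t1", "gA", "gB", "gD")
  fl <- detect_biased_homoeologs(pairs, t)
  expect_equal(fl$gene_id, "gA")
  # all positive: nothing flagged
  pairs2 <- data.table::copy(pairs)[, scc := c(0.5, 0.1, 0.3)]
  expect_equal(nrow(detect_biased_homoeologs(pairs2, t)), 0)
  # duplet: single-partner rule (2) only, reported with its set label
  td <- triplet_map("t2", "gX", "gY")
  pd <- data.table::data.table(triplet_id = "t2", gene1 = "gX", gene2 = "gY",
                               pair = "AB", scc = -0.45)
  fd <- detect_biased_homoeologs(pd, td)
  expect_setequal(fd$gene_id, c("gX", "gY"))
  expect_true(all(fd$set == "duplet"))
})

test_that("lowering the strong threshold never adds flagged genes", {
  sim <- small_cohort()
  prof <- homoeolog_scc_profile(sim$expression, sim$triplets,
                                n_random_pairs = 50, seed = 1)
  flagged <- lapply(c(-0.2, -0.4, -0.6), function(th)
    detect_biased_homoeologs(prof$pairs, sim$triplets, strong_thresh = th)$gene_id)
  expect_true(all(flagged[[2]] %in% flagged[[1]]))
  expect_true(all(flagged[[3]] %in% flagged[[2]]))
})

test_that("low-expressing calls require both the cap and the mean-sd rule", {
  m <- make_expr(rbind(g1 = c(0, 8, 9, 10),      # mean-sd ~ 2.18, only the 0 low
                       g2 = c(5, 5, 5, 5),       # constant: never low
                       g3 = c(2.5, 2.6, 2.4, 2.9)))  # all < 3 but not < mean-sd
  b <- count_low_expressing_alleles(m, c("g1", "g2", "g3"), tpm_cap = 3)
  expect_equal(as.numeric(b), c(1, 0, 0, 0))
  expect_equal(mean(c(0, 8, 9, 10)) - sd(c(0, 8, 9, 10)), 2.177, tolerance = 1e-3)
  # gene with all TPM >= 3 contributes nothing regardless of spread
  m2 <- make_expr(rbind(g1 = c(3, 50, 60, 70)))
  expect_equal(as.numeric(count_low_expressing_alleles(m2, "g1")),
               c(0, 0, 0, 0))
})

test_that("burden profiles are additive over disjoint gene sets", {
  sim <- small_cohort()
  m <- gene_tpm(sim$expression)
  genes <- rownames(m)
  s1 <- genes[1:20]; s2 <- genes[21:40]
  b1 <- count_low_expressing_alleles(m, s1)
  b2 <- count_low_expressing_alleles(m, s2)
  b12 <- count_low_expressing_alleles(m, c(s1, s2))
  expect_equal(as.numeric(b12), as.numeric(b1 + b2))
})

test_that("homoeolog SCC profile separates shared-trans triplets from random pairs", {
  sim <- simulate_cohort(sim_config(
    n_accessions = 150, n_triplets = 60, n_duplets = 0, n_singletons = 0,
    chroms_per_genome = 1, snps_per_chrom = 150, cis_prob = 0,
    trans_prob = 1, trans_share_prob = 0.8, trans_beta_sd = 0.8,
    silencing_prob = 0, n_hidden = 0, seed = 31))
  prof <- homoeolog_scc_profile(sim$expression, sim$triplets,
                                n_random_pairs = 500, seed = 2)
  w <- wilcox.test(prof$pairs$scc, prof$random_scc, alternative = "greater")
  expect_lt(w$p.value, 0.01)
  # identical expression vectors give SCC 1
  m <- make_expr(rbind(gA = 1:6, gB = 1:6, gD = 1:6))
  p1 <- homoeolog_scc_profile(m, triplet_map("t1", "gA", "gB", "gD"),
                              n_random_pairs = 0, seed = 1)
  expect_true(all(p1$pairs$scc == 1))
})

test_that("planted rare upstream down-alleles load onto the lowest expression ranks", {
  sim <- simulate_cohort(sim_config(
    n_accessions = 200, n_triplets = 100, n_duplets = 0, n_singletons = 0,
    chroms_per_genome = 1, snps_per_chrom = 400, snp_spacing_bp = 2000,
    ld_decay_bp = 0, structure_pools = NULL, cis_prob = 0, trans_prob = 0,
    silencing_prob = 0, n_hidden = 0, rare_down_prob = 1,
    rare_down_beta = -2, seed = 41))
  prof <- rare_allele_load_profile(sim$variants, sim$genes, sim$expression,
                                   n_bins = 5)
  expect_gt(prof$mean_load[1], prof$mean_load[3])
  # no rare SNPs at all: flat zero profile
  sim0 <- small_cohort()
  v0 <- sim0$variants
  prof0 <- rare_allele_load_profile(v0, sim0$genes, sim0$expression,
                                    maf_rare = 0, n_bins = 4)
  expect_true(all(prof0$mean_load == 0))
})

test_that("burden-trait correlation recovers a planted effect against the random-set null", {
  sim <- simulate_cohort(sim_config(
    n_accessions = 150, n_triplets = 150, n_duplets = 0, n_singletons = 0,
    chroms_per_genome = 1, snps_per_chrom = 100, silencing_prob = 0.3,
    n_hidden = 0,
    traits = list(yield = list(burden = -0.5, pleio_n = 0, pleio_sd = 0,
                               noise_sd = 1.5)),
    seed = 61))
  universe <- triplet_members(sim$triplets)$gene_id
  bt <- burden_trait_correlation(sim$expression, sim$truth$silencing$gene_id,
                                 sim$traits, universe, n_random_sets = 300,
                                 seed = 3)
  expect_lt(bt$scc[bt$trait == "yield"], 0)
  expect_gte(bt$percentile[bt$trait == "yield"], 99)
})

test_that("inter-locus LD profile is flat for random-vs-random comparisons", {
  sim <- small_cohort()
  mem <- triplet_members(sim$triplets)
  set.seed(8)
  mk_pairs <- function(n) data.table::data.table(
    gene1 = sample(mem$gene_id, n, replace = TRUE),
    gene2 = sample(mem$gene_id, n, replace = TRUE))
  eqtl <- data.table::data.table(
    transcript_id = mem$gene_id,
    class = "cis",
    lead_snp = sample(sim$variants$snps$snp_id, nrow(mem), replace = TRUE),
    lead_p = runif(nrow(mem), 1e-12, 1e-6))
  out <- interlocus_ld_profile(sim$variants, mk_pairs(30), eqtl, mk_pairs(30),
                               sim$genes, window_bp = 5e5)
  ok <- is.finite(out$ratio) & out$random$count >= 5
  if (any(ok)) expect_lt(max(abs(log(out$ratio[ok]))), log(3))
  # pair without an eQTL is skipped and reported
  eqtl2 <- eqtl[1:5]
  out2 <- interlocus_ld_profile(sim$variants,
                                data.table::data.table(gene1 = mem$gene_id[10],
                                                       gene2 = mem$gene_id[2]),
                                eqtl2, mk_pairs(2), sim$genes)
  expect_gte(out2$skipped, 1)
})
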