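test_that("GRM standardization arithmetic, duplication invariance and thinning", {
  d <- matrix(c(0, 2), 1, 2, dimnames = list("s1", c("a", "b")))
  v <- toy_variants(d, pos = 1L)
  K <- build_grm(v, thin_bp = NULL)$K
  expect_equal(unname(K), matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  # duplicating every SNP leaves the GRM unchanged
  sim <- small_cohort()
  g1 <- build_grm(sim$variants, thin_bp = NULL)
  ddup <- rbind(sim$variants$dosage, sim$variants$dosage)
  rownames(ddup) <- c(sim$variants$snps$snp_id,
                      paste0(sim$variants$snps$snp_id, "_dup"))
  vdup <- variant_table(ddup, rep(sim$variants$snps$chrom, 2),
                        rep(sim$variants$snps$pos, 2))
  g2 <- build_grm(vdup, thin_bp = NULL)
  expect_equal(g2$K, g1$K, tolerance = 1e-12)
  # thinning keeps the first SNP per non-overlapping 100-kb window
  d3 <- matrix(rep(c(0, 2, 0, 2), 3), 3, 4, byrow = TRUE,
               dimnames = list(c("x", "y", "z"), paste0("a", 1:4)))
  v3 <- toy_variants(d3, pos = c(10000L, 50000L, 150000L))
  g3 <- build_grm(v3, thin_bp = 1e5)
  expect_equal(g3$m, 2)   # SNPs at 10 kb and 150 kb retained
})

test_that("GRMs commute with accession reordering", {
  sim <- small_cohort()
  g1 <- build_grm(sim$variants)
  perm <- sample(colnames(sim$variants$dosage))
  g2 <- build_grm(subset_variants(sim$variants, accessions = perm))
  expect_equal(g2$K, g1$K[perm, perm], tolerance = 1e-12)
})

test_that("REML on independent noise attributes almost nothing to genetics", {
  sim <- small_cohort()
  g <- build_grm(sim$variants, thin_bp = NULL)
  set.seed(2)
  fr <- vapply(1:30, function(i) {
    y <- rnorm(60)
    reml_varcomp(y, g)$fractions[[1]]
  }, numeric(1))
  expect_lt(mean(fr), 0.08)
})

test_that("REML fractions are invariant to phenotype rescaling and die under permutation", {
  sim <- small_cohort()
  parts <- split(sim$variants$snps$snp_id, sim$variants$snps$genome)
  grms <- lapply(names(parts), function(g)
    build_grm(sim$variants, parts[[g]], thin_bp = NULL, label = g))
  y <- simulate_varcomp_phenotypes(sim$variants, parts, c(0.3, 0.2, 0.1),
                                   n_genes = 3, seed = 7)
  f1 <- reml_varcomp(y[1, ], grms)
  f2 <- reml_varcomp(5.7 * y[1, ], grms)
  expect_equal(f1$fractions, f2$fractions, tolerance = 1e-4)
  set.seed(11)
  fr_perm <- rowMeans(vapply(1:10, function(i) {
    reml_varcomp(sample(y[1, ]), grms)$fractions
  }, numeric(3)))
  # permutation breaks the genotype linkage: what remains is boundary
  # truncation noise, far below the planted signal
  expect_lt(sum(fr_perm), sum(f1$fractions) / 2)
  expect_lt(sum(fr_perm), 0.35)
})

test_that("Haseman-Elston cross-check agrees with REML on identifiable data", {
  sim <- simulate_cohort(sim_config(
    n_accessions = 150, n_triplets = 5, chroms_per_genome = 1,
    snps_per_chrom = 500, cis_prob = 0, trans_prob = 0, silencing_prob = 0,
    seed = 71))
  thin <- sim$variants$snps[, .SD[1],
                            by = .(chrom, win = (pos - 1) %/% 1e5)]
  parts <- split(thin$snp_id, thin$genome)
  y <- simulate_varcomp_phenotypes(sim$variants, parts,
                                   c(A = 0.35, B = 0.2, D = 0.1),
                                   n_genes = 30, seed = 3)
  grms <- lapply(names(parts), function(g)
    build_grm(sim$variants, parts[[g]], thin_bp = NULL, label = g))
  names(grms) <- names(parts)
  reml <- rowMeans(vapply(1:30, function(i)
    reml_varcomp(y[i, ], grms)$fractions, numeric(3)))
  he <- rowMeans(vapply(1:30, function(i)
    he_varcomp(y[i, ], grms), numeric(3)))
  expect_lt(max(abs(reml - he)), 0.12)
})

test_that("cis/trans-genic window rules are boundary-inclusive with an annulus", {
  sim <- simulate_cohort(sim_config(
    n_accessions = 60, n_triplets = 3, n_duplets = 0, n_singletons = 0,
    chroms_per_genome = 1, snps_per_chrom = 1200, snp_spacing_bp = 10000,
    cis_prob = 0, trans_prob = 0, silencing_prob = 0, seed = 81))
  g <- as.data.frame(sim$genes)[1, ]
  mid <- (g$start + g$end) / 2
  sn <- sim$variants$snps
  dist <- abs(sn$pos - mid)
  same <- sn$chrom == g$chrom
  r0 <- matrix(rnorm(60), 1, dimnames = list(g$gene_id,
                                             colnames(sim$variants$dosage)))
  res <- partition_cis_trans_genic(r0, sim$variants, sim$genes[1, ],
                                   cis_bp = 1e6, excl_bp = 5e6)
  expect_equal(res$n_cis_snps, sum(same & dist <= 1e6))
  # planted cis-only architecture: cis fraction dominates in most genes
  thin_ids <- sn[, .SD[1], by = .(chrom, win = (pos - 1) %/% 1e5)]$snp_id
  thin <- sn[snp_id %in% thin_ids]
  gm <- as.data.frame(sim$genes)
  y <- vapply(seq_len(nrow(gm)), function(i) {
    mid_i <- (gm$start[i] + gm$end[i]) / 2
    cis_ids <- thin[chrom == gm$chrom[i] & abs(pos - mid_i) <= 1e6, snp_id]
    simulate_varcomp_phenotypes(sim$variants, list(cis = cis_ids),
                                c(0.5), 1, seed = 100 + i)[1, ]
  }, numeric(60))
  ymat <- t(y)
  rownames(ymat) <- gm$gene_id
  res2 <- partition_cis_trans_genic(ymat, sim$variants, sim$genes)
  expect_gte(mean(res2$cis_frac > res2$trans_frac), 0.8)
})

test_that("genome partition labels own-genome variance cis-genomic and ranks by variance", {
  sim <- small_cohort()
  r <- remove_hidden_factors(normalize_expression(
    filter_transcripts(sim$expression)), k = 0)
  vars <- apply(r, 1, var)
  res <- partition_by_genome(r[1:10, ], sim$variants, sim$genes, top_n = 5,
                             thin_bp = NULL)
  expect_equal(nrow(res), 5)
  expect_setequal(res$gene_id,
                  names(sort(vars[1:10], decreasing = TRUE))[1:5])
  own <- vapply(seq_len(nrow(res)), function(i)
    res[[paste0("frac_", res$genome[i])]][i], numeric(1))
  expect_equal(res$cis_genomic, own)
})

test_that("regulatory-architecture classes follow the fraction thresholds", {
  res <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4"),
    cis_frac = c(0.005, 0.30, 0.15, 0.10),
    trans_frac = c(0.40, 0.005, 0.15, 0.02))
  cl <- classify_regulatory_architecture(res, total_min = 0.20, cis_max = 0.01)
  expect_equal(cl$architecture, c("trans-only", "cis-driven", "mixed",
                                  "unexplained"))
})
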