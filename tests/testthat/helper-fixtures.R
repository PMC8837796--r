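# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small default-architecture cohort for plumbing tests
small_cohort <- function() cached("small", simulate_cohort(sim_config(
  n_accessions = 60, n_triplets = 30, n_duplets = 4, n_singletons = 4,
  chroms_per_genome = 1, snps_per_chrom = 150, seed = 101)))

# a tiny variant table built by hand
toy_variants <- function(dosage, chrom = NULL, pos = NULL) {
  n <- nrow(dosage)
  if (is.null(chrom)) chrom <- rep("chr1A", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("s", seq_len(n))
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("a", seq_len(ncol(dosage)))
  variant_table(dosage, chrom, pos)
}

# textbook OLS oracle: per-pair lm fit with covariates
ols_oracle <- function(y, g, covs = NULL) {
  df <- data.frame(y = y, g = g)
  fit <- if (is.null(covs)) lm(y ~ g, data = df)
         else lm(y ~ g + covs)
  s <- summary(fit)$coefficients["g", ]
  list(beta = unname(s["Estimate"]), t = unname(s["t value"]),
       p = unname(s["Pr(>|t|)"]))
}

# exhaustive connected-components clustering oracle for the LD merge
merge_oracle <- function(pos, p, dosage, r2_min, gap_bp) {
  m <- length(pos)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    r2 <- ld_r2(dosage[i, ], dosage[j, ])
    adj[i, j] <- !is.na(r2) && r2 > r2_min && abs(pos[i] - pos[j]) < gap_bp
  }
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# profile-REML grid-search oracle over the heritability fraction
grid_reml_oracle <- function(y, K, h2s = seq(0, 1, by = 0.01)) {
  n <- length(y)
  ll <- vapply(h2s, function(h2) {
    V0 <- h2 * K + (1 - h2) * diag(n)
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vi <- chol2inv(ch)
    v1 <- rowSums(Vi); xvx <- sum(v1)
    P <- Vi - tcrossprod(v1) / xvx
    yPy <- sum(y * (P %*% y))
    s2 <- yPy / (n - 1)
    -0.5 * ((n - 1) * log(s2) + 2 * sum(log(diag(ch))) + log(xvx) + (n - 1))
  }, numeric(1))
  h2s[which.max(ll)]
}

# brute-force modularity maximum over all partitions of <= 6 nodes
best_modularity_oracle <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 6)
  parts <- list(integer(0))
  # enumerate set partitions via restricted growth strings
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    mx <- if (length(prefix)) max(prefix) else 0
    out <- list()
    for (v in seq_len(mx + 1)) out <- c(out, grow(c(prefix, v)))
    out
  }
  max(vapply(grow(integer(0)), function(memb)
    igraph::modularity(g, memb), numeric(1)))
}
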