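# Genetic relationship matrices and multi-component REML partitioning of
# per-gene expression variance onto named SNP sets (subgenomes, or
# cis-genic vs trans-genic windows).

#' Standardize a dosage matrix per SNP
#'
#' Centers each SNP to mean zero and scales to unit sample variance;
#' missing dosages are set to the SNP mean (0 after centering).
#' Monomorphic SNPs are dropped.
#'
#' @param d Dosage matrix, SNP x accession.
#' @return Standardized matrix (possibly fewer rows).
#' @export
standardize_dosage <- function(d) {
  mu <- rowMeans(d, na.rm = TRUE)
  z <- d - mu
  z[is.na(z)] <- 0
  s <- sqrt(rowSums(z^2) / (ncol(d) - 1))
  keep <- s > 0
  z[keep, , drop = FALSE] / s[keep]
}

#' Build a genetic relationship matrix
#'
#' GRM = Z Z' / m over standardized dosages ([standardize_dosage]). To
#' remove SNP-density confounding, SNPs are first thinned to one per
#' non-overlapping `thin_bp` window (the first SNP by position in each
#' window is kept).
#'
#' @param v A [variant_table].
#' @param snps Optional snp_id subset.
#' @param thin_bp Thinning window in bp; NULL disables thinning.
#' @param label Partition label carried in the result.
#' @return list(K, m, label) of class `grm`; `K` is accession x accession.
#' @export
build_grm <- function(v, snps = NULL, thin_bp = 1e5, label = "all") {
  stopifnot(is_variant_table(v))
  idx <- if (is.null(snps)) seq_len(nrow(v$dosage))
         else match(snps, v$snps$snp_id)
  if (anyNA(idx)) stop("unknown snp_id in GRM subset")
  if (!is.null(thin_bp)) idx <- thin_snps(v$snps[idx], thin_bp, idx)
  z <- standardize_dosage(v$dosage[idx, , drop = FALSE])
  if (!nrow(z)) stop("no polymorphic SNPs after thinning")
  structure(list(K = crossprod(z) / nrow(z), m = nrow(z), label = label),
            class = "grm")
}

# keep the first SNP (smallest pos) per non-overlapping window per chromosome
thin_snps <- function(snp_dt, thin_bp, orig_idx) {
  o <- order(snp_dt$chrom, snp_dt$pos)
  dt <- data.table(chrom = snp_dt$chrom[o], pos = snp_dt$pos[o],
                   idx = orig_idx[o])
  dt[, win := (pos - 1L) %/% thin_bp]
  dt[, .SD[1], by = .(chrom, win)]$idx
}

#' Multi-component REML estimation of variance fractions
#'
#' Fits y = sum_c u_c + e with Var(y) = sum_c sigma2_c G_c + sigma2_e I by
#' average-information REML with EM fallback steps; components are kept
#' non-negative by projection to a small positive floor. Convergence is a
#' restricted log-likelihood change below `tol`.
#'
#' @param y Numeric phenotype vector (one gene's residual expression).
#' @param grms List of `grm` objects or plain accession x accession
#'   matrices; names become component labels.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum iterations.
#' @return list(components, residual, fractions, converged, loglik,
#'   iterations) of class `varcomp`. On a singular variance structure the
#'   result is flagged non-converged (no exception).
#' @export
reml_varcomp <- function(y, grms, tol = 1e-8, max_iter = 200) {
  if (inherits(grms, "grm")) grms <- list(grms)
  Ks <- lapply(grms, function(g) if (inherits(g, "grm")) g$K else g)
  labs <- names(Ks)
  if (is.null(labs) || any(labs == ""))
    labs <- vapply(seq_along(grms), function(i) {
      g <- grms[[i]]
      if (inherits(g, "grm") && !is.null(g$label)) g$label
      else paste0("g", i)
    }, character(1))
  k <- length(Ks)
  stopifnot(k >= 1, k <= 4)
  n <- length(y)
  if (n < 30) stop("need at least 30 observations")
  vy <- var(y)
  fail <- function() structure(list(
    components = setNames(rep(NA_real_, k), labs), residual = NA_real_,
    fractions = setNames(rep(NA_real_, k), labs), converged = FALSE,
    loglik = NA_real_, iterations = 0L), class = "varcomp")
  if (!is.finite(vy) || vy <= 0) return(fail())

  Vlist <- c(Ks, list(diag(n)))
  theta <- rep(vy / (k + 1), k + 1)
  floor_v <- 1e-8 * vy
  ll_old <- -Inf
  converged <- FALSE
  ll <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    V <- matrix(0, n, n)
    for (i in seq_len(k + 1)) V <- V + theta[i] * Vlist[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(chol(V + diag(1e-6 * vy, n)), error = function(e) NULL)
      if (is.null(ch)) return(fail())
    }
    Vinv <- chol2inv(ch)
    v1 <- rowSums(Vinv)                       # Vinv %*% 1  (X = intercept)
    xvx <- sum(v1)
    P <- Vinv - tcrossprod(v1) / xvx
    Py <- as.vector(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + log(xvx) + sum(y * Py))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    Qs <- lapply(seq_len(k + 1), function(i)
      if (i <= k) as.vector(Vlist[[i]] %*% Py) else Py)
    score <- vapply(seq_len(k + 1), function(i)
      -0.5 * (sum(P * Vlist[[i]]) - sum(Py * Qs[[i]])), numeric(1))
    em_step <- function() {
      vapply(seq_len(k + 1), function(i) {
        theta[i] + theta[i]^2 *
          (sum(Py * Qs[[i]]) - sum(P * Vlist[[i]])) / n
      }, numeric(1))
    }
    cand <- NULL
    # active set: components pinned at the floor whose score pushes them
    # further down are held fixed this iteration
    active <- !(theta <= floor_v * 1.01 & score < 0)
    if (!any(active)) active[k + 1] <- TRUE
    if (iter > 1) {
      AI <- matrix(0, k + 1, k + 1)
      PQ <- lapply(Qs, function(q) as.vector(P %*% q))
      for (i in seq_len(k + 1)) for (j in i:(k + 1)) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(Qs[[i]] * PQ[[j]])
      }
      delta_a <- tryCatch(solve(AI[active, active, drop = FALSE],
                                score[active]), error = function(e) NULL)
      if (!is.null(delta_a) && all(is.finite(delta_a))) {
        delta <- rep(0, k + 1)
        delta[active] <- delta_a
        # step-halve an infeasible AI proposal, then project stragglers
        # onto the boundary; plain EM crawls on near-collinear GRMs
        step <- 1
        for (h in 1:6) {
          cand <- theta + step * delta
          if (all(cand >= 0)) break
          step <- step / 2
        }
        if (any(cand < 0)) cand[cand < 0] <- floor_v
      }
    }
    if (is.null(cand) || any(!is.finite(cand))) {
      cand <- em_step()
      cand[!active] <- theta[!active]
    }
    theta <- pmax(cand, floor_v)
  }
  comp <- setNames(theta[seq_len(k)], labs)
  total <- sum(theta)
  structure(list(components = comp, residual = theta[k + 1],
                 fractions = comp / total, converged = converged,
                 loglik = ll, iterations = iter),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("<varcomp> fractions:",
      paste(sprintf("%s=%.3f", names(x$fractions), x$fractions),
            collapse = " "),
      sprintf(" residual=%.3g converged=%s\n", x$residual, x$converged))
  invisible(x)
}

#' Haseman-Elston regression variance components
#'
#' Moment-based cross-check for [reml_varcomp]: regresses off-diagonal
#' products of the centered phenotype on the corresponding GRM entries.
#'
#' @inheritParams reml_varcomp
#' @return Named vector of variance-fraction estimates (can fall outside
#'   \[0,1\]; this estimator is unconstrained).
#' @export
he_varcomp <- function(y, grms) {
  if (inherits(grms, "grm")) grms <- list(grms)
  Ks <- lapply(grms, function(g) if (inherits(g, "grm")) g$K else g)
  n <- length(y)
  yc <- scale(y)[, 1]
  up <- upper.tri(Ks[[1]])
  yy <- tcrossprod(yc)[up]
  X <- vapply(Ks, function(K) K[up], numeric(sum(up)))
  setNames(coef(lm(yy ~ X))[-1], names(grms) %||% paste0("g", seq_along(Ks)))
}

#' Partition expression variance onto subgenome SNP sets
#'
#' For each gene, fits a joint three-component REML model with the A, B
#' and D genome GRMs (thinned to one SNP per `thin_bp`); the fraction on
#' the gene's own subgenome is reported as cis-genomic, the sum of the
#' other two as trans-genomic. Genes are ranked by expression variance
#' and only the `top_n` most variable are fitted.
#'
#' @param resid Residual expression matrix (gene x accession).
#' @param v A [variant_table] with genome labels.
#' @param genes A [gene_models] table covering the residual rows.
#' @param top_n Number of most-variable genes to fit.
#' @param thin_bp GRM thinning window.
#' @return data.table: gene_id, genome, per-genome fractions, cis_genomic,
#'   trans_genomic, residual fraction, converged, loglik.
#' @export
partition_by_genome <- function(resid, v, genes, top_n = 10000,
                                thin_bp = 1e5) {
  stopifnot(is_variant_table(v))
  genomes <- c("A", "B", "D")
  grms <- lapply(genomes, function(g) {
    ids <- v$snps[genome == g, snp_id]
    if (!length(ids)) return(NULL)
    build_grm(v, ids, thin_bp = thin_bp, label = g)
  })
  names(grms) <- genomes
  grms <- grms[!vapply(grms, is.null, logical(1))]
  gtab <- as.data.table(genes)
  vars <- apply(resid, 1, var)
  fit_ids <- names(sort(vars, decreasing = TRUE))[seq_len(min(top_n, nrow(resid)))]
  rbindlist(lapply(fit_ids, function(g) {
    fit <- reml_varcomp(resid[g, ], grms)
    own <- gtab[gene_id == g, genome]
    fr <- fit$fractions
    data.table(gene_id = g,
               genome = if (length(own)) own else NA_character_,
               frac_A = fr[["A"]], frac_B = fr[["B"]], frac_D = fr[["D"]],
               cis_genomic = if (length(own) && own %in% names(fr))
                 fr[[own]] else NA_real_,
               trans_genomic = if (length(own) && own %in% names(fr))
                 sum(fr[setdiff(names(fr), own)]) else NA_real_,
               residual_frac = fit$residual / (sum(fit$components) + fit$residual),
               converged = fit$converged, loglik = fit$loglik)
  }))
}

#' Partition expression variance into cis-genic and trans-genic SNPs
#'
#' Per gene, two GRMs: cis-genic SNPs within +/-`cis_bp` of the gene
#' midpoint, and trans-genic SNPs beyond +/-`excl_bp` on the gene's
#' chromosome plus all other chromosomes; SNPs in the annulus between the
#' two windows are excluded. Boundaries are inclusive for the cis window.
#'
#' @inheritParams partition_by_genome
#' @param cis_bp Half-width of the cis-genic window.
#' @param excl_bp Half-width of the exclusion window for trans-genic SNPs.
#' @param thin_bp GRM thinning window (NULL disables).
#' @return data.table: gene_id, cis_frac, trans_frac, residual fraction,
#'   n_cis_snps, converged, loglik. Genes with an empty cis set get a
#'   single-component fit with cis_frac 0.
#' @export
partition_cis_trans_genic <- function(resid, v, genes, cis_bp = 1e6,
                                      excl_bp = 5e6, thin_bp = NULL) {
  stopifnot(is_variant_table(v))
  idx_all <- if (is.null(thin_bp)) seq_len(nrow(v$dosage))
             else thin_snps(v$snps, thin_bp, seq_len(nrow(v$dosage)))
  z <- standardize_dosage(v$dosage[idx_all, , drop = FALSE])
  sn <- v$snps[match(rownames(z), v$snps$snp_id)]
  S_tot <- crossprod(z)
  m_tot <- nrow(z)
  gtab <- as.data.table(genes)[gene_id %in% rownames(resid)]
  rbindlist(lapply(seq_len(nrow(gtab)), function(i) {
    g <- gtab[i]
    mid <- (g$start + g$end) / 2
    same <- sn$chrom == g$chrom
    d <- abs(sn$pos - mid)
    cis_i <- which(same & d <= cis_bp)
    excl_i <- which(same & d <= excl_bp)   # cis + annulus
    y <- resid[g$gene_id, ]
    if (length(cis_i)) {
      zc <- z[cis_i, , drop = FALSE]
      K_cis <- crossprod(zc) / length(cis_i)
      ze <- z[setdiff(excl_i, cis_i), , drop = FALSE]
      m_tr <- m_tot - length(excl_i)
      K_tr <- (S_tot - crossprod(zc) -
               (if (nrow(ze)) crossprod(ze) else 0)) / m_tr
      fit <- reml_varcomp(y, list(cis = K_cis, trans = K_tr))
      cis_frac <- fit$fractions[["cis"]]; trans_frac <- fit$fractions[["trans"]]
    } else {
      ze <- z[excl_i, , drop = FALSE]
      m_tr <- m_tot - length(excl_i)
      K_tr <- (S_tot - (if (nrow(ze)) crossprod(ze) else 0)) / m_tr
      fit <- reml_varcomp(y, list(trans = K_tr))
      cis_frac <- 0; trans_frac <- fit$fractions[["trans"]]
    }
    data.table(gene_id = g$gene_id, cis_frac = cis_frac,
               trans_frac = trans_frac,
               residual_frac = fit$residual /
                 (sum(fit$components) + fit$residual),
               n_cis_snps = length(cis_i), converged = fit$converged,
               loglik = fit$loglik)
  }))
}

#' Classify genes by regulatory architecture
#'
#' @param results data.table with `cis_frac` and `trans_frac` columns
#'   (from [partition_cis_trans_genic] or the genome partition with
#'   cis_genomic/trans_genomic renamed).
#' @param total_min Minimum total explained fraction; below it a gene is
#'   "unexplained".
#' @param cis_max Fraction under which a component counts as absent.
#' @return Input with an added `architecture` column in
#'   \{cis-driven, trans-only, mixed, unexplained\}.
#' @export
classify_regulatory_architecture <- function(results, total_min = 0.20,
                                             cis_max = 0.01) {
  r <- as.data.table(results)
  total <- r$cis_frac + r$trans_frac
  r$architecture <- fifelse(total < total_min, "unexplained",
    fifelse(r$cis_frac < cis_max, "trans-only",
      fifelse(r$trans_frac < cis_max, "cis-driven", "mixed")))
  r[]
}
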