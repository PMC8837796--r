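# eQTL-derived regulatory-network construction with module detection, and
# ridge-regression trait prediction with nested cross-validation and
# random-gene-set nulls.

#' Build a co-expression / regulatory network around seed genes
#'
#' Undirected co-expression edges connect each seed gene to every gene
#' whose residual-expression |SCC| exceeds `scc_min` (and included genes
#' to each other). Directed regulation edges are added for every
#' (cis-eGene, trans-eGene) pair sharing a significant SNP, signed by the
#' SCC of their residuals, when |SCC| > `scc_min`.
#'
#' @param seed_genes Character vector of seed genes (e.g. SMR candidates).
#' @param resid Residual expression matrix (gene x accession).
#' @param assoc Classified significant associations: data.table with
#'   columns `gene` (or `transcript_id`), `snp_id`, `class` in
#'   \{cis, trans, other\}.
#' @param scc_min Absolute SCC threshold for an edge.
#' @return list(graph, edges, regulation, n_positive, n_negative):
#'   `graph` an igraph object with undirected weighted edges; `regulation`
#'   a data.table (regulator, target, snp_id, scc, sign).
#' @export
build_network <- function(seed_genes, resid, assoc = NULL, scc_min = 0.6) {
  resid <- unclass(resid)
  stopifnot(all(seed_genes %in% rownames(resid)))
  rk <- t(apply(resid, 1, rank))
  cors <- cor(t(rk[seed_genes, , drop = FALSE]), t(rk))  # seed x all genes
  edges <- as.data.table(as.table(cors))
  setnames(edges, c("gene1", "gene2", "scc"))
  edges <- edges[gene1 != gene2 & abs(scc) > scc_min]
  nodes <- union(seed_genes, edges$gene2)
  # edges among all included genes, deduplicated
  full <- cor(t(rk[nodes, , drop = FALSE]))
  idx <- which(upper.tri(full) & abs(full) > scc_min, arr.ind = TRUE)
  edge_dt <- data.table(gene1 = nodes[idx[, 1]], gene2 = nodes[idx[, 2]],
                        scc = full[idx])
  g <- igraph::graph_from_data_frame(
    edge_dt[, .(gene1, gene2, weight = abs(scc))], directed = FALSE,
    vertices = data.frame(name = nodes))
  regulation <- data.table(regulator = character(), target = character(),
                           snp_id = character(), scc = numeric(),
                           sign = character())
  if (!is.null(assoc) && nrow(assoc)) {
    a <- as.data.table(assoc)
    if (!"gene" %in% names(a)) a[, gene := transcript_id]
    reg <- merge(a[class == "cis", .(snp_id, regulator = gene)],
                 a[class == "trans", .(snp_id, target = gene)],
                 by = "snp_id", allow.cartesian = TRUE)
    reg <- unique(reg[regulator != target &
                      regulator %in% rownames(resid) &
                      target %in% rownames(resid)])
    if (nrow(reg)) {
      reg[, scc := vapply(seq_len(.N), function(i)
        suppressWarnings(spearman_scc(resid[regulator[i], ],
                                      resid[target[i], ])), numeric(1))]
      reg <- reg[!is.na(scc) & abs(scc) > scc_min]
      reg[, sign := fifelse(scc > 0, "positive", "negative")]
      regulation <- reg[, .(regulator, target, snp_id, scc, sign)]
    }
  }
  list(graph = g, edges = edge_dt, regulation = regulation,
       n_positive = sum(regulation$sign == "positive"),
       n_negative = sum(regulation$sign == "negative"))
}

#' Detect network modules by greedy modularity maximization
#'
#' @param g An igraph object (undirected projection is used) or the list
#'   returned by [build_network].
#' @param method "greedy" (deterministic fast-greedy modularity, followed
#'   by a deterministic single-node local-moving refinement) or "louvain".
#' @return list(membership, modularity): named module id per node. An
#'   edgeless graph puts each node in its own module (modularity 0).
#' @export
detect_modules <- function(g, method = c("greedy", "louvain")) {
  method <- match.arg(method)
  if (is.list(g) && !igraph::is_igraph(g)) g <- g$graph
  if (igraph::ecount(g) == 0) {
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- igraph::V(g)$name
    return(list(membership = memb, modularity = 0))
  }
  gs <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  cl <- if (method == "greedy") igraph::cluster_fast_greedy(gs)
        else igraph::cluster_louvain(gs)
  memb <- as.vector(igraph::membership(cl))
  if (method == "greedy") memb <- refine_membership(gs, memb)
  names(memb) <- igraph::V(gs)$name
  list(membership = memb,
       modularity = igraph::modularity(gs, memb))
}

# deterministic local-moving refinement: repeatedly move single nodes to
# the adjacent (or fresh) module that most improves modularity
refine_membership <- function(gs, memb) {
  n <- igraph::vcount(gs)
  repeat {
    improved <- FALSE
    q0 <- igraph::modularity(gs, memb)
    for (v in seq_len(n)) {
      nb <- igraph::neighbors(gs, v)
      cands <- unique(c(memb[as.integer(nb)], max(memb) + 1L))
      cands <- setdiff(cands, memb[v])
      for (cc in cands) {
        trial <- memb
        trial[v] <- cc
        q1 <- igraph::modularity(gs, trial)
        if (q1 > q0 + 1e-12) {
          memb <- trial
          q0 <- q1
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  match(memb, unique(memb))   # renumber compactly
}

#' Ridge-regression trait prediction with nested cross-validation
#'
#' Outer k-fold split; within each outer training set the ridge penalty
#' is chosen by inner cross-validation (glmnet, alpha = 0) over a
#' log-spaced lambda grid on predictors centered and standardized within
#' the training folds; predictions are concatenated over outer folds and
#' scored by SCC against the observed trait. The intercept is fixed at
#' the cohort trait mean rather than refit per training fold: refitting
#' it makes every held-out prediction anti-correlate with the held-out
#' observations (the fold-mean artifact), biasing the null accuracy
#' negative; with a fixed intercept folds differ only through gene
#' effects and an uninformative gene set scores near zero.
#'
#' @param expr Accession x gene matrix of TPM expression for the gene set.
#' @param y Named numeric trait vector keyed by accession (NAs dropped).
#' @param k_outer Outer folds.
#' @param n_lambda Lambda grid size (log-spaced over 1e-3..1e3).
#' @param inner_k Inner CV folds.
#' @param seed RNG seed for fold assignment.
#' @return list(scc_pred, predictions, observed, folds); scc_pred is NA
#'   for a constant trait.
#' @export
ridge_predict_traits <- function(expr, y, k_outer = 10, n_lambda = 50,
                                 inner_k = 5, seed = 1) {
  acc <- intersect(rownames(expr), names(y)[!is.na(y)])
  if (length(acc) < 30) stop("need at least 30 accessions")
  X <- as.matrix(expr[acc, , drop = FALSE])
  yy <- y[acc]
  if (sd(yy) == 0) return(list(scc_pred = NA_real_, predictions = NULL,
                               observed = yy, folds = NULL))
  set.seed(seed)
  folds <- sample(rep(seq_len(k_outer), length.out = length(acc)))
  lambda <- 10^seq(3, -3, length.out = n_lambda)
  yc <- yy - mean(yy)
  pred <- rep(NA_real_, length(acc))
  for (f in seq_len(k_outer)) {
    tr <- folds != f
    mu <- colMeans(X[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, mu)
    Xte <- sweep(X[!tr, , drop = FALSE], 2, mu)
    cv <- glmnet::cv.glmnet(Xtr, yc[tr], alpha = 0, lambda = lambda,
                            nfolds = inner_k, standardize = TRUE,
                            intercept = FALSE)
    pred[!tr] <- mean(yy) + as.vector(stats::predict(cv, Xte,
                                                     s = "lambda.min"))
  }
  names(pred) <- acc
  list(scc_pred = suppressWarnings(spearman_scc(pred, yy)),
       predictions = pred, observed = yy, folds = setNames(folds, acc))
}

#' Random-gene-set null for ridge prediction accuracy
#'
#' Repeats [ridge_predict_traits] on random gene sets of the stated size
#' drawn from a gene universe, returning the null SCC distribution and
#' the percentile of an observed SCC within it.
#'
#' @param expr_universe Accession x gene matrix spanning the universe.
#' @param set_size Genes per random set.
#' @param y Named trait vector.
#' @param observed_scc SCC to place in the null (optional).
#' @param n_reps Number of random sets.
#' @param seed RNG seed.
#' @param ... Passed to [ridge_predict_traits].
#' @return list(null_scc, percentile).
#' @export
random_geneset_null <- function(expr_universe, set_size, y,
                                observed_scc = NULL, n_reps = 100,
                                seed = 1, ...) {
  stopifnot(ncol(expr_universe) > set_size)
  set.seed(seed)
  sets <- replicate(n_reps, sample(colnames(expr_universe), set_size),
                    simplify = FALSE)
  null_scc <- vapply(seq_along(sets), function(i)
    ridge_predict_traits(expr_universe[, sets[[i]], drop = FALSE], y,
                         seed = seed + i, ...)$scc_pred, numeric(1))
  list(null_scc = null_scc,
       percentile = if (is.null(observed_scc)) NA_real_ else
         mean(observed_scc > null_scc, na.rm = TRUE) * 100)
}
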