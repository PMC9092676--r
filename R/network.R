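#' Build a gene network object from an edge list
#'
#' Symmetrizes and deduplicates the edge list (keeping the first weight seen
#' for a duplicated pair), drops self-loops, and returns the node set and a
#' symmetric weighted adjacency matrix.
#'
#' @param edges data.frame with gene_a, gene_b, weight (positive).
#' @param nodes optional full node set (genes without edges become isolated
#'   nodes).
#' @return list of class `gene_network` with `nodes` and `adjacency`.
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (nrow(edges) > 0 && any(edges$weight <= 0))
    stop("gene_network: edge weights must be positive", call. = FALSE)
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]; w <- edges$weight[keep]
  nodes <- sort(unique(c(nodes, a, b)))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ia <- match(a, nodes); ib <- match(b, nodes)
  A[cbind(ia, ib)] <- w
  A[cbind(ib, ia)] <- w
  structure(list(nodes = nodes, adjacency = A), class = "gene_network")
}

#' Column-normalized transition operator of a gene network
#'
#' Divides each column of the weighted adjacency by its sum so the result is
#' column-stochastic; isolated nodes receive a self-transition of 1.
#'
#' @param network a `gene_network` (or an edge-list data.frame, converted).
#' @return column-stochastic matrix with node dimnames.
#' @export
column_normalize <- function(network) {
  if (is.data.frame(network)) network <- gene_network(network)
  A <- network$adjacency
  cs <- colSums(A)
  iso <- cs == 0
  if (any(iso)) {
    diag(A)[iso] <- 1
    cs[iso] <- 1
  }
  sweep(A, 2, cs, "/")
}

#' Random walk with restart over a gene network
#'
#' Solves s = r * e + (1 - r) * W %*% s, where e is uniform over the seed
#' genes and W is the column-stochastic transition operator, by power
#' iteration to an L1 tolerance of 1e-10. The solution is a probability
#' vector over all nodes measuring network proximity to the seed set.
#'
#' @param transition column-stochastic matrix from [column_normalize()].
#' @param seed_genes character vector of seed genes; seeds absent from the
#'   network are dropped with a warning, and if none remain the restart
#'   vector falls back to uniform over all nodes (with a warning).
#' @param restart_prob restart probability r in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return list of class `rwr_result` with `scores` (named probability
#'   vector summing to 1) and `restart_prob`.
#' @export
rwr <- function(transition, seed_genes, restart_prob = 0.5,
                tol = 1e-10, max_iter = 10000L) {
  if (restart_prob <= 0 || restart_prob > 1)
    stop("rwr: restart_prob must lie in (0, 1]", call. = FALSE)
  nodes <- rownames(transition)
  seeds <- unique(seed_genes)
  absent <- setdiff(seeds, nodes)
  if (length(absent)) {
    warning("rwr: dropping seed(s) absent from network: ",
            paste(absent, collapse = ", "), call. = FALSE)
    seeds <- setdiff(seeds, absent)
  }
  e <- numeric(nrow(transition))
  if (length(seeds) == 0L) {
    warning("rwr: no seeds in network; using uniform restart", call. = FALSE)
    e[] <- 1 / length(e)
  } else {
    e[match(seeds, nodes)] <- 1 / length(seeds)
  }
  s <- e
  for (i in seq_len(max_iter)) {
    s_new <- restart_prob * e + (1 - restart_prob) * drop(transition %*% s)
    if (sum(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  names(s) <- nodes
  structure(list(scores = s, restart_prob = restart_prob),
            class = "rwr_result")
}

#' Closed-form random-walk-with-restart kernel
#'
#' Precomputes K = r * (I - (1 - r) W)^{-1}; for any restart vector e the
#' stationary RWR scores are K %*% e, so scores for a uniform seed set are a
#' column average of K. The Gibbs prioritizer uses this to make each
#' conditional update a cheap column-subset mean.
#'
#' @param transition column-stochastic matrix.
#' @param restart_prob restart probability in (0, 1].
#' @return dense kernel matrix with node dimnames.
#' @export
rwr_kernel <- function(transition, restart_prob = 0.5) {
  if (restart_prob <= 0 || restart_prob > 1)
    stop("rwr_kernel: restart_prob must lie in (0, 1]", call. = FALSE)
  n <- nrow(transition)
  K <- restart_prob * solve(diag(n) - (1 - restart_prob) * transition)
  dimnames(K) <- dimnames(transition)
  K
}

#' Locus-level prior from RWR scores
#'
#' Normalizes epsilon-floored RWR scores within a candidate set:
#' prior(g) = (score(g) + eps) / sum over the locus. Candidates missing from
#' the network contribute score 0 and still receive a strictly positive
#' prior when eps > 0.
#'
#' @param rwr_result an `rwr_result` (or bare named score vector).
#' @param candidate_genes candidate gene ids at the locus.
#' @param epsilon floor added to every score; default 1e-6 / number of
#'   network nodes.
#' @return named probability vector over `candidate_genes`, summing to 1.
#' @export
locus_prior <- function(rwr_result, candidate_genes, epsilon = NULL) {
  if (length(candidate_genes) == 0L)
    stop("locus_prior: empty candidate set", call. = FALSE)
  scores <- if (inherits(rwr_result, "rwr_result")) rwr_result$scores
            else rwr_result
  if (is.null(epsilon)) epsilon <- 1e-6 / length(scores)
  s <- scores[candidate_genes]
  s[is.na(s)] <- 0
  names(s) <- candidate_genes
  pr <- s + epsilon
  pr / sum(pr)
}
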