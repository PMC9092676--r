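# Small in-code fixtures shared across test files.

# A two-locus toy problem: loci are far apart, each with a handful of
# candidates, a small connected network, and hand-set log evidence.
toy_instance <- function(log_bf = NULL, edges = NULL) {
  candidates <- data.frame(
    locus_id = rep(c("locus_1", "locus_2"), c(3, 2)),
    snp_id = rep(c("rs001", "rs002"), c(3, 2)),
    gene_id = c("A", "B", "C", "D", "E"),
    tss_distance = c(1e4, 5e4, 9e5, 2e4, 3e5),
    is_closest = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  if (is.null(log_bf)) log_bf <- c(A = 2, B = 1, C = 0.5, D = 1.5, E = 1)
  evidence <- data.frame(gene_id = names(log_bf), log_bf = unname(log_bf),
                         stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(gene_a = c("A", "B", "A"),
                        gene_b = c("D", "E", "B"),
                        weight = c(1, 1, 0.5), stringsAsFactors = FALSE)
  list(candidates = candidates, evidence = evidence, network = edges)
}

# Random weighted undirected graph as an edge list over given node names.
random_edges <- function(nodes, p = 0.3) {
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
             weight = stats::runif(sum(keep), 0.2, 1),
             stringsAsFactors = FALSE)
}

# Independent step-up BH oracle (kept free of stats::p.adjust on purpose).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Hypergeometric upper-tail oracle by direct summation of dhyper mass.
hyper_tail_oracle <- function(overlap, panel, background, query) {
  sum(stats::dhyper(overlap:min(panel, query), panel,
                    background - panel, query))
}

# small simulation config used when full study-scale is not needed
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 2, n_genes = 150, n_loci = 4,
         candidates_per_locus_target = 10, n_cell_types = 3,
         n_cells_per_type = 40, markers_per_type = 8),
    list(...))
  do.call(sim_config, args)
}
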