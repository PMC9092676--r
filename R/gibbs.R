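# Internal sampling engine shared by the Gibbs sampler and the exact
# stationary oracle, so both evaluate the identical locus conditional:
#   P(g | others) ∝ (rwr_score(g | seeds) + eps) * exp(log_bf(g))
# with seeds = genes currently selected at all OTHER loci (set semantics).
.gibbs_engine <- function(candidates, evidence, network, restart_prob,
                          prior_epsilon) {
  loci <- unique(candidates$locus_id)
  ev_lb <- stats::setNames(evidence$log_bf, evidence$gene_id)
  cand <- split(candidates$gene_id, candidates$locus_id)[loci]
  cand <- lapply(cand, function(g) sort(unique(g)))
  logbf <- lapply(cand, function(g) {
    lb <- unname(ev_lb[g])
    if (any(is.na(lb) | !is.finite(lb)))
      stop("prgene: locus with candidates lacking finite log_bf", call. = FALSE)
    lb
  })
  has_net <- !is.null(network) &&
    (is.data.frame(network) && nrow(network) > 0 ||
       inherits(network, "gene_network"))
  if (has_net) {
    net <- if (inherits(network, "gene_network")) network else
      gene_network(network, nodes = unique(candidates$gene_id))
    W <- column_normalize(net)
    K <- rwr_kernel(W, restart_prob)
    nodes <- net$nodes
  } else {
    K <- NULL
    nodes <- character(0)
  }
  if (is.null(prior_epsilon))
    prior_epsilon <- if (length(nodes)) 1e-6 / length(nodes) else 1
  # per-locus kernel rows for on-network candidates
  Kl <- lapply(cand, function(g) {
    if (is.null(K)) return(NULL)
    idx <- match(g, nodes)
    on <- !is.na(idx)
    list(on = on, rows = K[idx[on], , drop = FALSE])
  })
  net_idx <- lapply(cand, function(g)
    if (length(nodes)) match(g, nodes) else rep(NA_integer_, length(g)))
  list(loci = loci, cand = cand, logbf = logbf, Kl = Kl,
       net_idx = net_idx, n_nodes = length(nodes),
       eps = prior_epsilon, restart_prob = restart_prob)
}

# conditional probabilities at locus l given network indices of the genes
# selected at the other loci (NA = off-network selection)
.cond_probs <- function(engine, l, other_net_idx) {
  g <- engine$cand[[l]]
  scores <- numeric(length(g))
  seeds <- unique(other_net_idx[!is.na(other_net_idx)])
  kl <- engine$Kl[[l]]
  if (!is.null(kl) && length(seeds)) {
    scores[kl$on] <- rowMeans(kl$rows[, seeds, drop = FALSE])
  }
  w <- log(scores + engine$eps) + engine$logbf[[l]]
  w <- w - max(w)
  p <- exp(w)
  p / sum(p)
}

#' Fit the Gibbs risk-gene prioritizer
#'
#' Samples one candidate gene per GWAS locus at a time, conditional on the
#' current selections at all other loci: the conditional probability of a
#' candidate is proportional to its network prior (random-walk-with-restart
#' proximity to the genes selected elsewhere, epsilon-floored) times its
#' evidence score exp(log_bf). After a burn-in, cumulative per-candidate
#' sampling frequencies are monitored and the chain stops when the sum of
#' squared frequency differences between consecutive checks falls below
#' `threshold` (0.01 by default). The per-locus sampling frequency is the
#' reported posterior probability; the top gene per locus is the prioritized
#' risk gene.
#'
#' @param candidates CandidateTable from [extract_candidates()] (locus_id,
#'   snp_id, gene_id at minimum).
#' @param evidence EvidenceTable with gene_id and log_bf (see
#'   [build_evidence()]).
#' @param network edge-list data.frame (gene_a, gene_b, weight), a
#'   `gene_network`, or NULL for uniform priors.
#' @param restart_prob RWR restart probability.
#' @param prior_epsilon score floor; default 1e-6 / number of network nodes.
#' @param threshold convergence threshold on the sum of squared frequency
#'   differences.
#' @param burn_in sweeps discarded before counting.
#' @param check_every sweeps between convergence checks.
#' @param max_sweeps hard cap; reaching it returns with `converged = FALSE`
#'   and a warning.
#' @param n_sweeps if supplied, run exactly this many post-burn-in sweeps
#'   and skip convergence checking (used for long reference runs).
#' @param scan "systematic" (fixed locus order, default) or "random"
#'   (order permuted each sweep).
#' @param seed integer RNG seed recorded in the fit.
#' @return an object of class `prgene`: list with `posterior` (locus_id,
#'   snp_id, gene_id, frequency, selected), `converged`, `sweeps`,
#'   `recorded_sweeps`, `restart_prob`, `seed`, `call`.
#' @seealso [select_prgenes()], [gibbs_exact_marginals()]
#' @export
prgene <- function(candidates, evidence, network = NULL, restart_prob = 0.5,
                   prior_epsilon = NULL, threshold = 0.01, burn_in = 500L,
                   check_every = 100L, max_sweeps = 20000L, n_sweeps = NULL,
                   scan = c("systematic", "random"), seed = NULL) {
  scan <- match.arg(scan)
  if (threshold <= 0) stop("prgene: threshold must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eng <- .gibbs_engine(candidates, evidence, network, restart_prob,
                       prior_epsilon)
  L <- length(eng$loci)
  # deterministic init: argmax log_bf, ties to lexicographically first gene
  sel <- vapply(seq_len(L), function(l) which.max(eng$logbf[[l]]), 0L)
  sel_net <- vapply(seq_len(L), function(l) eng$net_idx[[l]][sel[l]], 0L)
  counts <- lapply(eng$cand, function(g) integer(length(g)))
  total <- if (is.null(n_sweeps)) max_sweeps else burn_in + n_sweeps
  recorded <- 0L
  f_prev <- numeric(sum(lengths(counts)))
  converged <- if (is.null(n_sweeps)) FALSE else NA
  sweep_i <- 0L
  while (sweep_i < total) {
    sweep_i <- sweep_i + 1L
    order_l <- if (scan == "systematic") seq_len(L) else sample.int(L)
    for (l in order_l) {
      p <- .cond_probs(eng, l, sel_net[-l])
      if (any(is.nan(p)))
        stop("prgene: NaN conditional probability", call. = FALSE)
      j <- sample.int(length(p), 1L, prob = p)
      sel[l] <- j
      sel_net[l] <- eng$net_idx[[l]][j]
    }
    if (sweep_i > burn_in) {
      recorded <- recorded + 1L
      for (l in seq_len(L)) counts[[l]][sel[l]] <- counts[[l]][sel[l]] + 1L
      if (is.null(n_sweeps) && recorded %% check_every == 0L) {
        f <- unlist(counts, use.names = FALSE) / recorded
        if (sum((f - f_prev)^2) < threshold) {
          converged <- TRUE
          break
        }
        f_prev <- f
      }
    }
  }
  if (isFALSE(converged) && is.null(n_sweeps))
    warning("prgene: max_sweeps reached without meeting the convergence ",
            "criterion", call. = FALSE)
  snp_by_locus <- candidates$snp_id[match(eng$loci, candidates$locus_id)]
  post <- do.call(rbind, lapply(seq_len(L), function(l) {
    f <- counts[[l]] / recorded
    top <- order(-f, eng$cand[[l]])[1]
    data.frame(locus_id = eng$loci[l], snp_id = snp_by_locus[l],
               gene_id = eng$cand[[l]], frequency = f,
               selected = seq_along(f) == top, stringsAsFactors = FALSE)
  }))
  rownames(post) <- NULL
  structure(list(posterior = post, converged = converged, sweeps = sweep_i,
                 recorded_sweeps = recorded, burn_in = burn_in,
                 threshold = threshold, restart_prob = eng$restart_prob,
                 prior_epsilon = eng$eps, seed = seed, call = match.call()),
            class = "prgene")
}

#' Prioritized risk genes from a fitted prioritizer
#'
#' Per locus, the candidate with the highest sampling frequency (ties broken
#' by lexicographically smallest gene_id, with a message); plus the unique
#' gene set, since one gene may top several loci.
#'
#' @param object a `prgene` fit (or its posterior data.frame).
#' @return list with `per_locus` (locus_id, snp_id, gene_id, frequency) and
#'   `unique_genes` (gene_id, n_loci, loci, max_frequency).
#' @export
select_prgenes <- function(object) {
  post <- if (inherits(object, "prgene")) object$posterior else object
  sel <- post[post$selected, c("locus_id", "snp_id", "gene_id", "frequency")]
  ties <- vapply(split(post, post$locus_id), function(d)
    sum(d$frequency == max(d$frequency)) > 1L, TRUE)
  if (any(ties))
    message("select_prgenes: frequency tie at ",
            paste(names(ties)[ties], collapse = ", "),
            " broken by gene_id order")
  rownames(sel) <- NULL
  ug <- lapply(split(sel, sel$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], n_loci = nrow(d),
               loci = paste(d$locus_id, collapse = ","),
               max_frequency = max(d$frequency), stringsAsFactors = FALSE))
  ug <- do.call(rbind, ug)
  ug <- ug[order(-ug$n_loci, ug$gene_id), , drop = FALSE]
  rownames(ug) <- NULL
  list(per_locus = sel, unique_genes = ug)
}

#' @export
print.prgene <- function(x, ...) {
  sel <- x$posterior[x$posterior$selected, ]
  cat("Gibbs risk-gene prioritization\n")
  cat(sprintf("  loci: %d   candidates: %d   unique prioritized genes: %d\n",
              length(unique(x$posterior$locus_id)), nrow(x$posterior),
              length(unique(sel$gene_id))))
  cat(sprintf("  sweeps: %d (burn-in %d, recorded %d)   converged: %s\n",
              x$sweeps, x$burn_in, x$recorded_sweeps,
              if (is.na(x$converged)) "not checked" else x$converged))
  cat(sprintf("  restart_prob: %g   threshold: %g\n",
              x$restart_prob, x$threshold))
  invisible(x)
}

#' @export
summary.prgene <- function(object, ...) {
  res <- select_prgenes(object)
  structure(list(fit = object, per_locus = res$per_locus,
                 unique_genes = res$unique_genes), class = "summary.prgene")
}

#' @export
print.summary.prgene <- function(x, ...) {
  print(x$fit)
  cat("\nTop gene per locus (posterior sampling frequency):\n")
  print(x$per_locus, row.names = FALSE)
  multi <- x$unique_genes[x$unique_genes$n_loci > 1L, , drop = FALSE]
  if (nrow(multi)) {
    cat("\nGenes prioritized at multiple loci:\n")
    print(multi, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.prgene <- function(object, ...) {
  p <- object$posterior
  stats::setNames(p$frequency, paste(p$locus_id, p$gene_id, sep = ":"))
}

#' Plot per-locus posterior sampling frequencies
#'
#' One point per candidate, grouped by locus; the prioritized gene at each
#' locus is highlighted.
#'
#' @param x a `prgene` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prgene <- function(x, ...) {
  p <- x$posterior
  li <- match(p$locus_id, unique(p$locus_id))
  graphics::plot(li, p$frequency, pch = 16,
                 col = ifelse(p$selected, "firebrick", "grey60"),
                 xlab = "locus", ylab = "posterior sampling frequency",
                 ylim = c(0, 1), ...)
  sel <- p[p$selected, ]
  graphics::text(match(sel$locus_id, unique(p$locus_id)), sel$frequency,
                 sel$gene_id, pos = 3, cex = 0.6, xpd = NA)
  invisible(x)
}

#' Draw joint gene selections from a fitted posterior
#'
#' Each simulation draws one gene per locus from that locus's posterior
#' sampling frequencies (independently across loci).
#'
#' @param object a `prgene` fit.
#' @param nsim number of draws.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame of gene ids, loci in rows, simulations in columns.
#' @export
simulate.prgene <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  by_locus <- split(object$posterior, object$posterior$locus_id)
  out <- lapply(by_locus, function(d)
    sample(d$gene_id, nsim, replace = TRUE, prob = d$frequency))
  as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE,
                col.names = paste0("sim_", seq_len(nsim)))
}

#' Exact stationary per-locus marginals of the systematic-scan sampler
#'
#' Brute-force reference: enumerates every joint gene configuration, builds
#' the one-sweep transition matrix of the systematic-scan Gibbs chain (the
#' composition of the per-locus conditional updates, identical to the ones
#' the sampler uses), extracts the stationary distribution as the left
#' eigenvector for eigenvalue 1, and marginalizes per locus. Refuses
#' instances with more than `max_states` joint configurations.
#'
#' @inheritParams prgene
#' @param max_states configuration-count cap (default 4096).
#' @return named list: per locus, a named probability vector over its
#'   candidates.
#' @export
gibbs_exact_marginals <- function(candidates, evidence, network = NULL,
                                  restart_prob = 0.5, prior_epsilon = NULL,
                                  max_states = 4096L) {
  eng <- .gibbs_engine(candidates, evidence, network, restart_prob,
                       prior_epsilon)
  L <- length(eng$loci)
  sizes <- vapply(eng$cand, length, 0L)
  n_states <- prod(sizes)
  if (n_states > max_states)
    stop("gibbs_exact_marginals: ", n_states,
         " joint configurations exceed max_states", call. = FALSE)
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  # mixed-radix index of a configuration row (expand.grid varies col 1 fastest)
  radix <- cumprod(c(1, sizes[-L]))
  state_id <- function(conf) as.integer(1 + sum((conf - 1) * radix))
  P <- diag(1, n_states)
  for (l in seq_len(L)) {
    M <- matrix(0, n_states, n_states)
    for (s in seq_len(n_states)) {
      conf <- grid[s, ]
      other_net <- vapply(seq_len(L)[-l],
                          function(k) eng$net_idx[[k]][conf[k]], 0L)
      p <- .cond_probs(eng, l, other_net)
      for (j in seq_along(p)) {
        conf2 <- conf
        conf2[l] <- j
        M[s, state_id(conf2)] <- p[j]
      }
    }
    P <- P %*% M
  }
  ei <- eigen(t(P))
  k <- which.min(abs(ei$values - 1))
  pi_vec <- Re(ei$vectors[, k])
  pi_vec <- pi_vec / sum(pi_vec)
  out <- lapply(seq_len(L), function(l) {
    m <- vapply(seq_len(sizes[l]),
                function(j) sum(pi_vec[grid[, l] == j]), 0)
    stats::setNames(m, eng$cand[[l]])
  })
  stats::setNames(out, eng$loci)
}
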