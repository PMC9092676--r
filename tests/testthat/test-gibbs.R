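single_locus <- function(log_bf = c(A = log(3), B = 0)) {
  list(candidates = data.frame(locus_id = "locus_1", snp_id = "rs1",
                               gene_id = names(log_bf),
                               stringsAsFactors = FALSE),
       evidence = data.frame(gene_id = names(log_bf),
                             log_bf = unname(log_bf),
                             stringsAsFactors = FALSE))
}

test_that("the locus conditional combines prior and evidence as specified", {
  sl <- single_locus()
  eng <- prgene:::.gibbs_engine(sl$candidates, sl$evidence, NULL, 0.5, NULL)
  # no network: conditional proportional to exp(log_bf) alone
  expect_equal(prgene:::.cond_probs(eng, 1, integer(0)), c(0.75, 0.25))
  # a seeded network prior reweights the evidence
  toy <- toy_instance()
  eng2 <- prgene:::.gibbs_engine(toy$candidates, toy$evidence, toy$network,
                                 0.5, NULL)
  W <- column_normalize(gene_network(toy$network,
                                     nodes = toy$candidates$gene_id))
  sc <- rwr(W, "D", 0.5)$scores[c("A", "B", "C")]
  sc[is.na(sc)] <- 0
  lb <- toy$evidence$log_bf[match(c("A", "B", "C"), toy$evidence$gene_id)]
  expected <- (sc + eng2$eps) * exp(lb)
  expected <- unname(expected / sum(expected))
  d_net_idx <- match("D", sort(unique(c(toy$network$gene_a,
                                        toy$network$gene_b,
                                        toy$candidates$gene_id))))
  expect_equal(prgene:::.cond_probs(eng2, 1, d_net_idx), expected,
               tolerance = 1e-9)
})

test_that("long-run single-locus frequencies match the analytic posterior", {
  sl <- single_locus()
  fit <- prgene(sl$candidates, sl$evidence, NULL, n_sweeps = 50000,
                burn_in = 100, seed = 1)
  expect_equal(fit$posterior$frequency, c(0.75, 0.25), tolerance = 0.02)
  expect_equal(sum(fit$posterior$frequency), 1)
  expect_equal(fit$posterior$gene_id[fit$posterior$selected], "A")
})

test_that("fits are deterministic given a seed and reproducible across seeds", {
  toy <- toy_instance()
  f1 <- prgene(toy$candidates, toy$evidence, toy$network, seed = 5,
               burn_in = 200, max_sweeps = 5000)
  f2 <- prgene(toy$candidates, toy$evidence, toy$network, seed = 5,
               burn_in = 200, max_sweeps = 5000)
  expect_identical(f1$posterior, f2$posterior)
  f3 <- prgene(toy$candidates, toy$evidence, toy$network, seed = 99,
               burn_in = 200, max_sweeps = 5000)
  expect_identical(f1$posterior$gene_id[f1$posterior$selected],
                   f3$posterior$gene_id[f3$posterior$selected])
  expect_lt(max(abs(f1$posterior$frequency - f3$posterior$frequency)), 0.05)
})

test_that("frequencies per locus sum to one exactly", {
  toy <- toy_instance()
  fit <- prgene(toy$candidates, toy$evidence, toy$network, seed = 2,
                burn_in = 100, max_sweeps = 2000)
  sums <- tapply(fit$posterior$frequency, fit$posterior$locus_id, sum)
  expect_equal(as.numeric(sums), rep(1, 2))
})

test_that("convergence monitoring behaves at its edges", {
  toy <- toy_instance()
  # infinite threshold: stops at the first post-burn-in check
  fit <- prgene(toy$candidates, toy$evidence, NULL, threshold = Inf,
                burn_in = 50, check_every = 10, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$sweeps, 60)
  # unattainably tight threshold: hits max_sweeps with a warning
  expect_warning(
    fit2 <- prgene(toy$candidates, toy$evidence, NULL, threshold = 1e-12,
                   burn_in = 10, check_every = 10, max_sweeps = 100,
                   seed = 1),
    "max_sweeps")
  expect_false(fit2$converged)
  expect_error(prgene(toy$candidates, toy$evidence, NULL, threshold = 0),
               "threshold")
})

test_that("loci without finite evidence are rejected", {
  sl <- single_locus(c(A = Inf, B = 0))
  expect_error(prgene(sl$candidates, sl$evidence, NULL), "finite")
  sl2 <- single_locus()
  sl2$evidence <- sl2$evidence[1, , drop = FALSE]
  expect_error(prgene(sl2$candidates, sl2$evidence, NULL), "finite")
})

test_that("null evidence with uniform priors gives uniform frequencies", {
  sl <- single_locus(c(A = 0, B = 0, C = 0, D = 0))
  fit <- prgene(sl$candidates, sl$evidence, NULL, n_sweeps = 40000,
                burn_in = 100, seed = 3)
  expect_equal(fit$posterior$frequency, rep(0.25, 4), tolerance = 0.02)
})

test_that("exact stationary oracle handles its analytic cases", {
  # one locus, two candidates: marginal equals the conditional
  sl <- single_locus()
  m <- gibbs_exact_marginals(sl$candidates, sl$evidence, NULL)
  expect_equal(unname(m$locus_1), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(sum(m$locus_1), 1)
  # two independent loci (no network): product factorization
  cand <- data.frame(locus_id = rep(c("L1", "L2"), each = 2),
                     snp_id = rep(c("rs1", "rs2"), each = 2),
                     gene_id = c("A", "B", "C", "D"),
                     stringsAsFactors = FALSE)
  ev <- data.frame(gene_id = c("A", "B", "C", "D"),
                   log_bf = c(log(4), 0, log(2), 0))
  m2 <- gibbs_exact_marginals(cand, ev, NULL)
  expect_equal(unname(m2$L1), c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(unname(m2$L2), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # refuses oversized instances
  big <- data.frame(locus_id = rep(paste0("L", 1:13), each = 2),
                    snp_id = rep(paste0("rs", 1:13), each = 2),
                    gene_id = paste0("g", 1:26), stringsAsFactors = FALSE)
  evb <- data.frame(gene_id = big$gene_id, log_bf = 0)
  expect_error(gibbs_exact_marginals(big, evb, NULL), "max_states")
})

test_that("sampling frequencies agree with the exact stationary marginals", {
  toy <- toy_instance()
  fit <- prgene(toy$candidates, toy$evidence, toy$network, n_sweeps = 30000,
                burn_in = 500, seed = 7)
  oracle <- gibbs_exact_marginals(toy$candidates, toy$evidence, toy$network)
  got <- split(setNames(fit$posterior$frequency, fit$posterior$gene_id),
               fit$posterior$locus_id)
  for (l in names(oracle))
    expect_equal(got[[l]], oracle[[l]][names(got[[l]])], tolerance = 0.02)
})

test_that("prioritized-gene selection applies the tie and uniqueness rules", {
  post <- data.frame(
    locus_id = c("L1", "L1", "L2", "L2", "L3", "L3"),
    snp_id = c("rs1", "rs1", "rs2", "rs2", "rs3", "rs3"),
    gene_id = c("A", "B", "A", "C", "B", "D"),
    frequency = c(0.5, 0.5, 0.9, 0.1, 0.3, 0.7),
    selected = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  expect_message(res <- select_prgenes(post), "tie")
  expect_equal(res$per_locus$gene_id, c("A", "A", "D"))
  # a gene topping two loci appears once with both loci listed
  a_row <- res$unique_genes[res$unique_genes$gene_id == "A", ]
  expect_equal(a_row$n_loci, 2L)
  expect_equal(a_row$loci, "L1,L2")
})

test_that("fit methods print, coerce, plot, and simulate", {
  toy <- toy_instance()
  fit <- prgene(toy$candidates, toy$evidence, toy$network, seed = 4,
                burn_in = 100, max_sweeps = 2000)
  expect_output(print(fit), "Gibbs risk-gene prioritization")
  expect_output(print(summary(fit)), "Top gene per locus")
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(sum(cf), 2)  # two loci, each summing to one
  sims <- simulate(fit, nsim = 5, seed = 1)
  expect_equal(dim(sims), c(2L, 5L))
  expect_true(all(unlist(sims[1, ]) %in% c("A", "B", "C")))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
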