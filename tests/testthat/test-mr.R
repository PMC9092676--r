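make_instruments <- function(p_exp, pos, snp_id = NULL) {
  n <- length(p_exp)
  data.frame(snp_id = snp_id %||% sprintf("s%02d", seq_len(n)),
             gene_id = "G1", tissue = "t1",
             beta_exp = rep(0.3, n), se_exp = rep(0.02, n),
             p_exp = p_exp,
             effect_allele = rep("A", n), other_allele = rep("G", n),
             eaf = rep(0.3, n), pos = pos, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("instrument selection applies the strict p-value threshold", {
  tab <- make_instruments(c(2e-5, 2e-4, 1e-4, 5e-6), pos = 1:4 * 1e6)
  kept <- select_instruments(tab)
  expect_setequal(kept$snp_id, c("s01", "s04"))  # 2e-4 and exactly 1e-4 out
  set.seed(1)
  tab2 <- make_instruments(runif(50, 0, 2e-4), pos = 1:50)
  expect_setequal(select_instruments(tab2)$snp_id,
                  tab2$snp_id[tab2$p_exp < 1e-4])
  tab3 <- tab; tab3$p_exp <- rep(0.5, 4)
  expect_message(out <- select_instruments(tab3), "dropped gene")
  expect_equal(nrow(out), 0)
})

test_that("LD clumping keeps the best SNP and respects window and r2", {
  ld <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(c("s01", "s02"), c("s01", "s02")))
  ins <- make_instruments(c(1e-6, 1e-5), pos = c(1e6, 2e6))
  expect_equal(ld_clump(ins, ld)$snp_id, "s01")
  # r2 exactly at the boundary (0.0005 < 0.001): both kept
  ld2 <- ld; ld2[1, 2] <- ld2[2, 1] <- 0.0005
  expect_setequal(ld_clump(ins, ld2)$snp_id, c("s01", "s02"))
  # far apart (15 Mb): both kept despite r2 = 0.9
  ins3 <- make_instruments(c(1e-6, 1e-5), pos = c(1e6, 16e6))
  expect_setequal(ld_clump(ins3, ld)$snp_id, c("s01", "s02"))
  # missing LD entry within the window removes the SNP, with a message
  ld4 <- ld[1, 1, drop = FALSE]
  expect_message(out <- ld_clump(ins, ld4), "missing LD")
  expect_equal(out$snp_id, "s01")
})

test_that("clumped sets never violate the r2/window rule", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    ins <- make_instruments(runif(n, 1e-8, 1e-4),
                            pos = sort(sample.int(3e7, n)))
    r <- matrix(runif(n * n), n)
    ld <- (r + t(r)) / 2
    diag(ld) <- 1
    dimnames(ld) <- list(ins$snp_id, ins$snp_id)
    kept <- ld_clump(ins, ld)
    if (nrow(kept) >= 2) {
      pairs <- utils::combn(seq_len(nrow(kept)), 2)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        viol <- ld[kept$snp_id[a], kept$snp_id[b]] > 0.001 &&
          abs(kept$pos[a] - kept$pos[b]) <= 1e7
        expect_false(viol)
      }
    }
  }
})

test_that("harmonization aligns alleles and drops ambiguous SNPs", {
  ins <- make_instruments(rep(1e-6, 4), pos = 1:4 * 1e6)
  ins$effect_allele <- c("A", "A", "A", "C")
  ins$other_allele <- c("G", "G", "T", "G")
  ins$eaf <- c(0.3, 0.3, 0.50, 0.3)
  out <- data.frame(snp_id = ins$snp_id,
                    beta_out = c(0.1, 0.2, 0.3, 0.4),
                    se_out = rep(0.05, 4),
                    effect_allele = c("A", "G", "A", "T"),
                    other_allele = c("G", "A", "T", "A"),
                    stringsAsFactors = FALSE)
  suppressMessages(h <- harmonize(ins, out))
  expect_equal(h$beta_out[h$snp_id == "s01"], 0.1)   # same orientation
  expect_equal(h$beta_out[h$snp_id == "s02"], -0.2)  # swapped: negated
  expect_false("s03" %in% h$snp_id)  # palindromic A/T at eaf 0.5
  expect_false("s04" %in% h$snp_id)  # incompatible allele set
})

test_that("Wald ratio matches the delta-method oracle", {
  wr <- wald_ratio(0.25, 0.1, 0.5)
  expect_equal(wr$estimate, 0.5)
  expect_equal(wr$se, 0.2)
  expect_equal(wald_ratio(0, 0.1, 0.5)$estimate, 0)
  set.seed(3)
  for (i in 1:20) {
    bo <- rnorm(1); so <- runif(1, 0.01, 1); bx <- rnorm(1, 0.5, 0.2)
    if (bx == 0) next
    wr <- wald_ratio(bo, so, bx)
    expect_equal(wr$estimate, bo / bx)
    expect_equal(wr$se, so / abs(bx))
    expect_equal(wr$p, 2 * pnorm(-abs((bo / bx) / (so / abs(bx)))))
  }
  expect_error(wald_ratio(0.1, 0.1, 0), "nonzero")
})

test_that("IVW reduces to the Wald ratio for identical SNPs and is exact
           without noise", {
  est <- ivw(c(0.3, 0.3), c(0.15, 0.15), c(0.05, 0.05))
  expect_equal(est$estimate, 0.5)
  # zero-noise synthetic: exact recovery regardless of instrument spread
  cfg <- small_config(seed = 6, mr_noise_sd = 0, theta_mr = 0.5)
  mr <- sim_mr(cfg, list(theta_mr = 0.5), gene_ids = "G0001")
  h <- harmonize(mr$eqtl, mr$outcome)
  expect_equal(ivw(h$beta_exp, h$beta_out, h$se_out)$estimate, 0.5)
  expect_error(ivw(0.3, 0.15, 0.05), ">= 2")
})

test_that("BH adjustment matches an independent step-up oracle", {
  expect_equal(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(4)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("the full MR workflow recovers the planted causal effect", {
  cfg <- small_config(seed = 10, theta_mr = 0.5)
  mr <- sim_mr(cfg, list(theta_mr = 0.5),
               gene_ids = c("G0001", "G0002", "G0003"))
  res <- suppressMessages(mr_analyze(mr$eqtl, mr$outcome, mr$ld))
  expect_s3_class(res, "prgene_mr")
  expect_equal(nrow(res), 3)
  expect_true(all(abs(res$estimate - 0.5) < 0.15))
  expect_true(all(res$fdr >= res$p))
  expect_true(all(res$method == ifelse(res$n_snps == 1, "wald_ratio",
                                       "ivw")))
  expect_output(print(res), "Two-sample MR")
})
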