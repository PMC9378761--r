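test_that("wald_qtl flags a perfect fit as degenerate with beta exact", {
  w <- wald_qtl(c(1, 3, 5, 1, 3, 5), c(0, 1, 2, 0, 1, 2))
  expect_equal(w$beta, 2)
  expect_equal(w$status, "degenerate")
  expect_lte(w$p, 1e-300)
})

test_that("wald_qtl equals the least-squares oracle to 1e-10", {
  # fixed 12-sample worked dataset
  x <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1, 0, 2)
  y <- c(1, 3, 4, 2, 2, 5, 3, 1, 4, 2, 2, 5)
  w <- wald_qtl(y, x)
  o <- lm_oracle(y, x)
  expect_equal(w$beta, o$beta, tolerance = 1e-10)
  expect_equal(w$se, o$se, tolerance = 1e-10)
  expect_equal(w$p, o$p, tolerance = 1e-10)
  # randomized cases with missing data dropped pairwise
  set.seed(23)
  for (r in 1:25) {
    n <- sample(10:60, 1)
    x <- rbinom(n, 2, 0.3)
    y <- sample(1:5, n, TRUE)
    x[sample(n, 2)] <- NA
    y[sample(n, 2)] <- NA
    keep <- !(is.na(x) | is.na(y))
    if (var(x[keep]) == 0 || var(y[keep]) == 0) next
    w <- wald_qtl(y, x)
    o <- lm_oracle(y, x)
    expect_equal(w$beta, o$beta, tolerance = 1e-10)
    expect_equal(w$se, o$se, tolerance = 1e-10)
    expect_equal(w$n_used, sum(keep))
  }
})

test_that("untestable subsets are flagged, not errored", {
  expect_equal(wald_qtl(c(1, 2, 3), c(1, 1, 1))$status, "monomorphic")
  expect_equal(wald_qtl(c(2, 2, 2), c(0, 1, 2))$status,
               "constant_phenotype")
  expect_equal(wald_qtl(c(1, 2), c(0, 1))$status, "too_few")
  expect_equal(lrt_qtl(c(1, 2, 3), c(1, 1, 1))$status, "monomorphic")
})

test_that("lrt_qtl handles the no-improvement and perfect-fit extremes", {
  # orthogonal y: slope exactly 0 -> statistic 0, p = 1
  l <- lrt_qtl(c(1, 5, 1, 5), c(0, 0, 2, 2))
  expect_equal(l$stat, 0)
  expect_equal(l$p, 1)
  l <- lrt_qtl(c(1, 3, 5, 1, 3, 5), c(0, 1, 2, 0, 1, 2))
  expect_equal(l$status, "degenerate")
})

test_that("Wald and LRT p-values agree asymptotically", {
  set.seed(24)
  n <- 272
  wp <- lp <- numeric(400)
  for (j in seq_along(wp)) {
    x <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- sample(1:5, n, TRUE)
    wp[j] <- wald_qtl(y, x)$p
    lp[j] <- lrt_qtl(y, x)$p
  }
  expect_gt(cor(wp, lp, method = "spearman"), 0.99)
})

test_that("Wald type-I error is nominal under the permutation null", {
  set.seed(25)
  n <- 272
  p <- numeric(600)
  for (j in seq_along(p)) {
    x <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- sample(rep(1:5, length.out = n))  # permuted, independent of x
    p[j] <- wald_qtl(y, x)$p
  }
  for (alpha in c(0.05, 0.01)) {
    mc_se <- sqrt(alpha * (1 - alpha) / length(p))
    expect_lt(abs(mean(p < alpha) - alpha), 3 * mc_se)
  }
})

test_that("bonferroni_adjust is exact, linear and uncapped", {
  expect_equal(bonferroni_adjust(1 / 800000), 1)
  expect_equal(bonferroni_adjust(0.5), 4e5)      # far beyond 1, uncapped
  p <- c(1e-9, 1e-6, 1e-3)
  expect_equal(bonferroni_adjust(2 * p), 2 * bonferroni_adjust(p))
  expect_equal(bonferroni_adjust(0.5, m_tests = 10), 5)
  expect_error(bonferroni_adjust(0), "\\(0, 1]")
  expect_error(bonferroni_adjust(0.5, m_tests = 0), "m_tests")
})

test_that("assign_tier partitions (0, 1] at the quoted boundaries", {
  expect_equal(assign_tier(1.9e-9), "significant")
  expect_equal(assign_tier(5e-8), "suggestive")   # inclusive lower edge
  expect_equal(assign_tier(1e-5), "none")         # exclusive upper edge
  expect_equal(assign_tier(0.5), "none")
  set.seed(26)
  p <- c(10^runif(200, -12, 0), 5e-8, 1e-5, 1)
  tiers <- assign_tier(p)
  expect_false(any(is.na(tiers)))
  expect_true(all(tiers %in% c("significant", "suggestive", "none")))
  expect_error(assign_tier(0), "\\(0, 1]")
})

test_that("cluster_loci applies the co-segregation rule", {
  # 5 suggestive SNPs at 1 kb spacing: everyone has 4 neighbors -> clustered
  r5 <- assoc_row(sprintf("s%d", 1:5), 1, 1e6 + (0:4) * 1000)
  out <- cluster_loci(r5)
  expect_true(all(out$snps$locus_kind == "clustered"))
  expect_equal(nrow(out$loci), 1L)
  expect_equal(out$loci$n_snps, 5L)

  # one isolated SNP -> singleton
  out <- cluster_loci(assoc_row("solo", 2, 5e6, tier = "significant"))
  expect_equal(out$snps$locus_kind, "singleton")

  # 3 SNPs within the window: nobody exceeds 3 neighbors -> singletons
  # sharing a group annotation
  r3 <- assoc_row(sprintf("t%d", 1:3), 3, 2e6 + (0:2) * 1000)
  out <- cluster_loci(r3)
  expect_true(all(out$snps$locus_kind == "singleton"))
  expect_equal(length(unique(out$loci$group_id)), 1L)

  # untested ("none") SNPs never enter loci
  rn <- rbind(r5, assoc_row("null1", 1, 1e6 + 5000, tier = "none"))
  out <- cluster_loci(rn)
  expect_false("null1" %in% out$snps$snp_id)
})

test_that("cluster_loci output partitions the tiered SNP set", {
  set.seed(27)
  r <- assoc_row(sprintf("s%03d", 1:60), sample(1:4, 60, TRUE),
                 sample.int(5e7, 60))
  out <- cluster_loci(r)
  expect_setequal(out$snps$snp_id, r$snp_id)
  expect_false(anyDuplicated(out$snps$snp_id) > 0)
  expect_equal(sum(out$loci$n_snps), 60L)
})

test_that("replication_select applies all three thresholds", {
  mk <- function(p) data.frame(phenotype = "H1", snp_id = "rs1", beta = 0.5,
                               wald_p = p, stringsAsFactors = FALSE)
  expect_true(replication_select(mk(3e-6), mk(0.01), mk(0.04))$selected)
  expect_false(replication_select(mk(3e-6), mk(0.01), mk(0.06))$selected)
  expect_false(replication_select(mk(2e-5), mk(0.01), mk(0.04))$selected)
  # sign concordance is reported
  a <- mk(3e-6); b <- mk(0.01); b$beta <- -0.5
  expect_false(replication_select(a, b, mk(0.04))$beta_sign_concordant)
  # key mismatch errors
  bad <- mk(0.01); bad$snp_id <- "rs2"
  expect_error(replication_select(a, bad, mk(0.04)), "keys")
})

test_that("a planted effect at generator defaults survives replication", {
  # default planted effect size (0.8 per allele on the latent propensity);
  # the full filter: combined p < 1e-5 and both cohorts p < 0.05
  specs <- snp_spec("snpC", maf = 0.4)
  eff <- data.frame(snp_id = "snpC", phenotype = "H3", effect = 0.8)
  sel <- logical(60)
  for (r in seq_along(sel)) {
    g1 <- gen_genotypes(specs, 172, seed = 3000 + 2 * r,
                        sample_ids = sprintf("P1_%03d", 1:172))
    g2 <- gen_genotypes(specs, 100, seed = 3001 + 2 * r,
                        sample_ids = sprintf("P2_%03d", 1:100))
    c1 <- gen_pattern_codes(g1, eff, "H3", seed = 3000 + 2 * r)
    c2 <- gen_pattern_codes(g2, eff, "H3", seed = 3001 + 2 * r)
    geno <- list(genotypes = rbind(g1$genotypes, g2$genotypes),
                 variants = g1$variants)
    rs <- replication_select(assoc_scan(rbind(c1, c2), geno),
                             assoc_scan(c1, g1), assoc_scan(c2, g2))
    sel[r] <- rs$selected[1]
  }
  expect_gte(mean(sel), 0.8)
})

test_that("assoc_scan wires tiers, bonferroni and missingness together", {
  specs <- snp_spec(c("a", "b"), maf = c(0.4, 0.3),
                    missing_rate = c(0.1, 0))
  geno <- gen_genotypes(specs, 120, seed = 30)
  codes <- gen_pattern_codes(geno, NULL, c("H1", "V1"), seed = 30)
  res <- assoc_scan(codes, geno, m_tests = 1000)
  expect_equal(nrow(res), 4L)
  ok <- res$status == "ok"
  expect_equal(res$bonferroni[ok], res$wald_p[ok] * 1000)
  expect_true(all(res$n_used[res$snp_id == "a"] <= 120))
  expect_error(assoc_scan(codes, geno, snp_ids = "nope"), "unknown snp_id")
})
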