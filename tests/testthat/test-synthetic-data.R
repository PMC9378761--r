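test_that("generators are bit-identical for a fixed seed", {
  specs <- snp_spec(sprintf("s%02d", 1:10), maf = seq(0.05, 0.5, length.out = 10),
                    missing_rate = 0.05)
  g1 <- gen_genotypes(specs, 50, seed = 99)
  g2 <- gen_genotypes(specs, 50, seed = 99)
  expect_identical(g1, g2)
  eff <- data.frame(snp_id = "s05", phenotype = "H1", effect = 0.5)
  c1 <- gen_pattern_codes(g1, eff, c("H1", "V1"), seed = 99)
  c2 <- gen_pattern_codes(g2, eff, c("H1", "V1"), seed = 99)
  expect_identical(c1, c2)
  sp <- cohort_spec(50)
  expect_identical(gen_trajectories(c1, sp, seed = 99),
                   gen_trajectories(c2, sp, seed = 99))
  expect_false(identical(gen_genotypes(specs, 50, seed = 100), g1))
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(snp_spec("a", maf = 0.6), "maf")
  expect_error(snp_spec("a", missing_rate = 1), "missing_rate")
  expect_error(snp_spec("a", pos = 0), "pos")
  expect_error(snp_spec(c("a", "a")), "duplicate")
  expect_error(gen_genotypes(snp_spec("a"), n = 0, seed = 1), "n must be")
  expect_error(cohort_spec(0), "n_individuals")
  expect_error(cohort_spec(10, photos_per_person_range = c(2, 2)),
               "at least 3")
  expect_error(cohort_spec(10, noise_sd = -1), "noise_sd")
})

test_that("degenerate maf = 0 gives all-zero dosages", {
  g <- gen_genotypes(snp_spec("a", maf = 0), n = 50, seed = 2)
  expect_true(all(g$genotypes == 0L))
  expect_equal(variant_stats(g)$maf, 0)
})

test_that("generated genotypes match their target MAF and sit in HWE", {
  g <- gen_genotypes(snp_spec("a", maf = 0.3), n = 5000, seed = 4)
  st <- variant_stats(g)
  se <- sqrt(0.3 * 0.7 / (2 * 5000))  # binomial SE of the allele frequency
  expect_lt(abs(st$maf - 0.3), 3 * se)

  # HWE exact-test rejection rate across 200 null SNPs is ~0.05
  specs <- snp_spec(sprintf("s%03d", 1:200),
                    maf = rep(seq(0.1, 0.5, 0.1), 40))
  g <- gen_genotypes(specs, 500, seed = 5)
  st <- variant_stats(g)
  rej <- mean(st$hwe_p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(rej, 0.05 + 3 * mc_se)
})

test_that("missing_rate masks approximately the stated fraction", {
  g <- gen_genotypes(snp_spec("a", maf = 0.3, missing_rate = 0.1),
                     n = 5000, seed = 6)
  expect_lt(abs(mean(is.na(g$genotypes)) - 0.1), 3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("null pattern codes hit uniform marginals at quantile cuts", {
  g <- gen_genotypes(snp_spec("a"), n = 5000, seed = 7)
  codes <- gen_pattern_codes(g, NULL, "H1", seed = 7,
                             marginals = list(H1 = rep(0.2, 5)))
  freq <- tabulate(codes$code, 5) / 5000
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("a strong planted effect makes mean code monotone in dosage", {
  g <- gen_genotypes(snp_spec("a", maf = 0.5), n = 3000, seed = 8)
  codes <- gen_pattern_codes(
    g, data.frame(snp_id = "a", phenotype = "H3", effect = 2), "H3",
    seed = 8)
  means <- tapply(codes$code, g$genotypes[, "a"], mean)
  expect_true(all(diff(means[as.character(0:2)]) > 0))
})

test_that("unknown causal SNP ids are rejected", {
  g <- gen_genotypes(snp_spec("a"), n = 10, seed = 9)
  expect_error(
    gen_pattern_codes(g, data.frame(snp_id = "zzz", phenotype = "H1",
                                    effect = 1), "H1", seed = 9),
    "zzz")
})

test_that("noise-free trajectories realize their planted template shapes", {
  sp <- cohort_spec(5, noise_sd = 0)
  codes <- data.frame(person_id = sprintf("P%d", 1:5), phenotype = "H3",
                      code = 1:5)
  ph <- gen_trajectories(codes, sp, seed = 10)
  for (i in 1:5) {
    v <- ph[ph$person_id == sprintf("P%d", i), ]
    v <- v[order(v$age), ]
    if (i == 3) expect_equal(var(v$value), 0, tolerance = 1e-24)
    if (i == 1) expect_true(all(diff(v$value) < 0))  # strictly decreasing
    if (i == 5) expect_true(all(diff(v$value) > 0))
  }
  expect_error(
    gen_trajectories(data.frame(person_id = "P", phenotype = "H3", code = 7),
                     sp),
    "1..5")
})

test_that("photo schedules respect the cohort design", {
  sp <- cohort_spec(40)
  codes <- data.frame(person_id = sprintf("P%02d", 1:40), phenotype = "H1",
                      code = 3L)
  ph <- gen_trajectories(codes, sp, seed = 11)
  per <- split(ph, ph$person_id)
  for (d in per) {
    expect_true(max(d$age) == d$current_age[1])
    expect_true(d$current_age[1] >= 18 && d$current_age[1] <= 20)
    n_past <- sum(d$age < d$current_age)
    expect_true(n_past >= 5 && n_past <= 7)
    # at least one photo per age band
    past <- d$age[d$age < d$current_age]
    expect_true(any(past < 5) && any(past >= 5 & past < 10) &&
                  any(past >= 10 & past < 15) && any(past >= 15))
  }
})

test_that("landmark fixtures carry exact ground truth", {
  fx <- gen_landmark_fixtures(4, seed = 12)
  out <- compute_phenotypes(fx$landmarks)
  key <- function(d) paste(d$photo_id, d$phenotype)
  truth <- fx$truth$value[match(key(out), key(fx$truth))]
  expect_equal(out$value, truth, tolerance = 1e-12)
  expect_error(gen_landmark_fixtures(0), "n_photos")
})
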