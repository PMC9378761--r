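make_pheno <- function(person_id, ages, current_age, values,
                       phenotype = "H3") {
  data.frame(person_id = person_id,
             photo_id = paste0(person_id, "_", seq_along(ages)),
             age = ages, current_age = current_age,
             phenotype = phenotype, value = values,
             stringsAsFactors = FALSE)
}

test_that("build_trajectories puts photos on relative age", {
  ph <- make_pheno("P1", c(10, 15, 19), 19, c(1, 2, 3))
  built <- build_trajectories(ph)
  expect_length(built$trajectories, 1L)
  expect_equal(built$trajectories[[1]]$relative_age, c(-9, -4, 0))
  expect_equal(nrow(built$unclassifiable), 0L)
})

test_that("too few observations are unclassifiable, not an error", {
  ph <- make_pheno("P1", c(10, 19), 19, c(1, 2))
  built <- build_trajectories(ph)
  expect_length(built$trajectories, 0L)
  expect_equal(built$unclassifiable$reason, "too_few_observations")
})

test_that("same-age duplicate photos are averaged", {
  ph <- make_pheno("P1", c(10, 10, 15, 19), 19, c(1.0, 1.2, 2, 3))
  tr <- build_trajectories(ph)$trajectories[[1]]
  expect_equal(tr$value[tr$relative_age == -9], 1.1)
  expect_equal(nrow(tr), 3L)
})

test_that("a person with no current photo is an error", {
  ph <- make_pheno("P1", c(10, 12, 15), 19, c(1, 2, 3))
  expect_error(build_trajectories(ph), "current photo")
})

test_that("QC-removed current observation makes the record unclassifiable", {
  ph <- make_pheno("P1", c(10, 12, 15, 19), 19, c(1, 2, 3, 4))
  ph$qc_pass <- c(TRUE, TRUE, TRUE, FALSE)
  built <- build_trajectories(ph)
  expect_equal(built$unclassifiable$reason, "no_current_observation")
})

test_that("fit_growth recovers exact polynomials", {
  # linear: value = 2 + 0.5 t
  t <- c(-12, -8, -5, -2, 0)
  fit <- fit_growth(data.frame(relative_age = t, value = 2 + 0.5 * t))
  expect_equal(fit$b1, 0.5, tolerance = 1e-12)
  expect_equal(fit$b2, 0, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)

  # value = t^2 over [-10, 0]: analytic endpoint slopes -20 and 0
  t <- c(-10, -7, -4, 0)
  fit <- fit_growth(data.frame(relative_age = t, value = t^2))
  expect_equal(fit$s_start, -20, tolerance = 1e-10)
  expect_equal(fit$s_end, 0, tolerance = 1e-10)

  # three points interpolate
  fit <- fit_growth(data.frame(relative_age = c(-9, -4, 0),
                               value = c(5, 1, 7)))
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
})

test_that("fit_growth coefficients are within 3 SE of truth under noise", {
  # Monte-Carlo against the generating parameters (a=1.5, b1=0.04, b2=0.002)
  t <- c(-15, -12, -9, -6, -4, -2, 0)
  truth <- c(1.5, 0.04, 0.002)
  set.seed(101)
  miss <- 0L
  for (r in 1:100) {
    y <- truth[1] + truth[2] * t + truth[3] * t^2 + rnorm(7, sd = 0.01)
    fit <- fit_growth(data.frame(relative_age = t, value = y))
    X <- cbind(1, t, t^2)
    se <- sqrt(diag(solve(crossprod(X))) *
                 sum((y - X %*% c(fit$a, fit$b1, fit$b2))^2) / (7 - 3))
    miss <- miss + any(abs(c(fit$a, fit$b1, fit$b2) - truth) > 3 * se)
  }
  expect_lte(miss, 10)
})

test_that("fit_growth guards degenerate inputs", {
  expect_error(fit_growth(data.frame(relative_age = c(-1, 0),
                                     value = c(1, 2))), ">= 3")
  expect_error(fit_growth(data.frame(relative_age = c(0, 0, 0),
                                     value = 1:3)), "distinct")
})

test_that("classify_pattern follows the slope-sign rules", {
  mkfit <- function(a, b1, b2, t = c(-10, -5, 0)) {
    fit_growth(data.frame(relative_age = t, value = a + b1 * t + b2 * t^2))
  }
  expect_equal(classify_pattern(mkfit(10, -1, 0))$label, "DD")
  expect_equal(classify_pattern(mkfit(10, 1, 0))$label, "II")
  expect_equal(classify_pattern(mkfit(10, 0, 0))$label, "CC")
  # value = (t+5)^2: slopes -10 then +10 -> DI despite zero net change
  di <- fit_growth(data.frame(relative_age = c(-10, -7, -3, 0),
                              value = (c(-10, -7, -3, 0) + 5)^2))
  expect_equal(classify_pattern(di)$label, "DI")
  expect_equal(classify_pattern(di)$code, 2L)
  id <- fit_growth(data.frame(relative_age = c(-10, -7, -3, 0),
                              value = 50 - (c(-10, -7, -3, 0) + 5)^2))
  expect_equal(classify_pattern(id)$label, "ID")
})

test_that("label/code bijection is fixed", {
  expect_equal(pattern_codes(),
               c(DD = 1L, DI = 2L, CC = 3L, ID = 4L, II = 5L))
  expect_equal(pattern_label(c(1, 5, 3)), c("DD", "II", "CC"))
  expect_error(pattern_label(6), "1..5")
})

test_that("noise-free templates round-trip through the classifier", {
  for (code in 1:5) {
    fit <- fit_growth(template_traj(code))
    expect_equal(classify_pattern(fit)$code, code, label = paste("code", code))
  }
})

test_that("classification is invariant to uniform positive scaling", {
  # the flatness tolerance is relative to the fitted magnitude, so rescaling
  # all values (unit changes) never moves a label; offsets, by contrast,
  # change the magnitude the tolerance is relative to and are not invariant
  set.seed(21)
  for (r in 1:20) {
    code <- sample(1:5, 1)
    tr <- template_traj(code)
    tr$value <- tr$value + rnorm(nrow(tr), sd = 0.01)
    base <- classify_pattern(fit_growth(tr))$code
    for (s in c(1e-3, 7, 1000)) {
      scaled <- tr
      scaled$value <- tr$value * s
      expect_equal(classify_pattern(fit_growth(scaled))$code, base)
    }
  }
})

test_that("mean fitted total change increases across codes 1..5", {
  set.seed(31)
  n <- 250
  codes <- data.frame(person_id = sprintf("X%04d", 1:n), phenotype = "H3",
                      code = rep(1:5, each = n / 5))
  ph <- gen_trajectories(codes, cohort_spec(n, noise_sd = 0.01), seed = 31)
  cls <- classify_trajectories(build_trajectories(ph))
  m <- merge(cls, codes, by = "person_id")
  means <- tapply(m$total_change, m$code.y, mean)
  expect_true(all(diff(means) > 0))
})

test_that("accuracy degrades gracefully with noise and is high at low noise", {
  run_acc <- function(noise_sd) {
    n <- 250
    set.seed(77)
    codes <- data.frame(person_id = sprintf("X%04d", 1:n), phenotype = "H3",
                        code = rep(1:5, each = n / 5))
    ph <- gen_trajectories(codes, cohort_spec(n, noise_sd = noise_sd),
                           seed = 77)
    cls <- classify_trajectories(build_trajectories(ph))
    m <- merge(cls[, c("person_id", "code")], codes, by = "person_id")
    mean(m$code.x == m$code.y)
  }
  baseline <- default_phenotype_baselines("H3")[["H3"]]
  acc0 <- run_acc(0)
  acc_low <- run_acc(0.002 * baseline)
  acc_high <- run_acc(0.05 * baseline)
  expect_equal(acc0, 1)
  expect_gte(acc_low, 0.9)
  expect_gte(acc_low, acc_high)
})

test_that("pattern_table counts, proportions and modes", {
  pats <- data.frame(phenotype = rep("H3", 10), code = rep(5L, 10))
  tab <- pattern_table(pats, cohort_label = "POP1",
                       phenotype_levels = c("H3", "H4"))
  h3 <- tab[tab$phenotype == "H3", ]
  expect_equal(as.numeric(h3[paste0("code", 1:5)]), c(0, 0, 0, 0, 10))
  expect_equal(h3$modal_code, 5L)
  h4 <- tab[tab$phenotype == "H4", ]
  expect_equal(h4$n, 0L)
  expect_true(is.na(h4$modal_code))
  # sampling check against generator marginals
  set.seed(5)
  n <- 2000
  marg <- c(0.1, 0.1, 0.1, 0.1, 0.6)
  pats <- data.frame(phenotype = "H3",
                     code = sample(1:5, n, TRUE, prob = marg))
  tab <- pattern_table(pats)
  se <- sqrt(marg * (1 - marg) / n)
  expect_true(all(abs(as.numeric(tab[paste0("prop", 1:5)]) - marg) <=
                    3 * se))
})
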