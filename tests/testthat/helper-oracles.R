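# Independent oracles and fixture builders shared across the suite.

# Exact HWE p-value by full enumeration with the closed-form conditional
# probability (lgamma form) -- an independent code path from the package's
# ratio recurrence.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  nm <- min(nA, na)
  if (nm == 0) return(1)
  hs <- seq.int(nm %% 2L, nm, by = 2L)
  lp <- vapply(hs, function(h) {
    a <- (nm - h) / 2
    b <- (2 * n - nm - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  min(sum(p[p <= obs * (1 + 1e-10)]), 1)
}

# Closed-form simple-regression oracle via stats::lm (QR decomposition),
# independent of the package's direct normal-equation arithmetic.
lm_oracle <- function(y, x) {
  keep <- stats::complete.cases(y, x)
  fit <- stats::lm(y[keep] ~ x[keep])
  s <- summary(fit)$coefficients
  list(beta = unname(s[2, 1]), se = unname(s[2, 2]), p = unname(s[2, 4]))
}

# One landmark-schema row built from explicit coordinates. `points` is a
# named list of c(x, y); unspecified landmarks fall back to a spread-out
# template so the row always validates.
make_landmark_row <- function(points = list(), person_id = "P1",
                              photo_id = "ph1", age = 10, current_age = 18) {
  tmpl <- eafg:::face_template() * 60 + 500
  for (nm in names(points)) tmpl[nm, ] <- points[[nm]]
  rec <- c(list(person_id = person_id, photo_id = photo_id, age = age,
                current_age = current_age),
           stats::setNames(as.list(as.vector(t(tmpl))),
                           as.vector(rbind(paste0(rownames(tmpl), "_x"),
                                           paste0(rownames(tmpl), "_y")))))
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Noise-free trajectory realizing a planted code over a fixed age grid.
template_traj <- function(code, t = c(-15, -12, -8, -4, 0), baseline = 1.5,
                          amplitude = 0.3) {
  tmpl <- eafg:::trajectory_template(code, min(t), baseline, amplitude)
  data.frame(relative_age = t, value = tmpl(t))
}

# Minimal association result frame for cluster/replication tests.
assoc_row <- function(snp_id, chrom, pos, tier = "suggestive",
                      phenotype = "H1", beta = 0.5, wald_p = 1e-6) {
  data.frame(phenotype = phenotype, snp_id = snp_id, chrom = as.character(chrom),
             pos = as.integer(pos), beta = beta, wald_p = wald_p, tier = tier,
             stringsAsFactors = FALSE)
}
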