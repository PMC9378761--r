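## Synthetic cohorts with the statistical structure the analysis assumes:
## genotypes in Hardy-Weinberg equilibrium, latent-propensity pattern codes
## with planted per-allele effects, and quadratic growth trajectories whose
## endpoint slopes realize the coded pattern.

#' Specify a synthetic SNP panel
#'
#' @param snp_id Identifiers.
#' @param chrom Chromosome labels.
#' @param pos 1-based base positions (> 0).
#' @param maf Allele frequencies in `[0, 0.5]`.
#' @param missing_rate Per-entry missingness probabilities in `[0, 1)`.
#' @param effect Per-allele shifts on the latent pattern propensity (0 for
#'   null SNPs); the generative stand-in for the association beta.
#' @return Data frame of SNP specifications (recycled to a common length).
#' @export
snp_spec <- function(snp_id, chrom = "1", pos = seq_along(snp_id) * 1e6,
                     maf = 0.3, missing_rate = 0, effect = 0) {
  out <- data.frame(snp_id = snp_id, chrom = as.character(chrom),
                    pos = as.integer(pos), maf = maf,
                    missing_rate = missing_rate, effect = effect,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp_id)) stop_eafg("snp_spec: duplicate snp_id")
  if (any(out$maf < 0 | out$maf > 0.5)) {
    stop_eafg("snp_spec: maf must be in [0, 0.5]")
  }
  if (any(out$missing_rate < 0 | out$missing_rate >= 1)) {
    stop_eafg("snp_spec: missing_rate must be in [0, 1)")
  }
  if (any(out$pos <= 0)) stop_eafg("snp_spec: pos must be positive")
  out
}

#' Specify a synthetic cohort
#'
#' Defaults state the cohort design being emulated: individuals aged 18-20
#' at recruitment, each contributing 5-7 past photos (at least one per age
#' band below 5, 5-10, 10-15 and 15-20 years) plus one current photo.
#'
#' @param n_individuals Cohort size (the two study cohorts are 172 and 100).
#' @param current_age_range Inclusive integer range of current ages.
#' @param photos_per_person_range Inclusive range of past-photo counts.
#' @param noise_sd Measurement noise SD in normalized-distance units
#'   (default 0.02; the study does not state one).
#' @param label Cohort label used in person ids.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_individuals, current_age_range = c(18L, 20L),
                        photos_per_person_range = c(5L, 7L),
                        noise_sd = 0.02, label = "POP") {
  if (!is_count(n_individuals)) stop_eafg("cohort_spec: n_individuals >= 1")
  if (photos_per_person_range[1] < 3) {
    stop_eafg("cohort_spec: need at least 3 past photos")
  }
  if (noise_sd < 0) stop_eafg("cohort_spec: noise_sd must be >= 0")
  structure(list(n_individuals = as.integer(n_individuals),
                 current_age_range = as.integer(current_age_range),
                 photos_per_person_range = as.integer(photos_per_person_range),
                 noise_sd = noise_sd, label = label),
            class = "cohort_spec")
}

#' Generate genotypes under Hardy-Weinberg equilibrium
#'
#' Each dosage is the sum of two independent allele draws at the SNP's
#' specified frequency, so genotype proportions are in HWE in expectation.
#' Entries are then masked missing independently with `missing_rate`.
#'
#' @param snp_specs Data frame from [snp_spec()].
#' @param n Number of individuals.
#' @param seed Integer seed (fixed seed gives bit-identical output).
#' @param sample_ids Optional sample identifiers.
#' @return Genotype container: `genotypes` (n x SNPs integer matrix with NA
#'   for missing) and `variants` (`snp_id`, `chrom`, `pos`, `ref`, `alt`).
#' @examples
#' g <- gen_genotypes(snp_spec(c("rs1", "rs2"), maf = c(0.2, 0.4)),
#'                    n = 10, seed = 1)
#' g$genotypes
#' @export
gen_genotypes <- function(snp_specs, n, seed,
                          sample_ids = sprintf("S%04d", seq_len(n))) {
  specs <- snp_spec(snp_specs$snp_id, snp_specs$chrom, snp_specs$pos,
                    snp_specs$maf, snp_specs$missing_rate %||% 0,
                    snp_specs$effect %||% 0)
  if (!is_count(n)) stop_eafg("gen_genotypes: n must be >= 1")
  set.seed(derive_seed(seed, "genotypes"))
  m <- nrow(specs)
  g <- matrix(NA_integer_, nrow = n, ncol = m,
              dimnames = list(sample_ids, specs$snp_id))
  for (j in seq_len(m)) {
    d <- rbinom(n, 1L, specs$maf[j]) + rbinom(n, 1L, specs$maf[j])
    if (specs$missing_rate[j] > 0) {
      d[runif(n) < specs$missing_rate[j]] <- NA_integer_
    }
    g[, j] <- d
  }
  variants <- data.frame(snp_id = specs$snp_id, chrom = specs$chrom,
                         pos = specs$pos, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  new_genotypes(g, variants)
}

#' Default marginal pattern frequencies per phenotype
#'
#' Mimics the observed dominance of the continued-increase pattern (code 5)
#' for most facial distances, with eye-width phenotypes (H1, H2, H4)
#' dominated instead by continued decrease (code 1).
#'
#' @param phenotype_names Character vector of phenotype names.
#' @return Named list of length-5 frequency vectors (one per phenotype).
#' @export
default_pattern_marginals <- function(phenotype_names) {
  increase_dom <- c(0.10, 0.10, 0.10, 0.10, 0.60)
  decrease_dom <- rev(increase_dom)
  out <- lapply(phenotype_names, function(ph) {
    if (ph %in% c("H1", "H2", "H4")) decrease_dom else increase_dom
  })
  names(out) <- phenotype_names
  out
}

#' Generate growth-pattern codes from genotypes (latent-propensity model)
#'
#' For each phenotype, a latent propensity `L = sum_j effect_j dosage_j +
#' standard normal noise` is discretized into codes 1-5 at the empirical
#' quantiles of `L` implied by the requested marginal pattern frequencies,
#' so planted per-allele effects shift individuals monotonically toward
#' higher codes while the marginals stay on target. Missing dosages of a
#' causal SNP contribute their expected value `2 maf` (estimated from the
#' called genotypes) so every individual gets a code.
#'
#' @param geno Genotype container from [gen_genotypes()].
#' @param causal_effects Data frame `snp_id`, `phenotype`, `effect`
#'   (zero rows for a fully null cohort); SNP ids must exist in `geno`.
#' @param phenotype_names Phenotypes to code (default the 21 default
#'   measurements).
#' @param seed Integer seed.
#' @param marginals Named list of length-5 marginal frequency vectors,
#'   default [default_pattern_marginals()].
#' @return Data frame: `person_id`, `phenotype`, `code` (1-5).
#' @export
gen_pattern_codes <- function(geno, causal_effects = NULL,
                              phenotype_names = default_measurement_table()$name,
                              seed = 1,
                              marginals = default_pattern_marginals(phenotype_names)) {
  g <- geno$genotypes
  n <- nrow(g)
  if (is.null(causal_effects) || nrow(causal_effects) == 0) {
    causal_effects <- data.frame(snp_id = character(),
                                 phenotype = character(),
                                 effect = numeric(), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(causal_effects$snp_id, colnames(g))
  if (length(unknown)) {
    stop_eafg("gen_pattern_codes: unknown SNP id(s) in effects: ",
              paste(unknown, collapse = ", "))
  }
  if (!all(vapply(marginals, function(m) {
    length(m) == 5 && all(m >= 0) && abs(sum(m) - 1) < 1e-8
  }, logical(1)))) {
    stop_eafg("gen_pattern_codes: each marginal must be 5 frequencies ",
              "summing to 1")
  }
  set.seed(derive_seed(seed, "pattern_codes"))
  out <- vector("list", length(phenotype_names))
  for (k in seq_along(phenotype_names)) {
    ph <- phenotype_names[k]
    eff <- causal_effects[causal_effects$phenotype == ph, , drop = FALSE]
    latent <- rnorm(n)
    if (nrow(eff)) {
      for (i in seq_len(nrow(eff))) {
        d <- g[, eff$snp_id[i]]
        if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
        latent <- latent + eff$effect[i] * d
      }
    }
    marg <- marginals[[ph]]
    cuts <- quantile(latent, cumsum(marg)[1:4], names = FALSE, type = 7)
    code <- 1L + rowSums(outer(latent, cuts, `>`))
    out[[k]] <- data.frame(person_id = rownames(g), phenotype = ph,
                           code = as.integer(code), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Baseline normalized distances for the default phenotypes
#'
#' Plausible interocular-normalized magnitudes for each default measurement
#' (e.g. eye width ~0.6, full face height ~2.3); used as trajectory
#' baselines by [gen_trajectories()]. Unknown phenotypes default to 1.
#'
#' @param phenotype_names Phenotype names.
#' @return Named numeric vector of baselines.
#' @export
default_phenotype_baselines <- function(phenotype_names = default_measurement_table()$name) {
  base <- c(H1 = 0.63, H2 = 0.63, H3 = 0.44, H4 = 1.70, H5 = 0.60,
            H6 = 0.96, H7 = 0.34, H8 = 0.34, H9 = 1.25, H10 = 1.25,
            V1 = 0.22, V2 = 0.22, V3 = 1.20, V4 = 1.05, V5 = 0.85,
            V6 = 0.20, V7 = 0.30, V8 = 0.30, V9 = 0.65, V10 = 1.25,
            V11 = 2.30)
  out <- base[phenotype_names]
  out[is.na(out)] <- 1
  names(out) <- phenotype_names
  out
}

trajectory_template <- function(code, t0, baseline, amplitude) {
  ## quadratic over [t0, 0] whose endpoint slopes realize the coded pattern.
  ## For the monotone templates (DD, II) amplitude is the absolute change
  ## across the span. The turning templates (DI, ID) place their vertex at
  ## 40% of the span from the present, so the initial phase dominates and
  ## mean net change is ordered DD < DI < CC < ID < II (a property the
  ## pattern coding relies on); their maximum deviation is amplitude.
  stopifnot(t0 < 0)
  tv <- 0.4 * t0
  cc <- amplitude / (0.6 * t0)^2
  switch(code,
    function(t) baseline + (-amplitude / abs(t0)) * t,   # 1 DD
    function(t) baseline + cc * (t - tv)^2,              # 2 DI
    function(t) rep(baseline, length(t)),                # 3 CC
    function(t) baseline - cc * (t - tv)^2,              # 4 ID
    function(t) baseline + (amplitude / abs(t0)) * t     # 5 II
  )
}

sample_photo_ages <- function(current_age, n_past) {
  ## one age per band (<5, 5-10, 10-15, 15-current), extras spread randomly
  bands <- list(2:4, 5:9, 10:14, seq.int(15, max(15, current_age - 1)))
  ages <- vapply(bands, function(b) b[sample.int(length(b), 1)], numeric(1))
  pool <- setdiff(2:(current_age - 1), ages)
  extra <- n_past - length(ages)
  if (extra > 0) ages <- c(ages, sample(pool, extra))
  sort(ages)
}

#' Generate measurement trajectories realizing given pattern codes
#'
#' Each (person, phenotype) gets a quadratic template over relative age
#' `[-(current_age - first photo age), 0]` whose endpoint slopes realize the
#' planted code -- DD both negative, DI negative then positive, CC flat, ID
#' positive then negative, II both positive -- plus Gaussian measurement
#' noise of SD `noise_sd`. With zero noise the classifier recovers every
#' planted code exactly.
#'
#' @param codes Data frame `person_id`, `phenotype`, `code` from
#'   [gen_pattern_codes()].
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param amplitude_rel Fitted change across the span as a fraction of the
#'   phenotype baseline (default 0.2, a realistic growth-scale change).
#' @param baselines Named baseline vector, default
#'   [default_phenotype_baselines()].
#' @return Long-format phenotype data frame (`person_id`, `photo_id`, `age`,
#'   `current_age`, `phenotype`, `value`).
#' @export
gen_trajectories <- function(codes, spec, seed = 1, amplitude_rel = 0.2,
                             baselines = default_phenotype_baselines(unique(codes$phenotype))) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!all(codes$code %in% 1:5)) {
    stop_eafg("gen_trajectories: codes must be in 1..5")
  }
  set.seed(derive_seed(seed, "trajectories"))
  persons <- unique(codes$person_id)
  ## per-person photo schedule
  sched <- lapply(persons, function(p) {
    cur <- sample(seq.int(spec$current_age_range[1],
                          spec$current_age_range[2]), 1)
    n_past <- sample(seq.int(spec$photos_per_person_range[1],
                             spec$photos_per_person_range[2]), 1)
    ages <- sample_photo_ages(cur, n_past)
    data.frame(person_id = p, age = c(ages, cur), current_age = cur,
               photo_id = c(sprintf("%s_a%02d", p, ages),
                            sprintf("%s_current", p)),
               stringsAsFactors = FALSE)
  })
  names(sched) <- persons
  rows <- vector("list", nrow(codes))
  for (i in seq_len(nrow(codes))) {
    p <- codes$person_id[i]
    ph <- codes$phenotype[i]
    s <- sched[[p]]
    t <- s$age - s$current_age
    baseline <- unname(baselines[ph])
    tmpl <- trajectory_template(codes$code[i], min(t), baseline,
                                amplitude_rel * baseline)
    val <- tmpl(t)
    if (spec$noise_sd > 0) val <- val + rnorm(length(t), sd = spec$noise_sd)
    rows[[i]] <- data.frame(person_id = p, photo_id = s$photo_id,
                            age = s$age, current_age = s$current_age,
                            phenotype = ph, value = val,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Template face in interocular units (x right, y up, iris centers at +-0.5).
face_template <- function() {
  rbind(
    iris_L = c(-0.5, 0), iris_R = c(0.5, 0),
    exocanthion_L = c(-0.85, 0.02), endocanthion_L = c(-0.22, 0),
    endocanthion_R = c(0.22, 0), exocanthion_R = c(0.85, 0.02),
    palpebrale_sup_L = c(-0.5, 0.12), palpebrale_inf_L = c(-0.5, -0.10),
    palpebrale_sup_R = c(0.5, 0.12), palpebrale_inf_R = c(0.5, -0.10),
    nasion = c(0, 0.30), pronasale = c(0, -0.55), subnasale = c(0, -0.75),
    alare_L = c(-0.30, -0.60), alare_R = c(0.30, -0.60),
    labiale_sup = c(0, -1.05), labiale_inf = c(0, -1.35),
    cheilion_L = c(-0.48, -1.20), cheilion_R = c(0.48, -1.20),
    gnathion = c(0, -2.00), trichion = c(0, 1.50)
  )
}

#' Generate landmark-file fixtures with known ground-truth phenotypes
#'
#' Produces well-separated 19-point configurations (template face plus small
#' jitter) under a random similarity transform (rotation, uniform scale,
#' translation) per photo, together with the ground-truth normalized
#' distances computed by direct coordinate arithmetic -- an independent code
#' path against which [compute_phenotypes()] can be checked.
#'
#' @param n_photos Number of photos (>= 1).
#' @param seed Integer seed.
#' @param table Measurement table defining the ground-truth distances.
#' @param jitter_sd Landmark jitter SD in interocular units (default 0.02).
#' @return List: `landmarks` (landmark CSV schema data frame) and `truth`
#'   (long data frame `person_id`, `photo_id`, `phenotype`, `value`).
#' @export
gen_landmark_fixtures <- function(n_photos, seed = 1,
                                  table = default_measurement_table(),
                                  jitter_sd = 0.02) {
  if (!is_count(n_photos)) stop_eafg("n_photos must be >= 1")
  set.seed(derive_seed(seed, "landmark_fixtures"))
  tmpl <- face_template()
  lm_rows <- vector("list", n_photos)
  truth_rows <- vector("list", n_photos)
  for (i in seq_len(n_photos)) {
    pts <- tmpl + matrix(rnorm(length(tmpl), sd = jitter_sd), nrow(tmpl))
    theta <- runif(1, -0.2, 0.2)
    scale <- runif(1, 40, 120)
    shift <- runif(2, 200, 800)
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    xy <- scale * (pts %*% rot) +
      matrix(shift, nrow(pts), 2, byrow = TRUE)
    rownames(xy) <- rownames(tmpl)
    rec <- c(list(person_id = sprintf("FX%03d", i),
                  photo_id = sprintf("FX%03d_ph", i),
                  age = 18, current_age = 18),
             setNames(as.list(as.vector(t(xy))),
                      as.vector(rbind(paste0(rownames(xy), "_x"),
                                      paste0(rownames(xy), "_y")))))
    lm_rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    ## ground truth by direct arithmetic on the transformed coordinates
    iod <- sqrt(sum((xy["iris_L", ] - xy["iris_R", ])^2))
    vals <- vapply(seq_len(nrow(table)), function(k) {
      d <- xy[table$point_a[k], ] - xy[table$point_b[k], ]
      sqrt(d[1]^2 + d[2]^2) / iod
    }, numeric(1))
    truth_rows[[i]] <- data.frame(person_id = sprintf("FX%03d", i),
                                  photo_id = sprintf("FX%03d_ph", i),
                                  phenotype = table$name, value = vals,
                                  stringsAsFactors = FALSE)
  }
  list(landmarks = do.call(rbind, lm_rows),
       truth = do.call(rbind, truth_rows))
}

#' Write a landmark data frame as CSV
#' @param landmarks Landmark schema data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate one cohort end to end
#'
#' Genotypes, planted pattern codes and noisy trajectories for one cohort,
#' plus the ground truth needed by round-trip tests.
#'
#' @param spec A [cohort_spec()].
#' @param snp_specs SNP panel from [snp_spec()].
#' @param causal_effects Data frame `snp_id`, `phenotype`, `effect`.
#' @param seed Integer seed.
#' @param phenotype_names Phenotypes to simulate.
#' @param marginals Marginal pattern frequencies (see
#'   [gen_pattern_codes()]).
#' @param amplitude_rel Trajectory change fraction (see
#'   [gen_trajectories()]).
#' @return List: `geno`, `codes`, `phenotypes` (long measurement table),
#'   `spec`, `causal_effects`.
#' @export
simulate_cohort <- function(spec, snp_specs, causal_effects = NULL, seed = 1,
                            phenotype_names = default_measurement_table()$name,
                            marginals = default_pattern_marginals(phenotype_names),
                            amplitude_rel = 0.2) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- sprintf("%s_%04d", spec$label, seq_len(spec$n_individuals))
  geno <- gen_genotypes(snp_specs, spec$n_individuals,
                        seed = derive_seed(seed, spec$label),
                        sample_ids = ids)
  codes <- gen_pattern_codes(geno, causal_effects, phenotype_names,
                             seed = derive_seed(seed, paste0(spec$label, "_codes")),
                             marginals = marginals)
  phen <- gen_trajectories(codes, spec,
                           seed = derive_seed(seed, paste0(spec$label, "_traj")),
                           amplitude_rel = amplitude_rel)
  list(geno = geno, codes = codes, phenotypes = phen, spec = spec,
       causal_effects = causal_effects)
}
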