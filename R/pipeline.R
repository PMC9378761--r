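#' Build a pipeline configuration
#'
#' Collects every tunable of the analysis with its documented default:
#' measurement trimming 2% per tail; quadratic-fit flatness tolerance 0.02;
#' genotype filters call rate >= 0.98, MAF >= 0.10, HWE p > 1e-4; Bonferroni
#' multiplier 800000; tiers at 5e-8 / 1e-5; replication thresholds 1e-5
#' combined and 0.05 per cohort; 500 kb locus window. With no input paths
#' the pipeline simulates two cohorts (172 and 100 individuals) on the given
#' SNP panel.
#'
#' @param outdir Output directory for stage TSVs and the manifest.
#' @param seed Master seed; every random stage derives its stream from it.
#' @param landmarks_paths,vcf_path Optional real inputs: named list/vector of
#'   landmark CSVs per cohort and one VCF shared by all samples. If `NULL`,
#'   synthetic cohorts are generated.
#' @param cohorts List of [cohort_spec()]s (default POP1 n=172, POP2 n=100).
#' @param snp_specs SNP panel for simulation, default
#'   [default_snp_panel()].
#' @param causal_effects Planted effects for simulation (data frame
#'   `snp_id`, `phenotype`, `effect`), default
#'   [default_causal_effects()].
#' @param measurement_table Measurement table (default 21 measurements).
#' @param trim_pct Percent trimmed per tail (default 2).
#' @param eps_rel Classifier flatness tolerance (default 0.02).
#' @param call_rate_min,maf_min,hwe_p_min Genotype QC thresholds.
#' @param m_tests Bonferroni multiplier.
#' @param significant_max,suggestive_max Tier thresholds.
#' @param combined_max,cohort_max Replication thresholds.
#' @param window_bp,min_neighbors Locus clustering parameters.
#' @param plots Write Manhattan/QQ PNGs (default `FALSE`).
#' @return A `eafg_config` list.
#' @export
eafg_config <- function(outdir, seed = 1,
                        landmarks_paths = NULL, vcf_path = NULL,
                        cohorts = list(cohort_spec(172, label = "POP1"),
                                       cohort_spec(100, label = "POP2")),
                        snp_specs = default_snp_panel(),
                        causal_effects = default_causal_effects(),
                        measurement_table = default_measurement_table(),
                        trim_pct = 2, eps_rel = 0.02,
                        call_rate_min = 0.98, maf_min = 0.10,
                        hwe_p_min = 1e-4, m_tests = 800000,
                        significant_max = 5e-8, suggestive_max = 1e-5,
                        combined_max = 1e-5, cohort_max = 0.05,
                        window_bp = 500000, min_neighbors = 3,
                        plots = FALSE) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              landmarks_paths = landmarks_paths, vcf_path = vcf_path,
              cohorts = cohorts, snp_specs = snp_specs,
              causal_effects = causal_effects,
              measurement_table = measurement_table,
              trim_pct = trim_pct, eps_rel = eps_rel,
              call_rate_min = call_rate_min, maf_min = maf_min,
              hwe_p_min = hwe_p_min, m_tests = m_tests,
              significant_max = significant_max,
              suggestive_max = suggestive_max,
              combined_max = combined_max, cohort_max = cohort_max,
              window_bp = window_bp, min_neighbors = min_neighbors,
              plots = plots)
  class(cfg) <- "eafg_config"
  cfg
}

#' Default synthetic SNP panel
#'
#' 120 independent SNPs on four chromosomes: 100 null SNPs with MAFs on a
#' grid straddling the 0.10 filter boundary, low missingness, plus two
#' causal common SNPs and a clustered run of tiered-by-construction
#' neighbors used to exercise locus grouping.
#'
#' @return [snp_spec()] data frame.
#' @export
default_snp_panel <- function() {
  n_null <- 100
  mafs <- rep(seq(0.05, 0.5, by = 0.05), length.out = n_null)
  null_specs <- snp_spec(sprintf("null%03d", seq_len(n_null)),
                         chrom = rep(c("1", "2", "3", "4"), each = 25),
                         pos = rep(seq_len(25) * 2e6, times = 4),
                         maf = mafs, missing_rate = 0.01)
  causal <- snp_spec(c("causalH1", "causalV5"), chrom = c("11", "5"),
                     pos = c(119897453L, 60843706L), maf = c(0.4, 0.4),
                     missing_rate = 0, effect = c(0.8, -0.8))
  cluster <- snp_spec(sprintf("clust%02d", 1:5), chrom = "7",
                      pos = as.integer(4.76e6 + (0:4) * 1e5), maf = 0.4,
                      missing_rate = 0, effect = 0.8)
  rbind(null_specs, causal, cluster)
}

#' Default planted effects
#'
#' The two causal SNPs act on one horizontal (H1) and one vertical (V5)
#' phenotype with opposite-sign latent effects; the clustered SNPs all act
#' on H1.
#'
#' @return Data frame `snp_id`, `phenotype`, `effect`.
#' @export
default_causal_effects <- function() {
  data.frame(
    snp_id = c("causalH1", "causalV5", sprintf("clust%02d", 1:5)),
    phenotype = c("H1", "V5", rep("H1", 5)),
    effect = c(0.8, -0.8, rep(0.8, 5)),
    stringsAsFactors = FALSE)
}

#' Validate a pipeline configuration
#'
#' Total function: returns a character vector of violations (empty means
#' valid), each naming the offending field and its admissible range.
#'
#' @param cfg An [eafg_config()].
#' @return Character vector of violations (length 0 when the config is ok).
#' @export
validate_config <- function(cfg) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed: must be a single integer")
  chk(cfg$trim_pct >= 0 && cfg$trim_pct < 50,
      "trim_pct: must be in [0, 50)")
  chk(cfg$eps_rel > 0 && cfg$eps_rel < 1, "eps_rel: must be in (0, 1)")
  chk(is_prob(cfg$call_rate_min), "call_rate_min: must be in [0, 1]")
  chk(is.numeric(cfg$maf_min) && cfg$maf_min >= 0 && cfg$maf_min <= 0.5,
      "maf_min: must be in [0, 0.5]")
  chk(is.numeric(cfg$hwe_p_min) && cfg$hwe_p_min >= 0 && cfg$hwe_p_min < 1,
      "hwe_p_min: must be in [0, 1)")
  chk(is_count(cfg$m_tests), "m_tests: must be a count >= 1")
  chk(is.numeric(cfg$significant_max) && cfg$significant_max > 0 &&
        cfg$significant_max <= 1, "significant_max: must be in (0, 1]")
  chk(is.numeric(cfg$suggestive_max) && cfg$suggestive_max > 0 &&
        cfg$suggestive_max <= 1, "suggestive_max: must be in (0, 1]")
  if (is.numeric(cfg$significant_max) && is.numeric(cfg$suggestive_max)) {
    chk(cfg$significant_max < cfg$suggestive_max,
        "tier thresholds: significant_max must be below suggestive_max")
  }
  chk(is.numeric(cfg$combined_max) && cfg$combined_max > 0 &&
        cfg$combined_max <= 1, "combined_max: must be in (0, 1]")
  chk(is.numeric(cfg$cohort_max) && cfg$cohort_max > 0 &&
        cfg$cohort_max <= 1, "cohort_max: must be in (0, 1]")
  chk(is_count(cfg$window_bp), "window_bp: must be a count >= 1")
  chk(is.numeric(cfg$min_neighbors) && cfg$min_neighbors >= 0,
      "min_neighbors: must be >= 0")
  chk(length(cfg$cohorts) >= 1 &&
        all(vapply(cfg$cohorts, inherits, logical(1), "cohort_spec")),
      "cohorts: must be a non-empty list of cohort_spec objects")
  v
}

stage_log <- function(stage, msg) {
  message(sprintf("[eafg] %-10s %s", stage, msg))
}

config_fingerprint <- function(cfg) {
  flat <- cfg
  flat$cohorts <- lapply(flat$cohorts, unclass)
  fnv1a_hash(jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA,
                              force = TRUE))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or ingest) inputs; compute phenotypes;
#' measurement QC; trajectory classification and pattern tables; genotype
#' QC; association scans for the combined cohort and each cohort separately;
#' replication selection and locus clustering; modal-pattern concordance.
#' All stage outputs are written as TSVs under `cfg$outdir`, plus a
#' `manifest.json` recording the config fingerprint, seed, package version
#' and per-stage record counts. Identical config and seed give identical
#' outputs.
#'
#' @param cfg An [eafg_config()]; invalid configs abort with the violation
#'   list.
#' @return Invisibly, a list with the main in-memory results: `phenotypes`,
#'   `patterns` (per cohort), `pattern_tables`, `variant_stats`, `assoc`
#'   (combined/pop per phenotype), `replication`, `loci`, `concordance`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  viol <- validate_config(cfg)
  if (length(viol)) {
    stop_eafg("invalid config:\n  ", paste(viol, collapse = "\n  "))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  fail_marker <- file.path(cfg$outdir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(stage, conditionMessage(e)), fail_marker)
      stop_eafg("pipeline stage '", stage, "' failed: ",
                conditionMessage(e))
    })
  }

  ## ---- stage: inputs (simulate or ingest) ----
  cohort_labels <- vapply(cfg$cohorts, `[[`, "", "label")
  if (is.null(cfg$landmarks_paths)) {
    inputs <- run_stage("simulate", {
      stage_log("simulate", paste("cohorts:",
                                  paste(cohort_labels, collapse = ", ")))
      sims <- lapply(cfg$cohorts, function(sp) {
        simulate_cohort(sp, cfg$snp_specs, cfg$causal_effects,
                        seed = cfg$seed,
                        phenotype_names = cfg$measurement_table$name)
      })
      names(sims) <- cohort_labels
      ## one shared genotype container (same panel, stacked samples)
      geno <- new_genotypes(
        do.call(rbind, lapply(sims, function(s) s$geno$genotypes)),
        sims[[1]]$geno$variants)
      write_vcf(geno, file.path(cfg$outdir, "genotypes.vcf"))
      truth <- do.call(rbind, lapply(sims, `[[`, "codes"))
      write.table(truth, file.path(cfg$outdir, "planted_codes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      phen <- do.call(rbind, lapply(seq_along(sims), function(i) {
        cbind(sims[[i]]$phenotypes, cohort = cohort_labels[i],
              stringsAsFactors = FALSE)
      }))
      list(phenotypes = phen, geno = geno)
    })
  } else {
    inputs <- run_stage("ingest", {
      stage_log("ingest", "reading landmark CSVs and VCF")
      phen <- do.call(rbind, lapply(seq_along(cfg$landmarks_paths),
                                    function(i) {
        lm <- read_landmarks(cfg$landmarks_paths[[i]])
        cbind(compute_phenotypes(lm, cfg$measurement_table),
              cohort = names(cfg$landmarks_paths)[i] %||% cohort_labels[i],
              stringsAsFactors = FALSE)
      }))
      list(phenotypes = phen, geno = read_vcf(cfg$vcf_path))
    })
    cohort_labels <- unique(inputs$phenotypes$cohort)
  }
  phenotypes <- inputs$phenotypes
  geno <- inputs$geno
  counts$phenotype_records <- nrow(phenotypes)
  write_phenotypes(phenotypes, file.path(cfg$outdir, "phenotypes.tsv"))

  ## ---- stage: measurement QC ----
  phenotypes <- run_stage("measure_qc", {
    out <- apply_measurement_qc(phenotypes, cfg$trim_pct, cfg$trim_pct)
    stage_log("measure_qc", sprintf("flagged %d of %d records",
                                    sum(!out$qc_pass), nrow(out)))
    out
  })
  counts$qc_flagged <- sum(!phenotypes$qc_pass)
  write.table(phenotypes[, c("person_id", "photo_id", "phenotype",
                             "qc_flag")],
              file.path(cfg$outdir, "qc_mask.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## ---- stage: classify ----
  patterns <- run_stage("classify", {
    out <- lapply(cohort_labels, function(lab) {
      built <- build_trajectories(
        phenotypes[phenotypes$cohort == lab, , drop = FALSE])
      cls <- classify_trajectories(built, eps_rel = cfg$eps_rel)
      stage_log("classify", sprintf(
        "%s: %d classified, %d unclassifiable", lab, nrow(cls),
        nrow(built$unclassifiable)))
      list(patterns = cls, unclassifiable = built$unclassifiable)
    })
    names(out) <- cohort_labels
    out
  })
  all_patterns <- do.call(rbind, lapply(cohort_labels, function(lab) {
    cbind(patterns[[lab]]$patterns, cohort = lab, stringsAsFactors = FALSE)
  }))
  counts$classified <- nrow(all_patterns)
  counts$unclassifiable <- sum(vapply(patterns, function(p)
    nrow(p$unclassifiable), integer(1)))
  write.table(all_patterns, file.path(cfg$outdir, "patterns.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pattern_tables <- lapply(cohort_labels, function(lab) {
    pattern_table(patterns[[lab]]$patterns, cohort_label = lab,
                  phenotype_levels = cfg$measurement_table$name)
  })
  names(pattern_tables) <- cohort_labels
  write.table(do.call(rbind, pattern_tables),
              file.path(cfg$outdir, "pattern_tables.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## ---- stage: genotype QC ----
  vstats <- run_stage("geno_qc", {
    st <- filter_variants(variant_stats(geno), cfg$call_rate_min,
                          cfg$maf_min, cfg$hwe_p_min)
    stage_log("geno_qc", sprintf("%d of %d SNPs retained", sum(st$pass),
                                 nrow(st)))
    st
  })
  counts$snps_total <- nrow(vstats)
  counts$snps_retained <- sum(vstats$pass)
  write.table(vstats, file.path(cfg$outdir, "variant_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- vstats$snp_id[vstats$pass]

  ## ---- stage: association ----
  assoc <- run_stage("assoc", {
    runs <- list(combined = all_patterns)
    for (lab in cohort_labels) {
      runs[[lab]] <- all_patterns[all_patterns$cohort == lab, , drop = FALSE]
    }
    out <- lapply(names(runs), function(nm) {
      res <- assoc_scan(runs[[nm]], geno, m_tests = cfg$m_tests,
                        snp_ids = kept)
      res$tier <- assign_tier(res$wald_p, cfg$significant_max,
                              cfg$suggestive_max)
      stage_log("assoc", sprintf("%s: %d tests, %d tiered", nm, nrow(res),
                                 sum(res$tier != "none", na.rm = TRUE)))
      res
    })
    names(out) <- names(runs)
    out
  })
  counts$assoc_tests <- nrow(assoc$combined)
  for (nm in names(assoc)) {
    out <- assoc[[nm]]
    out$bonferroni <- ifelse(is.na(out$bonferroni), NA,
                             signif(out$bonferroni, 2))
    write.table(out, file.path(cfg$outdir, paste0("assoc_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(cfg$plots)) {
    for (ph in unique(assoc$combined$phenotype)) {
      sub <- assoc$combined[assoc$combined$phenotype == ph, , drop = FALSE]
      manhattan_plot(sub, file.path(cfg$outdir,
                                    sprintf("manhattan_%s.png", ph)),
                     cfg$significant_max, cfg$suggestive_max)
      qq_plot(sub$wald_p, file.path(cfg$outdir, sprintf("qq_%s.png", ph)))
    }
  }

  ## ---- stage: replication + loci ----
  repl <- loci <- NULL
  if (length(cohort_labels) >= 2) {
    repl <- run_stage("replicate", {
      r <- replication_select(assoc$combined, assoc[[cohort_labels[1]]],
                              assoc[[cohort_labels[2]]],
                              cfg$combined_max, cfg$cohort_max)
      stage_log("replicate", sprintf("%d of %d selected", sum(r$selected),
                                     nrow(r)))
      r
    })
    write.table(repl, file.path(cfg$outdir, "replication.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts$replicated <- sum(repl$selected)
  }
  loci <- run_stage("loci", {
    cluster_loci(unique(assoc$combined[, c("snp_id", "chrom", "pos",
                                           "tier")]),
                 cfg$window_bp, cfg$min_neighbors)
  })
  write.table(loci$loci, file.path(cfg$outdir, "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts$loci <- if (is.null(loci$loci)) 0L else nrow(loci$loci)

  ## ---- stage: concordance ----
  concordance <- NULL
  if (length(cohort_labels) >= 2) {
    concordance <- run_stage("concord", {
      cc <- modal_concordance(pattern_tables[[cohort_labels[1]]],
                              pattern_tables[[cohort_labels[2]]])
      stage_log("concord", sprintf("modal agreement %.2f",
                                   cc$fraction_agree))
      cc
    })
    write.table(concordance$per_phenotype,
                file.path(cfg$outdir, "concordance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(packageVersion("eafg")),
    seed = cfg$seed,
    config_fingerprint = config_fingerprint(cfg),
    counts = counts,
    fraction_agree = if (!is.null(concordance))
      concordance$fraction_agree else NA)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(phenotypes = phenotypes, patterns = patterns,
                 pattern_tables = pattern_tables, variant_stats = vstats,
                 assoc = assoc, replication = repl, loci = loci,
                 concordance = concordance, manifest = manifest))
}
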