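## Single-SNP quantitative-trait association of the ordinal growth-pattern
## code (1-5) on allele dosage (0/1/2). The trait is treated as quantitative
## in a simple linear model without covariates, mirroring the classic
## qassoc convention: t-distribution Wald p with n - 2 df, plus a Gaussian
## likelihood-ratio test against the intercept-only model.

P_FLOOR <- .Machine$double.xmin

#' Wald test of a single SNP on the coded growth pattern
#'
#' Ordinary least squares of the pattern code on dosage (intercept + slope,
#' no covariates). `beta` is the slope, its standard error comes from the
#' residual variance with `n - 2` degrees of freedom, and the two-sided
#' Wald p-value from the t distribution with `n - 2` df. Samples with a
#' missing genotype or phenotype are dropped pairwise.
#'
#' @param codes Numeric phenotype vector (pattern codes 1-5; NA allowed).
#' @param dosages Allele dosages 0/1/2 (NA allowed).
#' @return List: `beta`, `se`, `t`, `p`, `n_used`, `status` (one of
#'   `"ok"`, `"degenerate"` for a perfect fit with the p-value floored,
#'   `"monomorphic"`, `"constant_phenotype"`, `"too_few"`; estimates are NA
#'   for untestable SNPs).
#' @examples
#' wald_qtl(c(1, 3, 5, 1, 3, 5), c(0, 1, 2, 0, 1, 2))
#' @export
wald_qtl <- function(codes, dosages) {
  keep <- !(is.na(codes) | is.na(dosages))
  y <- as.numeric(codes[keep])
  x <- as.numeric(dosages[keep])
  n <- length(y)
  na_out <- function(status) list(beta = NA_real_, se = NA_real_,
                                  t = NA_real_, p = NA_real_, n_used = n,
                                  status = status)
  if (n < 3) return(na_out("too_few"))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0) return(na_out("monomorphic"))
  if (syy == 0) return(na_out("constant_phenotype"))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  rss <- max(rss, 0)
  sigma2 <- rss / (n - 2)
  if (sigma2 <= 0 || sqrt(sigma2 / sxx) == 0) {
    return(list(beta = beta, se = 0, t = Inf, p = P_FLOOR, n_used = n,
                status = "degenerate"))
  }
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  list(beta = beta, se = se, t = tval, p = max(p, P_FLOOR), n_used = n,
       status = "ok")
}

#' Likelihood-ratio test of a single SNP on the coded growth pattern
#'
#' Gaussian likelihood-ratio statistic `n log(RSS0 / RSS1)` of the
#' dosage-slope model against the intercept-only model, compared with a
#' chi-square distribution with 1 df.
#'
#' @inheritParams wald_qtl
#' @return List: `stat`, `p`, `n_used`, `status` (as in [wald_qtl()];
#'   a perfect fit floors the p-value and flags `"degenerate"`).
#' @export
lrt_qtl <- function(codes, dosages) {
  keep <- !(is.na(codes) | is.na(dosages))
  y <- as.numeric(codes[keep])
  x <- as.numeric(dosages[keep])
  n <- length(y)
  na_out <- function(status) list(stat = NA_real_, p = NA_real_, n_used = n,
                                  status = status)
  if (n < 3) return(na_out("too_few"))
  sxx <- sum((x - mean(x))^2)
  rss0 <- sum((y - mean(y))^2)
  if (sxx == 0) return(na_out("monomorphic"))
  if (rss0 == 0) return(na_out("constant_phenotype"))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss1 <- max(rss0 - beta^2 * sxx, 0)
  if (rss1 == 0) {
    return(list(stat = Inf, p = P_FLOOR, n_used = n, status = "degenerate"))
  }
  stat <- n * log(rss0 / rss1)
  list(stat = stat, p = max(pchisq(stat, df = 1, lower.tail = FALSE),
                            P_FLOOR),
       n_used = n, status = "ok")
}

#' Bonferroni adjustment, uncapped
#'
#' Multiplies the raw p-value by the number of tests. The product is
#' deliberately not capped at 1: genome-wide result tables conventionally
#' print values such as 9.1E+03 for clearly null SNPs, and the adjusted
#' value stays exactly linear in p. Tables render it to 2 significant
#' figures; the returned value is unrounded.
#'
#' @param p Raw p-value(s) in (0, 1].
#' @param m_tests Number of tests (default 800000, the approximate size of a
#'   genome-wide SNP panel).
#' @return `p * m_tests` (may exceed 1).
#' @examples
#' signif(bonferroni_adjust(1.9e-9), 2)  # 0.0015
#' @export
bonferroni_adjust <- function(p, m_tests = 800000) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop_eafg("bonferroni_adjust: p must be in (0, 1]")
  }
  if (!is_count(m_tests)) stop_eafg("bonferroni_adjust: m_tests must be >= 1")
  p * m_tests
}

#' Assign genome-wide significance tier from a raw p-value
#'
#' `significant` iff `p < 5e-8`; `suggestive` iff `5e-8 <= p < 1e-5`;
#' `none` otherwise. The boundaries partition (0, 1]: exactly 5e-8 is
#' suggestive, exactly 1e-5 is none.
#'
#' @param p Raw p-value(s) in (0, 1] (NA gives NA).
#' @param significant_max Exclusive upper bound for `significant`.
#' @param suggestive_max Exclusive upper bound for `suggestive`.
#' @return Character vector in `{"significant", "suggestive", "none"}`.
#' @export
assign_tier <- function(p, significant_max = 5e-8, suggestive_max = 1e-5) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    stop_eafg("assign_tier: p must be in (0, 1]")
  }
  out <- ifelse(p < significant_max, "significant",
                ifelse(p < suggestive_max, "suggestive", "none"))
  out[is.na(p)] <- NA_character_
  out
}

#' Genome scan: every SNP against every phenotype's pattern codes
#'
#' Runs [wald_qtl()] and [lrt_qtl()] for each (phenotype, SNP) pair,
#' attaches the uncapped Bonferroni value and the significance tier.
#'
#' @param codes Data frame with columns `person_id`, `phenotype`, `code`
#'   (e.g. from [classify_trajectories()]).
#' @param geno Genotype container; `rownames(geno$genotypes)` are person ids.
#' @param m_tests Bonferroni multiplier (default 800000).
#' @param snp_ids Optional subset of SNPs to test (default: all).
#' @return Data frame: `phenotype`, `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `beta`, `se`, `wald_p`, `lrt_p`, `bonferroni`, `tier`, `n_used`,
#'   `status`.
#' @export
assoc_scan <- function(codes, geno, m_tests = 800000, snp_ids = NULL) {
  g <- geno$genotypes
  v <- geno$variants
  if (!is.null(snp_ids)) {
    j <- match(snp_ids, v$snp_id)
    if (anyNA(j)) stop_eafg("unknown snp_id(s): ",
                            paste(snp_ids[is.na(j)], collapse = ", "))
    g <- g[, j, drop = FALSE]
    v <- v[j, , drop = FALSE]
  }
  phenos <- unique(codes$phenotype)
  out <- vector("list", length(phenos))
  for (k in seq_along(phenos)) {
    ph <- phenos[k]
    sub <- codes[codes$phenotype == ph, , drop = FALSE]
    y <- sub$code[match(rownames(g), sub$person_id)]
    rows <- lapply(seq_len(ncol(g)), function(j) {
      w <- wald_qtl(y, g[, j])
      l <- lrt_qtl(y, g[, j])
      data.frame(phenotype = ph, snp_id = v$snp_id[j], chrom = v$chrom[j],
                 pos = v$pos[j], ref = v$ref[j], alt = v$alt[j],
                 beta = w$beta, se = w$se, wald_p = w$p, lrt_p = l$p,
                 bonferroni = if (is.na(w$p)) NA_real_ else
                   bonferroni_adjust(w$p, m_tests),
                 tier = assign_tier(w$p), n_used = w$n_used,
                 status = w$status, stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group tiered SNPs into singleton and clustered loci
#'
#' Tiered (significant or suggestive) SNPs on the same chromosome are linked
#' when within `window_bp` of each other (single linkage). A connected group
#' is a clustered locus iff some member co-segregates with more than
#' `min_neighbors` other tiered SNPs within the window; otherwise each
#' member is reported as a singleton, annotated with its group id.
#'
#' @param results Association results (rows with `tier != "none"` are used;
#'   needs `snp_id`, `chrom`, `pos`). Pass one phenotype's results at a time
#'   or deduplicated SNPs.
#' @param window_bp Linkage window in base pairs (default 500000).
#' @param min_neighbors Neighbor count that must be exceeded for a group to
#'   be clustered (default 3, i.e. "more than three others").
#' @return List with `snps` (per-SNP `locus_id`, `locus_kind`) and `loci`
#'   (per-locus `locus_id`, `chrom`, `start`, `end`, `n_snps`, `kind`).
#' @export
cluster_loci <- function(results, window_bp = 500000, min_neighbors = 3) {
  keep <- !is.na(results$tier) & results$tier != "none"
  snps <- unique(results[keep, c("snp_id", "chrom", "pos"), drop = FALSE])
  if (anyDuplicated(snps$snp_id)) {
    stop_eafg("cluster_loci: conflicting positions for a snp_id")
  }
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  if (!nrow(snps)) {
    return(list(
      snps = cbind(snps, data.frame(locus_id = character(),
                                    locus_kind = character())),
      loci = data.frame(locus_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        n_snps = integer(), kind = character(),
                        stringsAsFactors = FALSE)))
  }
  ## single-linkage groups: split where the gap to the previous SNP on the
  ## same chromosome exceeds the window
  new_group <- c(TRUE, diff(snps$pos) > window_bp |
                   snps$chrom[-1] != snps$chrom[-nrow(snps)])
  grp <- cumsum(new_group)
  locus_kind <- character(nrow(snps))
  locus_id <- character(nrow(snps))
  loci <- list()
  for (gidx in unique(grp)) {
    idx <- which(grp == gidx)
    pos <- snps$pos[idx]
    neighbors <- vapply(pos, function(p) sum(abs(pos - p) <= window_bp) - 1L,
                        integer(1))
    gid <- sprintf("%s:%d-%d", snps$chrom[idx[1]], min(pos), max(pos))
    if (any(neighbors > min_neighbors)) {
      locus_kind[idx] <- "clustered"
      locus_id[idx] <- gid
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = gid, chrom = snps$chrom[idx[1]],
        start = min(pos), end = max(pos), n_snps = length(idx),
        kind = "clustered", stringsAsFactors = FALSE)
    } else {
      for (i in idx) {
        sid <- sprintf("%s:%d", snps$chrom[i], snps$pos[i])
        locus_kind[i] <- "singleton"
        locus_id[i] <- sid
        loci[[length(loci) + 1L]] <- data.frame(
          locus_id = sid, chrom = snps$chrom[i],
          start = snps$pos[i], end = snps$pos[i], n_snps = 1L,
          kind = "singleton", group_id = gid, stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_along(loci)) {
    if (is.null(loci[[i]]$group_id)) loci[[i]]$group_id <- loci[[i]]$locus_id
  }
  snps$locus_id <- locus_id
  snps$locus_kind <- locus_kind
  list(snps = snps, loci = do.call(rbind, loci))
}

#' Select SNPs replicated across two cohorts
#'
#' A (phenotype, SNP) result is selected iff the combined-cohort p-value is
#' below `combined_max` and both per-cohort p-values are below `cohort_max`.
#' Concordance of the beta sign across the three analyses is reported
#' alongside.
#'
#' @param combined,pop1,pop2 Association result data frames sharing
#'   `phenotype`, `snp_id`, `beta` and a p-value column.
#' @param combined_max Combined p threshold (default 1e-5, exclusive).
#' @param cohort_max Per-cohort p threshold (default 0.05, exclusive).
#' @param p_col Which p-value column to use (default `"wald_p"`).
#' @return Data frame keyed by (`phenotype`, `snp_id`) with the three betas
#'   and p-values, `selected` and `beta_sign_concordant`.
#' @export
replication_select <- function(combined, pop1, pop2, combined_max = 1e-5,
                               cohort_max = 0.05, p_col = "wald_p") {
  key <- function(d) paste(d$phenotype, d$snp_id, sep = "\r")
  kc <- key(combined)
  k1 <- key(pop1)
  k2 <- key(pop2)
  if (!setequal(kc, k1) || !setequal(kc, k2)) {
    stop_eafg("replication_select: cohort results do not share ",
              "(phenotype, snp_id) keys")
  }
  i1 <- match(kc, k1)
  i2 <- match(kc, k2)
  out <- data.frame(
    phenotype = combined$phenotype, snp_id = combined$snp_id,
    beta_combined = combined$beta, p_combined = combined[[p_col]],
    beta_pop1 = pop1$beta[i1], p_pop1 = pop1[[p_col]][i1],
    beta_pop2 = pop2$beta[i2], p_pop2 = pop2[[p_col]][i2],
    stringsAsFactors = FALSE)
  out$selected <- !is.na(out$p_combined) & !is.na(out$p_pop1) &
    !is.na(out$p_pop2) & out$p_combined < combined_max &
    out$p_pop1 < cohort_max & out$p_pop2 < cohort_max
  s <- sign(out$beta_combined)
  out$beta_sign_concordant <- !is.na(s) & s != 0 &
    sign(out$beta_pop1) == s & sign(out$beta_pop2) == s
  out
}

#' Plain Manhattan plot of association results
#'
#' @param results Association results for one phenotype.
#' @param path PNG output path.
#' @param significant_max,suggestive_max Tier thresholds drawn as lines.
#' @return `path`, invisibly.
#' @export
manhattan_plot <- function(results, path, significant_max = 5e-8,
                           suggestive_max = 1e-5) {
  r <- results[!is.na(results$wald_p), , drop = FALSE]
  r <- r[order(r$chrom, r$pos), , drop = FALSE]
  png(path, width = 900, height = 400)
  on.exit(dev.off())
  chrom <- factor(r$chrom, levels = unique(r$chrom))
  plot(seq_len(nrow(r)), -log10(r$wald_p),
       col = (as.integer(chrom) %% 2) + 1, pch = 20,
       xlab = "SNP (genome order)", ylab = "-log10 p", xaxt = "n",
       main = unique(r$phenotype)[1])
  abline(h = -log10(significant_max), col = "red", lty = 2)
  abline(h = -log10(suggestive_max), col = "blue", lty = 3)
  invisible(path)
}

#' Plain QQ plot of association p-values
#'
#' @param p Vector of p-values.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
qq_plot <- function(p, path) {
  p <- sort(p[!is.na(p)])
  exp_p <- (seq_along(p) - 0.5) / length(p)
  png(path, width = 450, height = 450)
  on.exit(dev.off())
  plot(-log10(exp_p), -log10(p), pch = 20,
       xlab = "expected -log10 p", ylab = "observed -log10 p")
  abline(0, 1, col = "red")
  invisible(path)
}
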