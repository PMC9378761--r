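#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: given the observed number of
#' minor alleles, the probability of every attainable heterozygote count `h`
#' (same parity as the minor-allele count) is computed from the exact
#' conditional distribution, and the p-value is the sum of the probabilities
#' of all configurations no more probable than the observed one. The
#' probabilities are built by the numerically stable ratio recurrence
#' `P(h+2)/P(h) = (nA - h)(na - h) / ((h + 2)(h + 1))` in log space, then
#' normalized. A monomorphic SNP has a single
#' attainable configuration and p = 1. `midp = TRUE` subtracts half the
#' observed configuration's probability (mid-p variant); the standard
#' p-value is the default.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote). Vectorized.
#' @param midp Use the mid-p variant (default `FALSE`).
#' @return p-value(s) in (0, 1]; invariant under allele-label swap.
#' @examples
#' hwe_exact(25, 50, 25)
#' hwe_exact(5, 0, 5)   # strong heterozygote deficit
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  if (length(n_AA) > 1L || length(n_Aa) > 1L || length(n_aa) > 1L) {
    n <- max(length(n_AA), length(n_Aa), length(n_aa))
    return(vapply(seq_len(n), function(i) {
      hwe_exact(rep_len(n_AA, n)[i], rep_len(n_Aa, n)[i],
                rep_len(n_aa, n)[i], midp = midp)
    }, numeric(1)))
  }
  counts <- c(n_AA, n_Aa, n_aa)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop_eafg("hwe_exact: counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) stop_eafg("hwe_exact: no called genotypes")
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # minor allele count
  if (n_minor == 0) return(1)
  hs <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  hs <- hs[hs <= n_minor & (n_minor - hs) %% 2L == 0L &
             (2L * n - n_minor - hs) >= 0L]
  ## unnormalized log-probabilities via the ratio recurrence from the lowest
  ## attainable h, shifted by the running maximum before exponentiating
  nmaj <- 2L * n - n_minor
  log_ratio <- function(h) {
    ## log P(h+2) - log P(h)
    log((n_minor - h) * (nmaj - h)) - log((h + 2) * (h + 1))
  }
  k <- length(hs)
  lp <- numeric(k)
  if (k > 1) {
    for (i in seq_len(k - 1)) lp[i + 1] <- lp[i] + log_ratio(hs[i])
  }
  lp <- lp - max(lp)
  p_all <- exp(lp)
  p_all <- p_all / sum(p_all)
  obs <- match(n_Aa, hs)
  if (is.na(obs)) stop_eafg("hwe_exact: inconsistent genotype counts")
  p_obs <- p_all[obs]
  p <- sum(p_all[p_all <= p_obs * (1 + 1e-10)])
  if (midp) p <- p - p_obs / 2
  min(max(p, .Machine$double.xmin), 1)
}

#' Per-SNP genotype statistics
#'
#' Call rate, genotype counts, minor-allele frequency among called genotypes
#' and the exact Hardy-Weinberg p-value for every SNP of a genotype matrix.
#'
#' @param geno Genotype container (list with `genotypes`, `variants`) or a
#'   samples x SNPs dosage matrix with values 0/1/2/NA.
#' @return Data frame with one row per SNP: `snp_id`, `n_samples`,
#'   `n_called`, `call_rate`, `n_AA`, `n_Aa`, `n_aa`, `maf`, `hwe_p`,
#'   `computable`.
#' @export
variant_stats <- function(geno) {
  g <- if (is.list(geno)) geno$genotypes else geno
  if (is.null(dim(g))) g <- matrix(g, ncol = 1)
  if (!all(g %in% c(0L, 1L, 2L, NA))) {
    stop_eafg("dosages must be 0, 1, 2 or NA")
  }
  n_samples <- nrow(g)
  n_AA <- colSums(g == 0L, na.rm = TRUE)
  n_Aa <- colSums(g == 1L, na.rm = TRUE)
  n_aa <- colSums(g == 2L, na.rm = TRUE)
  n_called <- n_AA + n_Aa + n_aa
  f <- ifelse(n_called > 0, (n_Aa + 2 * n_aa) / (2 * n_called), NA_real_)
  maf <- pmin(f, 1 - f)
  hwe_p <- rep(NA_real_, ncol(g))
  ok <- n_called > 0
  if (any(ok)) hwe_p[ok] <- hwe_exact(n_AA[ok], n_Aa[ok], n_aa[ok])
  ids <- colnames(g) %||% paste0("snp", seq_len(ncol(g)))
  data.frame(snp_id = ids, n_samples = n_samples, n_called = n_called,
             call_rate = n_called / n_samples,
             n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
             maf = maf, hwe_p = hwe_p, computable = ok,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter SNPs on call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Retains a SNP iff `call_rate >= call_rate_min` and `maf >= maf_min`
#' (inclusive bounds) and `hwe_p > hwe_p_min` (strict bound). SNPs with no
#' called genotypes fail as uncomputable. Every exclusion is logged with its
#' reasons.
#'
#' @param stats Data frame from [variant_stats()].
#' @param call_rate_min Minimum call rate (default 0.98).
#' @param maf_min Minimum minor-allele frequency (default 0.10).
#' @param hwe_p_min Hardy-Weinberg p-value floor, exclusive (default 1e-4).
#' @return `stats` with added columns `pass` (logical) and `fail_reason`
#'   (comma-joined, `""` for retained SNPs).
#' @export
filter_variants <- function(stats, call_rate_min = 0.98, maf_min = 0.10,
                            hwe_p_min = 1e-4) {
  reasons <- vector("list", nrow(stats))
  for (i in seq_len(nrow(stats))) {
    r <- character()
    if (!stats$computable[i]) {
      r <- "uncomputable"
    } else {
      if (stats$call_rate[i] < call_rate_min) r <- c(r, "call_rate")
      if (stats$maf[i] < maf_min) r <- c(r, "maf")
      if (stats$hwe_p[i] <= hwe_p_min) r <- c(r, "hwe")
    }
    reasons[[i]] <- r
  }
  stats$pass <- lengths(reasons) == 0L
  stats$fail_reason <- vapply(reasons, paste, "", collapse = ",")
  stats
}
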