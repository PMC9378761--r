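#' Modal-pattern concordance between two cohorts
#'
#' Compares two pattern frequency tables (see [pattern_table()]): for each
#' phenotype, do the two cohorts agree on the most frequent growth pattern?
#' Modal ties are broken toward the lower code and flagged. The headline
#' statistic is the fraction of phenotypes whose modal pattern replicates;
#' a per-phenotype chi-square distance between the two distributions is
#' reported alongside but does not enter the fraction. Counts and
#' proportions give identical reports, and swapping the cohorts only swaps
#' the column labels.
#'
#' @param table1,table2 Pattern frequency tables sharing the phenotype set.
#' @return List with `per_phenotype` (data frame: `phenotype`,
#'   `modal_code_1`, `modal_code_2`, `tied_1`, `tied_2`, `agree`,
#'   `chisq_stat`) and scalars `n_agree`, `n_phenotypes`, `fraction_agree`.
#' @export
modal_concordance <- function(table1, table2) {
  if (!setequal(table1$phenotype, table2$phenotype)) {
    stop_eafg("modal_concordance: cohorts do not share the phenotype set")
  }
  t2 <- table2[match(table1$phenotype, table2$phenotype), , drop = FALSE]
  cnt_cols <- paste0("code", 1:5)
  chisq_stat <- numeric(nrow(table1))
  for (i in seq_len(nrow(table1))) {
    m <- rbind(as.numeric(table1[i, cnt_cols]), as.numeric(t2[i, cnt_cols]))
    keep <- colSums(m) > 0
    if (sum(keep) > 1 && all(rowSums(m) > 0)) {
      ## proportions-based statistic so counts and scaled counts agree
      p1 <- m[1, keep] / sum(m[1, ])
      p2 <- m[2, keep] / sum(m[2, ])
      pbar <- (p1 + p2) / 2
      chisq_stat[i] <- sum((p1 - pbar)^2 / pbar) + sum((p2 - pbar)^2 / pbar)
    } else {
      chisq_stat[i] <- NA_real_
    }
  }
  per <- data.frame(
    phenotype = table1$phenotype,
    modal_code_1 = table1$modal_code, modal_code_2 = t2$modal_code,
    tied_1 = table1$modal_tied, tied_2 = t2$modal_tied,
    agree = table1$modal_code == t2$modal_code,
    chisq_stat = chisq_stat,
    stringsAsFactors = FALSE)
  n_agree <- sum(per$agree, na.rm = TRUE)
  n_phen <- sum(!is.na(per$agree))
  list(per_phenotype = per, n_agree = n_agree, n_phenotypes = n_phen,
       fraction_agree = if (n_phen > 0) n_agree / n_phen else NA_real_)
}
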