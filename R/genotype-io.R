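## Genotype container: a list with
##   genotypes: integer matrix, samples x SNPs, entries 0/1/2 (ALT dosage)
##              with NA for missing; dimnames = (sample ids, snp ids)
##   variants:  data.frame(snp_id, chrom, pos, ref, alt)
## Only biallelic, unphased GT-only records are supported -- the subset the
## pipeline itself emits.

new_genotypes <- function(genotypes, variants) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == nrow(variants))
  stopifnot(all(c("snp_id", "chrom", "pos", "ref", "alt") %in%
                  names(variants)))
  stopifnot(all(genotypes %in% c(0L, 1L, 2L, NA)))
  list(genotypes = genotypes, variants = variants)
}

#' Write a genotype matrix as a minimal VCF (v4.2, GT only)
#'
#' Biallelic sites, unphased genotypes, missing entries written as `./.`.
#'
#' @param geno Genotype container (see [gen_genotypes()]).
#' @param path Output `.vcf` path (uncompressed text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  g <- geno$genotypes
  v <- geno$variants
  samples <- rownames(g)
  gt_map <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=eafg",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(g))) {
    gt <- ifelse(is.na(g[, j]), "./.", gt_map[g[, j] + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$snp_id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Parses the GT-only biallelic VCF subset written by [write_vcf()] (also
#' accepts phased separators). Dosage counts ALT alleles; `./.` is missing.
#'
#' @param path VCF file (uncompressed text).
#' @return Genotype container: `genotypes` matrix + `variants` data frame.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_eafg("not a VCF: no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(new_genotypes(
      matrix(integer(), nrow = length(samples), ncol = 0,
             dimnames = list(samples, NULL)),
      data.frame(snp_id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character(),
                 stringsAsFactors = FALSE)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9 + length(samples))) {
    stop_eafg("malformed VCF record(s) at line(s) ",
              paste(utils::head(hdr[1] + which(nf != 9 + length(samples)), 5),
                    collapse = ", "))
  }
  m <- do.call(rbind, fields)
  if (any(grepl(",", m[, 5], fixed = TRUE))) {
    stop_eafg("multi-allelic records are not supported")
  }
  fmt1 <- vapply(strsplit(m[, 9], ":", fixed = TRUE), `[`, "", 1L)
  if (any(fmt1 != "GT")) stop_eafg("FORMAT must lead with GT")
  gt <- m[, -(1:9), drop = FALSE]
  gt <- sub(":.*$", "", gt)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
             ".|." = NA_integer_, "." = NA_integer_)
  bad <- !(gt %in% names(known))
  if (any(bad)) {
    stop_eafg("unsupported GT value(s): ",
              paste(utils::head(unique(gt[bad]), 5), collapse = ", "))
  }
  dose[] <- known[gt]
  genotypes <- t(dose)
  dimnames(genotypes) <- list(samples, m[, 3])
  variants <- data.frame(snp_id = m[, 3], chrom = m[, 1],
                         pos = as.integer(m[, 2]), ref = m[, 4], alt = m[, 5],
                         stringsAsFactors = FALSE)
  new_genotypes(genotypes, variants)
}

#' Write genotypes as PLINK-style text (.ped + .map)
#'
#' Classic whitespace-delimited pedigree format: family and individual id
#' (both the sample id), founder parents, unknown sex, missing phenotype,
#' then two allele columns per SNP with `0 0` for missing.
#'
#' @param geno Genotype container.
#' @param prefix Output prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_ped_map <- function(geno, prefix) {
  g <- geno$genotypes
  v <- geno$variants
  map <- data.frame(chrom = v$chrom, snp_id = v$snp_id, cm = 0, pos = v$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  allele_pairs <- function(dose, ref, alt) {
    out <- matrix("0", nrow = length(dose), ncol = 2)
    out[!is.na(dose) & dose == 0L, ] <- ref
    out[!is.na(dose) & dose == 1L, 1] <- ref
    out[!is.na(dose) & dose == 1L, 2] <- alt
    out[!is.na(dose) & dose == 2L, ] <- alt
    out
  }
  cols <- vector("list", ncol(g))
  for (j in seq_len(ncol(g))) {
    cols[[j]] <- allele_pairs(g[, j], v$ref[j], v$alt[j])
  }
  ped <- cbind(rownames(g), rownames(g), "0", "0", "0", "-9",
               do.call(cbind, cols))
  write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK-style .ped/.map text genotypes
#'
#' @param prefix Path prefix of `<prefix>.ped` and `<prefix>.map`.
#' @param ref,alt Optional explicit REF/ALT alleles per SNP; by default the
#'   two observed alleles are taken with the lexicographically smaller as REF
#'   (monomorphic SNPs get alt `"N"`), and dosage counts the ALT allele.
#' @return Genotype container.
#' @export
read_ped_map <- function(prefix, ref = NULL, alt = NULL) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    stringsAsFactors = FALSE)
  names(map) <- c("chrom", "snp_id", "cm", "pos")[seq_len(ncol(map))]
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp) {
    stop_eafg(".ped column count does not match .map (expected ",
              6 + 2 * n_snp, ", got ", ncol(ped), ")")
  }
  samples <- ped[[2]]
  g <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_snp,
              dimnames = list(samples, map$snp_id))
  refs <- character(n_snp)
  alts <- character(n_snp)
  for (j in seq_len(n_snp)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    obs <- setdiff(sort(unique(c(a1, a2))), "0")
    if (length(obs) > 2) {
      stop_eafg("SNP ", map$snp_id[j], " has more than two alleles")
    }
    rj <- if (!is.null(ref)) ref[j] else if (length(obs) >= 1) obs[1] else "N"
    aj <- if (!is.null(alt)) alt[j] else
      if (length(obs) == 2) obs[2] else "N"
    miss <- a1 == "0" | a2 == "0"
    d <- (a1 == aj) + (a2 == aj)
    d[miss] <- NA_integer_
    g[, j] <- as.integer(d)
    refs[j] <- rj
    alts[j] <- aj
  }
  variants <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                         pos = map$pos, ref = refs, alt = alts,
                         stringsAsFactors = FALSE)
  new_genotypes(g, variants)
}
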