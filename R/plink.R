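# PLINK text (.ped/.map) import/export. Text format chosen for
# inspectability at desk scale; alleles are coded 1/2, "0 0" = missing,
# and the dosage is the count of allele 2. Base-pair positions follow the
# 1 cM = 1 Mb convention.

#' Write genotypes as PLINK text files
#'
#' @param genotypes individuals x markers allele-count matrix (0/1/2, `NA`
#'   = missing), rownames ids.
#' @param genome a [build_genome()] map supplying marker chromosome and
#'   position.
#' @param prefix output path prefix (writes `<prefix>.ped` and
#'   `<prefix>.map`).
#' @param pedigree optional pedigree data frame to fill the family columns
#'   (`sire`, `dam`, `sex`); unknown fields are written as 0.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(genotypes, genome, prefix, pedigree = NULL) {
  mk <- genome$markers
  if (ncol(genotypes) != nrow(mk))
    stop("genotype columns must match the genome's markers", call. = FALSE)
  map <- data.frame(chrom = mk$chrom,
                    snp = sprintf("snp%d", seq_len(nrow(mk))),
                    cM = mk$pos_cM,
                    bp = as.integer(round(mk$pos_cM * 1e6)))
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(genotypes)))
  sire <- dam <- rep("0", length(ids)); sexcode <- rep("0", length(ids))
  if (!is.null(pedigree)) {
    i <- match(ids, pedigree$id)
    sire <- ifelse(is.na(i) | is.na(pedigree$sire[i]), "0", pedigree$sire[i])
    dam <- ifelse(is.na(i) | is.na(pedigree$dam[i]), "0", pedigree$dam[i])
    sexcode <- ifelse(is.na(i), "0",
                      c(M = "1", F = "2")[pedigree$sex[i]])
    sexcode[is.na(sexcode)] <- "0"
  }
  a1 <- matrix("1", nrow(genotypes), ncol(genotypes))
  a2 <- matrix("1", nrow(genotypes), ncol(genotypes))
  a1[genotypes >= 1] <- "2"
  a2[genotypes == 2] <- "2"
  a1[is.na(genotypes)] <- "0"; a2[is.na(genotypes)] <- "0"
  inter <- matrix("", nrow(genotypes), 2 * ncol(genotypes))
  inter[, seq(1, 2 * ncol(genotypes), 2)] <- a2  # allele-2 count = dosage
  inter[, seq(2, 2 * ncol(genotypes), 2)] <- a1
  lines <- paste("FAM", ids, sire, dam, sexcode, "-9",
                 apply(inter, 1, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PLINK text files into an allele-count matrix
#'
#' @param prefix path prefix of a `.ped`/`.map` pair.
#' @return list with `genotypes` (allele-2 counts, `NA` for the 0/0
#'   missing code, rownames = individual ids) and `map` (data frame:
#'   `chrom`, `snp`, `cM`, `bp`).
#' @export
read_plink <- function(prefix) {
  map_path <- paste0(prefix, ".map"); ped_path <- paste0(prefix, ".ped")
  map <- read.table(map_path, sep = "\t", col.names = c("chrom", "snp",
                                                        "cM", "bp"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  geno <- matrix(NA_integer_, length(lines), m)
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop(sprintf(
        "%s line %d: %d genotype fields, expected %d (map has %d markers)",
        basename(ped_path), i, length(f) - 6, 2 * m, m), call. = FALSE)
    ids[i] <- f[2]
    al <- matrix(f[-(1:6)], ncol = 2, byrow = TRUE)
    miss <- al[, 1] == "0" | al[, 2] == "0"
    d <- (al[, 1] == "2") + (al[, 2] == "2")
    d[miss] <- NA_integer_
    geno[i, ] <- d
  }
  rownames(geno) <- ids
  list(genotypes = geno, map = map)
}
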