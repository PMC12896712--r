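# Tab-separated study artefacts with provenance headers.

provenance_header <- function(stage, seed = NA, config_md5 = NA) {
  sprintf("# crosspopgs stage=%s seed=%s config_md5=%s", stage,
          as.character(seed), as.character(config_md5))
}

write_tsv <- function(df, path, stage, seed = NA, config_md5 = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(stage, seed, config_md5), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write a simulated study to a directory
#'
#' Writes PLINK text genotypes of the genotyped generations, pedigree,
#' phenotype, true-breeding-value and QTL-effect tables; every table
#' carries a provenance comment line (producing stage, seed, config hash).
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @param config_md5 optional configuration hash recorded in the headers.
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir, config_md5 = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- study$seed %||% NA
  gen_ids <- study$pedigree$id[study$pedigree$generation %in%
                                 study$genotyped_generations]
  write_plink(study$genotypes[gen_ids, , drop = FALSE], study$genome,
              file.path(dir, paste0("pop", study$population)),
              pedigree = study$pedigree)
  write_tsv(study$pedigree, file.path(dir, "pedigree.tsv"),
            "simulate", seed, config_md5)
  write_tsv(data.frame(id = names(study$phenotype),
                       y = unname(study$phenotype),
                       fixed_level = 1L),
            file.path(dir, "phenotypes.tsv"), "simulate", seed, config_md5)
  write_tsv(data.frame(id = names(study$tbv), tbv = unname(study$tbv)),
            file.path(dir, "tbv.tsv"), "simulate", seed, config_md5)
  write_tsv(data.frame(qtl = seq_along(study$architecture$beta),
                       chrom = study$genome$qtl$chrom,
                       pos_cM = study$genome$qtl$pos_cM,
                       beta = study$architecture$beta),
            file.path(dir, "qtl_effects.tsv"), "simulate", seed, config_md5)
  invisible(dir)
}

#' Read back the tabular parts of a written study
#'
#' @param dir directory written by [write_study()].
#' @param population population label used in the PLINK prefix.
#' @return list with `genotypes`, `map`, `pedigree`, `phenotype`, `tbv`.
#' @export
read_study <- function(dir, population = "A") {
  pl <- read_plink(file.path(dir, paste0("pop", population)))
  ped <- read_tsv(file.path(dir, "pedigree.tsv"))
  ph <- read_tsv(file.path(dir, "phenotypes.tsv"))
  tb <- read_tsv(file.path(dir, "tbv.tsv"))
  list(genotypes = pl$genotypes, map = pl$map, pedigree = ped,
       phenotype = setNames(ph$y, ph$id), tbv = setNames(tb$tbv, tb$id))
}
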