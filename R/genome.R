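#' Build a genome map with uniformly placed markers and QTL
#'
#' Lays out `n_chromosomes` autosomes whose map lengths sum to
#' `total_length`, then scatters neutral biallelic markers and QTL uniformly
#' at random along them. The default dimensions mirror a 29-autosome bovine
#' genome of 2715.85 cM carrying 50,000 SNP markers and 725 QTL. Marker and
#' QTL counts are apportioned to chromosomes in proportion to map length by
#' the largest-remainder rule, so longer chromosomes carry proportionally
#' more loci. Relative chromosome lengths taper linearly from about 1.6 to
#' 0.45 times the mean, approximating the size gradient of real livestock
#' autosomes.
#'
#' @param n_chromosomes number of autosomes.
#' @param total_length total map length in centimorgans.
#' @param n_markers number of neutral SNP markers (>= 1).
#' @param n_qtl number of QTL (>= 1).
#' @param seed optional integer seed; the same seed reproduces the same map.
#' @return an object of class `genome_map`: a list with elements
#'   `chromosomes` (data frame: `chrom`, `length_cM`), `markers` and `qtl`
#'   (data frames: `chrom`, `pos_cM`, sorted within chromosome) and
#'   `total_length`.
#' @examples
#' g <- build_genome(5, 500, n_markers = 200, n_qtl = 20, seed = 1)
#' g
#' @export
build_genome <- function(n_chromosomes = 29, total_length = 2715.85,
                         n_markers = 50000, n_qtl = 725, seed = NULL) {
  if (n_chromosomes < 1 || total_length <= 0 || n_markers < 1 || n_qtl < 1)
    stop("chromosome/marker/QTL counts must be positive and total_length > 0",
         call. = FALSE)
  local_seed(seed)
  w <- if (n_chromosomes == 1) 1
       else seq(1.6, 0.45, length.out = n_chromosomes)
  len <- w / sum(w) * total_length
  chromosomes <- data.frame(chrom = seq_len(n_chromosomes), length_cM = len)

  place <- function(n_total) {
    n_chr <- largest_remainder(n_total, len)
    chrom <- rep.int(seq_len(n_chromosomes), n_chr)
    pos <- runif(n_total) * rep.int(len, n_chr)
    ord <- order(chrom, pos)
    data.frame(chrom = chrom[ord], pos_cM = pos[ord])
  }
  out <- list(chromosomes = chromosomes,
              markers = place(n_markers),
              qtl = place(n_qtl),
              total_length = total_length)
  class(out) <- "genome_map"
  out
}

# Apportion `n` items to bins proportionally to `weights` (largest remainder,
# ties to the earlier bin).
largest_remainder <- function(n, weights) {
  q <- n * weights / sum(weights)
  k <- floor(q)
  left <- n - sum(k)
  if (left > 0) {
    extra <- order(q - k, decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

#' @export
#' @method print genome_map
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes, %.2f cM, %d markers, %d QTL\n",
              nrow(x$chromosomes), x$total_length,
              nrow(x$markers), nrow(x$qtl)))
  invisible(x)
}

# Combined locus table in simulation storage order (chromosome, position).
# Returns 0-based chromosome column ranges for the C++ meiosis kernel plus
# index maps back to marker and QTL columns.
genome_loci <- function(genome) {
  m <- genome$markers
  q <- genome$qtl
  loci <- rbind(
    data.frame(chrom = m$chrom, pos_cM = m$pos_cM, type = "marker",
               idx = seq_len(nrow(m))),
    data.frame(chrom = q$chrom, pos_cM = q$pos_cM, type = "qtl",
               idx = seq_len(nrow(q))))
  loci <- loci[order(loci$chrom, loci$pos_cM), , drop = FALSE]
  rownames(loci) <- NULL
  n_chr <- nrow(genome$chromosomes)
  first <- last <- integer(n_chr)
  for (c in seq_len(n_chr)) {
    rows <- which(loci$chrom == c)
    first[c] <- if (length(rows)) rows[1] - 1L else 0L
    last[c] <- if (length(rows)) rows[length(rows)] - 1L else -1L
  }
  list(loci = loci,
       chr_first = first, chr_last = last,
       chr_len = genome$chromosomes$length_cM,
       marker_cols = which(loci$type == "marker"),
       qtl_cols = which(loci$type == "qtl"))
}
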