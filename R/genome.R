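#' Construct a genome build
#'
#' A genome build holds the ordered chromosome set of a reference assembly:
#' name, physical length in bp, optionally the DNA sequence, and a uniform
#' genetic-map density used to convert physical position to genetic distance.
#' The uniform cM/Mb map is the minimal model needed to simulate
#' recombination; real C. elegans maps are non-uniform, which is out of scope
#' here.
#'
#' @param chromosomes A data frame with columns `name` and `length`, and
#'   optionally `sequence` (DNA string of exactly `length` characters, or
#'   `NA`). Row order is preserved as chromosome order.
#' @param cm_per_mb Genetic-map density in centimorgans per megabase
#'   (constant per chromosome). Default 5, a round figure of the right order
#'   for C. elegans autosome averages.
#' @return An object of class `genome_build`: a list with elements
#'   `chromosomes` (tibble) and `cm_per_mb`.
#' @examples
#' genome_build(data.frame(name = c("chrI", "chrII"), length = c(2e6, 1e6)))
#' @export
genome_build <- function(chromosomes, cm_per_mb = 5) {
  chromosomes <- as_tibble(chromosomes)
  if (!all(c("name", "length") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns `name` and `length`")
  }
  if (!"sequence" %in% names(chromosomes)) chromosomes$sequence <- NA_character_
  chromosomes <- chromosomes[, c("name", "length", "sequence")]
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (nrow(chromosomes) == 0) abort("genome must have at least one chromosome")
  if (anyDuplicated(chromosomes$name)) {
    abort("duplicate chromosome names in genome")
  }
  if (any(chromosomes$length < 1)) abort("chromosome lengths must be >= 1 bp")
  has_seq <- !is.na(chromosomes$sequence)
  if (any(nchar(chromosomes$sequence[has_seq]) != chromosomes$length[has_seq])) {
    abort("sequence length disagrees with declared chromosome length")
  }
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1 || cm_per_mb <= 0) {
    abort("`cm_per_mb` must be a single positive number")
  }
  structure(list(chromosomes = chromosomes, cm_per_mb = cm_per_mb),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", nrow(x$chromosomes), " chromosome(s), ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp total, ",
      x$cm_per_mb, " cM/Mb\n", sep = "")
  print(x$chromosomes[, c("name", "length")])
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) abort(paste0("unknown chromosome: ", chrom[which(is.na(i))[1]]))
  genome$chromosomes$length[i]
}

chrom_seq <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (is.na(i)) abort(paste0("unknown chromosome: ", chrom))
  s <- genome$chromosomes$sequence[i]
  if (is.na(s)) abort(paste0("chromosome ", chrom, " has no sequence"))
  s
}

genome_has_sequence <- function(genome) {
  all(!is.na(genome$chromosomes$sequence))
}

#' Read a genome from FASTA
#'
#' One chromosome per FASTA record; record order is preserved. Only the first
#' whitespace-delimited token of each header is used as the chromosome name.
#'
#' @param path Path to a FASTA file.
#' @inheritParams genome_build
#' @return A [genome_build()] with sequences attached.
#' @export
read_genome <- function(path, cm_per_mb = 5) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort("FASTA file contains no records")
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) abort("duplicate record names in FASTA")
  genome_build(
    tibble(name = nm, length = Biostrings::width(seqs),
           sequence = unname(as.character(seqs))),
    cm_per_mb = cm_per_mb
  )
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_build()] with sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (!genome_has_sequence(genome)) abort("genome has no sequences to write")
  seqs <- Biostrings::DNAStringSet(genome$chromosomes$sequence)
  names(seqs) <- genome$chromosomes$name
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Convert physical position to genetic position
#'
#' Under the uniform map, genetic position is `pos / 1e6 * cm_per_mb` cM from
#' the left end of the chromosome; it is linear and strictly increasing in
#' `pos`.
#'
#' @param genome A [genome_build()].
#' @param chrom Chromosome name (recycled against `pos`).
#' @param pos 1-based physical position(s), bp.
#' @return Genetic position(s) in cM.
#' @examples
#' g <- genome_build(data.frame(name = "chrI", length = 2e6))
#' pos_to_cm(g, "chrI", 1e6)  # 5 cM at the default 5 cM/Mb
#' @export
pos_to_cm <- function(genome, chrom, pos) {
  len <- chrom_length(genome, chrom)
  if (any(pos < 0 | pos > len)) abort("position outside chromosome")
  pos / 1e6 * genome$cm_per_mb
}

#' Generate a random toy genome
#'
#' Utility for simulations and tests: i.i.d. uniform A/C/G/T sequence on each
#' chromosome. For large genotype-level simulations, pass `with_sequence =
#' FALSE`; sequence is only needed by [mutagenize()] and [annotate_variants()].
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome, bp.
#' @param with_sequence Generate sequence? Default `TRUE`.
#' @inheritParams genome_build
#' @return A [genome_build()].
#' @export
random_genome <- function(n_chrom = 5, chrom_length = 1e6,
                          with_sequence = TRUE, cm_per_mb = 5) {
  nm <- paste0("chr", utils::as.roman(seq_len(n_chrom)))
  seqs <- if (with_sequence) {
    vapply(seq_len(n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
            collapse = "")
    }, character(1))
  } else {
    rep(NA_character_, n_chrom)
  }
  genome_build(tibble(name = nm, length = rep(chrom_length, n_chrom),
                      sequence = seqs),
               cm_per_mb = cm_per_mb)
}
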