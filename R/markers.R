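#' Read a mapping-strain marker map from VCF
#'
#' The marker map catalogs the known SNVs distinguishing the mapping strain
#' (e.g. the Hawaiian isolate CB4856) from the laboratory background; REF is
#' the laboratory allele, ALT the mapping-strain allele. Only biallelic SNV
#' records are kept; indels and multiallelic records are skipped and counted,
#' never silently dropped. Unsorted input is sorted with a warning.
#'
#' @param path Path to a VCF 4.2 file.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `map_allele`, sorted
#'   and unique on (chrom, pos), with attribute `skipped` = number of
#'   non-SNV records dropped.
#' @export
read_marker_map <- function(path) {
  tbl <- read_vcf_table(path)
  keep <- is_biallelic_snv(tbl$ref, tbl$alt)
  skipped <- sum(!keep)
  tbl <- tbl[keep, c("chrom", "pos", "ref", "alt")]
  names(tbl)[4] <- "map_allele"
  out <- marker_map(tbl, warn_unsorted = TRUE)
  attr(out, "skipped") <- skipped
  out
}

#' Construct / validate a marker map
#'
#' @param markers Data frame with columns `chrom`, `pos`, `ref`,
#'   `map_allele`.
#' @param warn_unsorted Warn (rather than silently reorder) if input was not
#'   position-sorted.
#' @return A sorted, deduplicated marker tibble of class `marker_map`.
#' @export
marker_map <- function(markers, warn_unsorted = FALSE) {
  markers <- as_tibble(markers)[, c("chrom", "pos", "ref", "map_allele")]
  if (any(markers$ref == markers$map_allele)) {
    abort("marker with ref allele equal to mapping-strain allele")
  }
  srt <- sort_by_chrom_pos(markers)
  if (warn_unsorted && !identical(srt$pos, markers$pos)) {
    warn("marker map was not position-sorted; sorting")
  }
  srt <- distinct(srt, .data$chrom, .data$pos, .keep_all = TRUE)
  class(srt) <- c("marker_map", class(srt))
  srt
}

#' Write a marker map to VCF
#'
#' @param markers A [marker_map()] tibble.
#' @param path Output VCF path.
#' @param genome Optional [genome_build()] for contig header lines.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(markers, path, genome = NULL) {
  header <- vcf_header(genome)
  body <- paste(markers$chrom, as.integer(markers$pos), ".",
                markers$ref, markers$map_allele, ".", "PASS", ".",
                sep = "\t")
  write_vcf_lines(header, body, path)
}

#' Lay out an evenly spaced marker map on a genome
#'
#' Places one marker every `spacing` bp on every chromosome, starting at
#' `spacing`. Marker alleles are taken from the genome sequence when present
#' (ref = reference base, mapping allele = its transition partner), else
#' fixed A/T placeholders; mapping only uses positions and allele depths, so
#' the base identities are immaterial to linkage.
#'
#' @param genome A [genome_build()].
#' @param spacing Marker spacing in bp (default 1e5, i.e. one per 100 kb).
#' @return A [marker_map()] tibble.
#' @export
make_marker_grid <- function(genome, spacing = 1e5) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  per_chrom <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    len <- genome$chromosomes$length[i]
    pos <- seq(spacing, len, by = spacing)
    if (length(pos) == 0) return(NULL)
    if (!is.na(genome$chromosomes$sequence[i])) {
      ref <- vapply(pos, function(p) {
        substr(genome$chromosomes$sequence[i], p, p)
      }, character(1))
      alt <- unname(transition[ref])
    } else {
      ref <- rep("A", length(pos))
      alt <- rep("T", length(pos))
    }
    tibble(chrom = genome$chromosomes$name[i], pos = pos, ref = ref,
           map_allele = alt)
  })
  marker_map(bind_rows(per_chrom))
}

#' Validate genome, gene models and marker map against each other
#'
#' Checks that every marker sits on a known chromosome within its length,
#' that every gene model's chromosome exists and its span fits, and (when
#' sequence is present) that marker ref alleles match the reference base.
#'
#' @param genome A [genome_build()].
#' @param genes Optional list of [gene_model()] objects.
#' @param markers Optional [marker_map()].
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_inputs <- function(genome, genes = NULL, markers = NULL) {
  if (!is.null(markers)) {
    len <- chrom_length(genome, markers$chrom)
    if (any(markers$pos < 1 | markers$pos > len)) {
      abort("marker position outside chromosome")
    }
    if (genome_has_sequence(genome)) {
      base <- ref_base_at(genome, markers$chrom, markers$pos)
      bad <- which(base != markers$ref)
      if (length(bad)) {
        abort(paste0("marker ref mismatch at ", markers$chrom[bad[1]], ":",
                     markers$pos[bad[1]]))
      }
    }
  }
  for (g in genes %||% list()) {
    len <- chrom_length(genome, g$chrom)
    sp <- gene_span(g)
    if (sp[1] < 1 || sp[2] > len) {
      abort(paste0("gene ", g$gene_id, " extends outside ", g$chrom))
    }
  }
  invisible(TRUE)
}

ref_base_at <- function(genome, chrom, pos) {
  i <- match(chrom, genome$chromosomes$name)
  vapply(seq_along(pos), function(k) {
    substr(genome$chromosomes$sequence[i[k]], pos[k], pos[k])
  }, character(1))
}
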