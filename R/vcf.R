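# Internal VCF 4.2 helpers. Reading goes through vcfR; writing is a minimal
# text emitter for the two record shapes the pipeline produces (homozygous
# strain calls with GT, pooled calls with AD/DP) because the pipeline's
# contract is plain-text VCF.

vcf_header <- function(genome = NULL, format_lines = character(),
                       sample = NULL) {
  h <- c("##fileformat=VCFv4.2", "##source=ectamapper")
  if (!is.null(genome)) {
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>",
                      genome$chromosomes$name,
                      as.integer(genome$chromosomes$length)))
  }
  h <- c(h, format_lines)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample)) cols <- c(cols, "FORMAT", sample)
  c(h, paste(cols, collapse = "\t"))
}

write_vcf_lines <- function(header, body, path) {
  writeLines(c(header, body), path)
  invisible(path)
}

sort_by_chrom_pos <- function(tbl, chrom_levels = NULL) {
  ord <- if (is.null(chrom_levels)) {
    order(tbl$chrom, tbl$pos)
  } else {
    order(match(tbl$chrom, chrom_levels), tbl$pos)
  }
  tbl[ord, , drop = FALSE]
}

# read all records of a VCF; returns tibble with chrom,pos,ref,alt plus
# per-sample AD strings when present
read_vcf_table <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                ref = fix$REF, alt = fix$ALT)
  if (ncol(v@gt) >= 2 && any(grepl("AD", v@gt[, "FORMAT"]))) {
    ad <- vcfR::extract.gt(v, element = "AD")
    out$ad <- ad[, 1]
  }
  out
}

is_biallelic_snv <- function(ref, alt) {
  !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}
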