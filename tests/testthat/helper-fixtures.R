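# Programmatic fixtures: everything is generated in code at test time.

# deterministic toy genome with sequence
toy_genome <- function(n_chrom = 2, len = 5e4, seed = 101, cm_per_mb = 5) {
  set.seed(seed)
  random_genome(n_chrom, len, with_sequence = TRUE, cm_per_mb = cm_per_mb)
}

# single-chromosome genome built around an explicit sequence
genome_from_seq <- function(seq, name = "chrI", cm_per_mb = 5) {
  genome_build(tibble::tibble(name = name, length = nchar(seq),
                              sequence = seq),
               cm_per_mb = cm_per_mb)
}

# a forward-strand single-exon gene whose CDS is an explicit codon string,
# embedded at `offset` (0-based) into random flanking sequence
toy_coding_gene <- function(cds_seq, offset = 100, flank = 200, seed = 7,
                            strand = "+", gene_id = "toyA") {
  set.seed(seed)
  n <- offset + nchar(cds_seq) + flank
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  cds_on_genome <- if (strand == "+") {
    cds_seq
  } else {
    # place the reverse complement so the transcribed CDS equals cds_seq
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
  }
  bases[(offset + 1):(offset + nchar(cds_seq))] <-
    strsplit(cds_on_genome, "")[[1]]
  genome <- genome_from_seq(paste(bases, collapse = ""))
  iv <- tibble::tibble(start = offset + 1, end = offset + nchar(cds_seq))
  gene <- gene_model(gene_id, "chrI", strand, exons = iv, cds = iv)
  list(genome = genome, gene = gene)
}

# write a small VCF body with arbitrary records (for parser edge cases)
write_test_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               records), path)
  path
}

# random variant table over a virtual genome
random_variant_tbl <- function(n, chroms = c("chrI", "chrII"), max_pos = 1e5) {
  pos <- sample.int(max_pos, n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE), pos = pos,
                 ref = ref, alt = alt)
}
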