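#' Predicted protein effect of SNVs against gene models
#'
#' Codon-level consequence calling: for each variant and each overlapping
#' transcript, the CDS coordinate is computed by summing exon offsets in
#' transcription order, reverse-strand transcripts use reverse-complemented
#' alleles, and the affected codon is translated with the standard nuclear
#' code. Classes: `intergenic`, `intronic`, `splice_site` (within 2 bp of an
#' intron boundary, overriding `intronic`), `synonymous`, `missense`,
#' `nonsense`, `stop_lost`, `start_lost` (any SNV in the initiator codon).
#' Positions inside a transcript but outside its CDS (UTR exons, genes
#' without CDS) follow the intronic/splice logic. The variant's REF allele
#' is checked against the genome sequence; a mismatch is an error naming the
#' position.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`; extra
#'   columns such as `strain_id` are carried through).
#' @param genes List of [gene_model()] objects.
#' @param genome A [genome_build()] with sequences.
#' @return Tibble with one row per (variant, overlapping transcript) — or a
#'   single `intergenic` row for variants overlapping none — with columns
#'   `chrom`, `pos`, `ref`, `alt`, `gene_id`, `effect_class`,
#'   `protein_change` (present iff the class is coding).
#' @export
annotate_variants <- function(variants, genes, genome) {
  variants <- as_tibble(variants)
  if (!genome_has_sequence(genome)) abort("annotation needs genome sequence")
  if (nrow(variants) > 0) {
    refs <- ref_base_at(genome, variants$chrom, variants$pos)
    bad <- which(refs != variants$ref)
    if (length(bad)) {
      abort(paste0("REF mismatch at ", variants$chrom[bad[1]], ":",
                   variants$pos[bad[1]], " (expected ", refs[bad[1]],
                   ", got ", variants$ref[bad[1]], ")"))
    }
  }
  genes <- genes[order(vapply(genes, function(g) g$gene_id, character(1)))]
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hits <- keep(genes, function(g) {
      sp <- gene_span(g)
      g$chrom == v$chrom && v$pos >= sp[1] && v$pos <= sp[2]
    })
    if (length(hits) == 0) {
      return(mutate(v, gene_id = NA_character_, effect_class = "intergenic",
                    protein_change = NA_character_))
    }
    bind_rows(lapply(hits, function(g) {
      eff <- classify_in_gene(v, g, genome)
      mutate(v, gene_id = g$gene_id, effect_class = eff$class,
             protein_change = eff$protein_change)
    }))
  })
  bind_rows(rows)
}

# consequence of a single SNV within one gene model
classify_in_gene <- function(v, gene, genome) {
  pos <- v$pos
  ex <- gene$exons
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  cds <- gene$cds
  in_cds <- nrow(cds) > 0 && any(pos >= cds$start & pos <= cds$end)
  if (in_cds) {
    return(classify_coding(v, gene, genome))
  }
  if (!in_exon && nrow(ex) > 1) {
    # introns: gaps between consecutive exons
    istart <- ex$end[-nrow(ex)] + 1
    iend <- ex$start[-1] - 1
    for (k in seq_along(istart)) {
      if (pos >= istart[k] && pos <= iend[k]) {
        splice <- pos <= istart[k] + 1 || pos >= iend[k] - 1
        return(list(class = if (splice) "splice_site" else "intronic",
                    protein_change = NA_character_))
      }
    }
  }
  # exonic-but-noncoding (UTR) or single-exon noncoding gene
  list(class = "intronic", protein_change = NA_character_)
}

classify_coding <- function(v, gene, genome) {
  cds <- gene$cds  # ascending genomic order
  lens <- cds$end - cds$start + 1
  cum_before <- cumsum(c(0, lens[-length(lens)]))
  piece <- which(v$pos >= cds$start & v$pos <= cds$end)[1]
  fwd_pos <- cum_before[piece] + (v$pos - cds$start[piece] + 1)
  total <- sum(lens)
  cds_pos <- if (gene$strand == "+") fwd_pos else total - fwd_pos + 1
  cds_seq <- cds_sequence(gene, genome)
  ci <- ceiling(cds_pos / 3)
  within <- ((cds_pos - 1) %% 3) + 1
  codon <- substr(cds_seq, 3 * (ci - 1) + 1, 3 * ci)
  alt_cds <- if (gene$strand == "+") v$alt else dna_complement(v$alt)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_cds
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(alt_codon)
  change <- paste0(ref_aa, ci, alt_aa)
  cls <- if (ci == 1) {
    "start_lost"
  } else if (ref_aa == "*") {
    if (alt_aa == "*") "synonymous" else "stop_lost"
  } else if (alt_aa == "*") {
    "nonsense"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else {
    "missense"
  }
  list(class = cls, protein_change = change)
}

cds_sequence <- function(gene, genome) {
  seqs <- vapply(seq_len(nrow(gene$cds)), function(i) {
    substr(chrom_seq(genome, gene$chrom), gene$cds$start[i], gene$cds$end[i])
  }, character(1))
  s <- paste(seqs, collapse = "")
  if (gene$strand == "-") s <- dna_revcomp(s)
  s
}

dna_complement <- function(x) chartr("ACGT", "TGCA", x)

dna_revcomp <- function(x) {
  paste(rev(strsplit(dna_complement(x), "")[[1]]), collapse = "")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Enumerate every possible SNV in a CDS with its effect class
#'
#' Test/QC oracle generator: all 3 alternative alleles at every CDS
#' position of a complete model, classified with [annotate_variants()].
#'
#' @param gene A complete [gene_model()].
#' @param genome A [genome_build()] with sequence.
#' @return Tibble of `3 x CDS length` rows: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `effect_class`, `protein_change`.
#' @export
enumerate_cds_effects <- function(gene, genome) {
  if (!gene$complete || nrow(gene$cds) == 0) {
    abort("enumerate_cds_effects needs a complete CDS")
  }
  pos <- unlist(lapply(seq_len(nrow(gene$cds)), function(i) {
    seq(gene$cds$start[i], gene$cds$end[i])
  }))
  refs <- ref_base_at(genome, rep(gene$chrom, length(pos)), pos)
  grid <- bind_rows(lapply(seq_along(pos), function(i) {
    ref_i <- refs[i]
    tibble(chrom = gene$chrom, pos = pos[i], ref = ref_i,
           alt = setdiff(c("A", "C", "G", "T"), ref_i))
  }))
  ann <- annotate_variants(grid, list(gene), genome)
  filter(ann, .data$gene_id == gene$gene_id)
}

severity_rank <- c(nonsense = 1, splice_site = 1, start_lost = 1,
                   stop_lost = 1, missense = 2, synonymous = 3,
                   intronic = 4, intergenic = 5)

#' Rank candidate variants inside the mapped interval
#'
#' Keeps annotations whose position falls inside the candidate interval and
#' orders them by predicted severity (nonsense / splice-site / start-lost /
#' stop-lost, then missense, synonymous, intronic, intergenic), stable by
#' position within a severity tier.
#'
#' @param annotated Tibble from [annotate_variants()].
#' @param interval One-row tibble from [candidate_interval()].
#' @return Ranked tibble with a `severity` column; zero rows (with a
#'   message) when nothing falls inside the interval.
#' @export
prioritize_candidates <- function(annotated, interval) {
  hits <- filter(annotated, .data$chrom == interval$chrom,
                 .data$pos >= interval$start, .data$pos <= interval$end)
  hits$severity <- unname(severity_rank[hits$effect_class])
  hits <- arrange(hits, .data$severity, .data$pos)
  if (nrow(hits) == 0) message("no candidate variants inside the interval")
  hits
}
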