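#' Construct a gene model
#'
#' A transcript-level gene model: exon and CDS intervals in 1-based closed
#' genomic coordinates, plus strand. CDS intervals must lie within exons; for
#' a complete model the total CDS length is divisible by 3.
#'
#' @param gene_id Transcript/gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (1-based closed).
#' @param cds Data frame with columns `start`, `end` and optionally `frame`
#'   (0/1/2 phase of the first base of each CDS piece, in transcription
#'   order); frame is recomputed if absent.
#' @param complete Is the model a complete CDS (length divisible by 3,
#'   enforced)? Default `TRUE`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds, complete = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- arrange(as_tibble(exons)[, c("start", "end")], .data$start)
  cds <- as_tibble(cds)
  if (!"frame" %in% names(cds)) cds$frame <- NA_integer_
  cds <- arrange(cds[, c("start", "end", "frame")], .data$start)
  check_intervals <- function(iv, what) {
    if (nrow(iv) == 0) return(invisible())
    if (any(iv$end < iv$start)) abort(paste(what, "interval with end < start"))
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      abort(paste(what, "intervals overlap"))
    }
  }
  check_intervals(exons, "exon")
  check_intervals(cds, "CDS")
  # every CDS piece must sit inside some exon
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    if (!inside) abort(paste0("CDS interval outside exons in ", gene_id))
  }
  cds_len <- sum(cds$end - cds$start + 1)
  if (complete && nrow(cds) > 0 && cds_len %% 3 != 0) {
    abort(paste0("complete model ", gene_id, " has CDS length ", cds_len,
                 ", not divisible by 3"))
  }
  # frame in transcription order: phase of first base of each piece
  if (nrow(cds) > 0 && anyNA(cds$frame)) {
    tx_order <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    lens <- (cds$end - cds$start + 1)[tx_order]
    fr <- cumsum(c(0, lens[-length(lens)])) %% 3
    cds$frame[tx_order] <- as.integer(fr)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, complete = complete),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " ", x$chrom, "(", x$strand, ") ",
      nrow(x$exons), " exon(s), CDS ", sum(x$cds$end - x$cds$start + 1),
      " bp\n", sep = "")
  invisible(x)
}

gene_span <- function(gene) c(min(gene$exons$start), max(gene$exons$end))

#' Read gene models from GFF3
#'
#' Builds one [gene_model()] per mRNA feature, collecting its exon and CDS
#' children by `Parent` attribute. Seqids must exist in the genome; CDS
#' intervals outside exons are an error.
#'
#' @param path Path to a GFF3 file.
#' @param genome A [genome_build()] used to validate seqids.
#' @return A named list of [gene_model()] objects (names = mRNA IDs).
#' @export
read_gene_models <- function(path, genome) {
  gff <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gff)
  df$seqnames <- as.character(df$seqnames)
  df$type <- as.character(df$type)
  bad <- setdiff(unique(df$seqnames), genome$chromosomes$name)
  if (length(bad)) abort(paste0("unknown seqid in GFF3: ", bad[1]))
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  if (nrow(mrna) == 0) abort("no mRNA features in GFF3")
  first_parent <- function(p) vapply(p, function(x) as.character(x)[1], character(1))
  models <- lapply(seq_len(nrow(mrna)), function(i) {
    id <- mrna$ID[i]
    kids <- df[!vapply(df$Parent, function(p) length(p) == 0, logical(1)), , drop = FALSE]
    kids <- kids[first_parent(kids$Parent) == id, , drop = FALSE]
    ex <- kids[kids$type == "exon", c("start", "end")]
    cd <- kids[kids$type == "CDS", c("start", "end", "phase")]
    names(cd)[3] <- "frame"
    if (nrow(ex) == 0) ex <- mrna[i, c("start", "end")]
    gene_model(gene_id = id, chrom = mrna$seqnames[i],
               strand = as.character(mrna$strand[i]),
               exons = ex, cds = cd)
  })
  setNames(models, mrna$ID)
}

#' Write gene models to GFF3
#'
#' Minimal gene/mRNA/exon/CDS GFF3 emitter for models built with
#' [gene_model()]; round-trips through [read_gene_models()].
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    sp <- gene_span(g)
    lines <- c(lines,
      paste(g$chrom, "ectamapper", "gene", sp[1], sp[2], ".", g$strand, ".",
            paste0("ID=gene:", g$gene_id), sep = "\t"),
      paste(g$chrom, "ectamapper", "mRNA", sp[1], sp[2], ".", g$strand, ".",
            paste0("ID=", g$gene_id, ";Parent=gene:", g$gene_id), sep = "\t"))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines,
        paste(g$chrom, "ectamapper", "exon", g$exons$start[i], g$exons$end[i],
              ".", g$strand, ".", paste0("Parent=", g$gene_id), sep = "\t"))
    }
    for (i in seq_len(nrow(g$cds))) {
      lines <- c(lines,
        paste(g$chrom, "ectamapper", "CDS", g$cds$start[i], g$cds$end[i],
              ".", g$strand, g$cds$frame[i],
              paste0("Parent=", g$gene_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
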