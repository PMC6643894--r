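#' Read a strain's variant calls from VCF
#'
#' Keeps biallelic SNV records only (EMS induces point mutations; indels are
#' outside the model), skipping others with a count.
#'
#' @param path VCF 4.2 path.
#' @param strain_id Strain label; defaults to the file name without
#'   extension.
#' @return A variant tibble (`strain_id`, `chrom`, `pos`, `ref`, `alt`),
#'   sorted and unique on (chrom, pos, ref, alt), with attribute `skipped`.
#' @export
read_variants <- function(path, strain_id = NULL) {
  strain_id <- strain_id %||% sub("\\.[^.]*$", "", basename(path))
  tbl <- read_vcf_table(path)
  keep <- is_biallelic_snv(tbl$ref, tbl$alt)
  skipped <- sum(!keep)
  out <- variant_set(tbl[keep, c("chrom", "pos", "ref", "alt")], strain_id)
  attr(out, "skipped") <- skipped
  out
}

#' Construct / normalize a variant set
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param strain_id Strain label stored in a `strain_id` column.
#' @return Sorted, deduplicated tibble keyed by (chrom, pos, ref, alt).
#' @export
variant_set <- function(variants, strain_id = "strain") {
  v <- as_tibble(variants)[, c("chrom", "pos", "ref", "alt")]
  v$pos <- as.numeric(v$pos)
  v$ref <- unname(v$ref)
  v$alt <- unname(v$alt)
  if (nrow(v) > 0 && any(v$ref == v$alt)) abort("variant with ref == alt")
  v <- distinct(sort_by_chrom_pos(v))
  v$strain_id <- rep(strain_id, nrow(v))
  v[, c("strain_id", "chrom", "pos", "ref", "alt")]
}

#' Write a variant set as a homozygous-call VCF
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @param genome Optional [genome_build()] for contig lines.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, genome = NULL) {
  sample <- if (nrow(variants)) variants$strain_id[1] else "strain"
  header <- vcf_header(
    genome,
    format_lines = '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sample = sample)
  body <- paste(variants$chrom, as.integer(variants$pos), ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT", "1/1", sep = "\t")
  write_vcf_lines(header, body, path)
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Exclusive variant list by subtraction
#'
#' Returns the variants of `target` present in none of the `others`, keyed
#' by exact (chrom, pos, ref, alt) match — the "exclusive variant list" that
#' isolates a strain's private candidate mutations from shared background
#' and mapping-strain variation.
#'
#' @param target Variant tibble.
#' @param others List of variant tibbles to subtract (may be empty).
#' @return Variant tibble; `strain_id` of `target` preserved.
#' @export
subtract_variants <- function(target, others = list()) {
  if (is.data.frame(others)) others <- list(others)
  out <- target
  for (o in others) {
    out <- anti_join(out, o, by = c("chrom", "pos", "ref", "alt"))
  }
  out
}

#' Jaccard overlap of two variant sets
#'
#' `|A intersect B| / |A union B|` on (chrom, pos, ref, alt) keys; defined
#' as 0 when both sets are empty.
#'
#' @param a,b Variant tibbles.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  ka <- unique(variant_key(a))
  kb <- unique(variant_key(b))
  u <- length(union(ka, kb))
  if (u == 0) return(0)
  length(intersect(ka, kb)) / u
}

#' Detect sibling strains by variant-set overlap
#'
#' Sibling strains — independently isolated lines descending from the same
#' mutagenized genome — share most of their induced variants, while
#' independent EMS strains share essentially none. Strains are grouped by
#' single linkage on pairwise Jaccard overlap at or above `threshold`.
#' The overlap-threshold rule is this package's operationalization of
#' sibling calling; the default 0.5 sits far above the near-zero overlap of
#' independent strains and far below the near-1 overlap of true siblings.
#'
#' @param strains List of variant tibbles (each with a `strain_id`).
#' @param threshold Jaccard threshold in `(0, 1]`. Default 0.5.
#' @return Tibble `strain_id`, `group`, `max_overlap` (largest pairwise
#'   overlap with any other strain); groups are numbered in order of their
#'   first strain and singletons get their own group.
#' @export
detect_siblings <- function(strains, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  ids <- vapply(strains, function(s) {
    if (nrow(s)) s$strain_id[1] else "strain"
  }, character(1))
  n <- length(strains)
  jac <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        jac[i, j] <- jac[j, i] <- jaccard_index(strains[[i]], strains[[j]])
      }
    }
  }
  # single-linkage components over the >= threshold graph (union-find)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (jac[i, j] >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # groups numbered by order of first member in the input
  grp <- match(root, unique(root))
  max_ov <- if (n > 1) {
    vapply(seq_len(n), function(i) max(jac[i, -i]), numeric(1))
  } else {
    rep(NA_real_, n)
  }
  tibble(strain_id = ids, group = grp, max_overlap = max_ov)
}
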