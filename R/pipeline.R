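#' Generate toy gene models on a genome
#'
#' Places `n_per_chrom` two-exon genes (alternating strand) at regular
#' offsets on each chromosome, with the whole of each exon coding; CDS
#' length is a multiple of 3. Used by the simulate mode of the pipeline so
#' that causal variants can be constrained to coding sequence and annotated.
#'
#' @param genome A [genome_build()].
#' @param n_per_chrom Genes per chromosome. Default 3.
#' @param exon_len Length of each of the two exons, bp (multiple of 3
#'   enforced jointly). Default 300.
#' @param intron_len Intron length, bp. Default 200.
#' @return Named list of [gene_model()] objects.
#' @export
random_genes <- function(genome, n_per_chrom = 3, exon_len = 300,
                         intron_len = 200) {
  if ((2 * exon_len) %% 3 != 0) abort("total CDS length must be divisible by 3")
  genes <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    span <- 2 * exon_len + intron_len
    starts <- round(seq(len * 0.1, len * 0.9 - span,
                        length.out = n_per_chrom))
    for (j in seq_len(n_per_chrom)) {
      s <- starts[j]
      ex <- tibble(start = c(s, s + exon_len + intron_len),
                   end = c(s + exon_len - 1, s + 2 * exon_len + intron_len - 1))
      g <- gene_model(gene_id = sprintf("%s_g%d", ch, j), chrom = ch,
                      strand = if (j %% 2 == 1) "+" else "-",
                      exons = ex, cds = ex)
      genes[[g$gene_id]] <- g
    }
  }
  genes
}

#' Build a pipeline run configuration
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param out_dir Output directory (created if missing).
#' @param seed RNG seed; all randomness in a run flows from it.
#' @param cross A [cross_config()] (simulate mode).
#' @param n_strains Number of independent strains to simulate. Default 2.
#' @param sibling_pair Simulate the last strain as a sibling of the first
#'   (same mutagenized genome plus 5% private variants)? Default `FALSE`.
#' @param n_chrom,chrom_length,marker_spacing,cm_per_mb Simulated genome
#'   layout (simulate mode).
#' @param genome_fasta,markers_vcf,gff3 Input paths (ingest mode; `gff3`
#'   optional).
#' @param strains Ingest mode: named list `strain_id = list(variants = path,
#'   pool = path)`.
#' @param min_depth,span,degree,link_threshold,interval_threshold,
#'   sibling_threshold Analysis thresholds (see the stage functions).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"), out_dir, seed = 1,
                       cross = cross_config(), n_strains = 2,
                       sibling_pair = FALSE, n_chrom = 5, chrom_length = 1e6,
                       marker_spacing = 5e4, cm_per_mb = 5,
                       genome_fasta = NULL, markers_vcf = NULL, gff3 = NULL,
                       strains = NULL, min_depth = 5, span = 0.3, degree = 1,
                       link_threshold = 0.25, interval_threshold = 0.25,
                       sibling_threshold = 0.5) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, seed = seed, cross = cross,
              n_strains = n_strains, sibling_pair = sibling_pair,
              n_chrom = n_chrom, chrom_length = chrom_length,
              marker_spacing = marker_spacing, cm_per_mb = cm_per_mb,
              genome_fasta = genome_fasta, markers_vcf = markers_vcf,
              gff3 = gff3, strains = strains, min_depth = min_depth,
              span = span, degree = degree, link_threshold = link_threshold,
              interval_threshold = interval_threshold,
              sibling_threshold = sibling_threshold)
  if (mode == "ingest") {
    paths <- c(genome_fasta, markers_vcf, gff3,
               unlist(lapply(strains, unlist)))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      abort(paste0("input file not found: ", missing[1]))
    }
    if (length(strains) == 0) abort("ingest mode needs at least one strain")
  }
  for (th in c("link_threshold", "interval_threshold")) {
    if (cfg[[th]] <= 0 || cfg[[th]] >= 0.5) {
      abort(paste0(th, " must lie in (0, 0.5)"))
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()];
#'   `cross:` sub-keys are passed to [cross_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cross)) y$cross <- do.call(cross_config, y$cross)
  do.call(run_config, y)
}

#' Run the full mapping-by-sequencing analysis
#'
#' Stages, in order: sibling detection over all strains' variant sets;
#' exclusive variant lists by subtraction; mapping-strain allele
#' frequencies; per-chromosome Loess fit; linked-chromosome call; candidate
#' interval; effect annotation of the exclusive variants; severity-ranked
#' shortlist. Every stage's output is written under
#' `out_dir/<strain_id>/`; a failure in one strain is recorded and does not
#' abort the others. Runs are deterministic: identical config (including
#' seed) reproduces byte-identical outputs.
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return A `run_report`: list with `strains` (per-strain result tibble),
#'   `siblings`, `errors` (named list), `truth` (simulate mode),
#'   `config`, and `status` (0 clean, 2 partial per-strain failure).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  if (config$mode == "simulate") {
    inp <- simulate_screen_inputs(config)
  } else {
    inp <- ingest_screen_inputs(config)
  }
  genome <- inp$genome
  markers <- inp$markers
  genes <- inp$genes
  strains <- inp$strain_variants     # list of variant tibbles
  pools <- inp$pool_counts           # list of allele-count tibbles

  readable <- !vapply(strains, inherits, logical(1), "error") &
    !vapply(pools, inherits, logical(1), "error")
  sib <- detect_siblings(strains[readable], config$sibling_threshold)
  readr::write_tsv(sib, file.path(config$out_dir, "siblings.tsv"))

  errors <- list()
  rows <- list()
  for (sid in names(strains)) {
    res <- tryCatch({
      if (inherits(strains[[sid]], "error")) stop(strains[[sid]])
      if (inherits(pools[[sid]], "error")) stop(pools[[sid]])
      sdir <- file.path(config$out_dir, sid)
      dir.create(sdir, showWarnings = FALSE)
      excl <- subtract_variants(
        strains[[sid]],
        strains[readable & names(strains) != sid])
      write_variants(excl, file.path(sdir, "exclusive.vcf"), genome)
      prof <- marker_allele_frequencies(pools[[sid]], config$min_depth)
      prof <- fit_profile(prof, span = config$span, degree = config$degree)
      readr::write_tsv(as_tibble(prof), file.path(sdir, "frequencies.tsv"))
      call <- call_linked_chromosome(prof, config$link_threshold)
      readr::write_tsv(tidy(call), file.path(sdir, "linkage.tsv"))
      if (any(call$linked)) {
        interval <- candidate_interval(prof, call, config$interval_threshold)
        write_interval_bed(interval, file.path(sdir, "interval.bed"))
        shortlist <- if (!is.null(genes) && genome_has_sequence(genome)) {
          prioritize_candidates(annotate_variants(excl, genes, genome),
                                interval)
        } else {
          filter(excl, .data$chrom == interval$chrom,
                 .data$pos >= interval$start, .data$pos <= interval$end)
        }
        readr::write_tsv(shortlist, file.path(sdir, "candidates.tsv"))
      } else {
        interval <- tibble(chrom = NA_character_, start = NA_real_,
                           end = NA_real_, min_fitted = min(call$min_fitted))
        shortlist <- tibble()
      }
      tibble(strain_id = sid,
             group = sib$group[sib$strain_id == sid],
             n_variants = nrow(strains[[sid]]),
             n_exclusive = nrow(excl),
             linked = any(call$linked),
             linked_chrom = interval$chrom,
             interval_start = interval$start,
             interval_end = interval$end,
             n_candidates = nrow(shortlist))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sid]] <- conditionMessage(res)
    } else {
      rows[[sid]] <- res
    }
  }
  cfg_echo <- config
  cfg_echo$cross <- unclass(cfg_echo$cross)
  yaml::write_yaml(lapply(unclass(cfg_echo), function(x) {
    if (is.null(x)) NA else x
  }), file.path(config$out_dir, "config.yaml"))
  report <- structure(
    list(strains = bind_rows(rows), siblings = sib, errors = errors,
         truth = inp$truth, config = config,
         status = if (length(errors)) 2L else 0L),
    class = "run_report")
  readr::write_tsv(report$strains, file.path(config$out_dir, "report.tsv"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", nrow(x$strains), " strain(s) analysed, ",
      length(x$errors), " failed; status ", x$status, "\n", sep = "")
  print(x$strains)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.run_report <- function(x, ...) x$strains

#' @exportS3Method generics::glance
glance.run_report <- function(x, ...) {
  tibble(n_strains = nrow(x$strains) + length(x$errors),
         n_failed = length(x$errors),
         n_linked = sum(x$strains$linked),
         n_sibling_groups = length(unique(x$siblings$group)),
         status = x$status)
}

# simulate-mode input generation: genome + genes + markers + per-strain
# variant sets and pooled counts, plus the truth table
simulate_screen_inputs <- function(config) {
  genome <- random_genome(config$n_chrom, config$chrom_length,
                          with_sequence = TRUE, cm_per_mb = config$cm_per_mb)
  genes <- random_genes(genome)
  markers <- make_marker_grid(genome, config$marker_spacing)
  n <- config$n_strains
  strain_ids <- sprintf("sim%02d", seq_len(n))
  strain_variants <- list()
  pool_counts <- list()
  truth <- list()
  cross <- config$cross
  cross$seed <- NULL  # one stream for the whole run, seeded once
  parents <- vector("list", n)
  for (i in seq_len(n)) {
    if (config$sibling_pair && i == n && n >= 2) {
      parents[[i]] <- sibling_of(parents[[1]], genome, strain_ids[i])
    } else {
      parents[[i]] <- mutagenize(genome, cross, strain_id = strain_ids[i],
                                 causal_in_cds = TRUE, genes = genes)
    }
    st <- parents[[i]]
    pool <- simulate_cross(st, markers, genome, cross)
    pool_counts[[st$strain_id]] <- simulate_pool_readcounts(pool, cross)
    strain_variants[[st$strain_id]] <- variant_set(st$variants, st$strain_id)
    truth[[st$strain_id]] <- tibble(strain_id = st$strain_id,
                                    causal_chrom = st$causal$chrom,
                                    causal_pos = st$causal$pos)
  }
  truth <- bind_rows(truth)
  readr::write_tsv(truth, file.path(config$out_dir, "truth.tsv"))
  list(genome = genome, genes = genes, markers = markers,
       strain_variants = strain_variants, pool_counts = pool_counts,
       truth = truth)
}

#' Derive a sibling strain from an existing mutant strain
#'
#' Siblings descend from the same mutagenized genome: the new strain keeps
#' every induced variant (including the causal one) and gains private
#' variants amounting to `private_frac` of the shared count, placed like EMS
#' variants.
#'
#' @param strain A [mutant_strain()].
#' @param genome A [genome_build()] with sequence.
#' @param strain_id Name for the sibling.
#' @param private_frac Fraction of shared variants added privately. Default
#'   0.05.
#' @return A [mutant_strain()].
#' @export
sibling_of <- function(strain, genome, strain_id, private_frac = 0.05) {
  n_priv <- max(1, round(private_frac * nrow(strain$variants)))
  cfg <- cross_config(mutation_rate = n_priv / sum(genome$chromosomes$length))
  extra <- mutagenize(genome, cfg, strain_id = "tmp")
  v <- bind_rows(strain$variants[, c("chrom", "pos", "ref", "alt")],
                 extra$variants[, c("chrom", "pos", "ref", "alt")])
  v <- distinct(sort_by_chrom_pos(v), .data$chrom, .data$pos, .keep_all = TRUE)
  mutant_strain(strain_id, v, strain$causal$chrom, strain$causal$pos)
}

ingest_screen_inputs <- function(config) {
  genome <- if (!is.null(config$genome_fasta)) {
    read_genome(config$genome_fasta, cm_per_mb = config$cm_per_mb)
  } else {
    NULL
  }
  markers <- read_marker_map(config$markers_vcf)
  genes <- if (!is.null(config$gff3)) read_gene_models(config$gff3, genome)
  strain_variants <- list()
  pool_counts <- list()
  for (sid in names(config$strains)) {
    s <- config$strains[[sid]]
    # defer per-strain read failures to the stage loop so one broken input
    # does not abort the other strains
    strain_variants[[sid]] <- tryCatch(read_variants(s$variants,
                                                     strain_id = sid),
                                       error = function(e) e)
    pool_counts[[sid]] <- tryCatch(read_pool_vcf(s$pool),
                                   error = function(e) e)
  }
  list(genome = genome, genes = genes, markers = markers,
       strain_variants = strain_variants, pool_counts = pool_counts,
       truth = NULL)
}
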