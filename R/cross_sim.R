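#' Cross/sequencing simulation configuration
#'
#' Bundles the knobs of the synthetic screen: pool size, sequencing depth,
#' per-read miscall rate, EMS mutation rate and substitution spectrum.
#' Defaults describe the study conditions used throughout: 50 phenotype-
#' selected F2 animals pooled, 30x mean depth, 0.2% read error, and the
#' canonical EMS bias of 87% G:C->A:T transitions with the remaining 13%
#' spread uniformly over the other five substitution classes.
#'
#' @param n_f2 Pool size N (selected F2 animals). Default 50.
#' @param depth Mean sequencing depth D per site (Poisson). Default 30.
#' @param error_rate Per-read miscall probability, in `[0, 0.5)`. Default
#'   0.002.
#' @param mutation_rate EMS variants per bp. Default 1e-5 (hundreds of
#'   induced SNVs on a Mb-scale toy genome, genome-scale realistic density).
#' @param spectrum Named probability vector over the six strand-symmetric
#'   substitution classes `GC_AT`, `GC_TA`, `GC_CG`, `AT_GC`, `AT_TA`,
#'   `AT_CG`; must sum to 1.
#' @param seed Optional RNG seed; every stochastic simulator in the package
#'   draws from this single stream.
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(n_f2 = 50, depth = 30, error_rate = 0.002,
                         mutation_rate = 1e-5,
                         spectrum = ems_spectrum(), seed = NULL) {
  if (n_f2 < 1) abort("n_f2 must be >= 1")
  if (depth <= 0) abort("depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("error_rate must be in [0, 0.5)")
  }
  if (mutation_rate < 0) abort("mutation_rate must be >= 0")
  cls <- c("GC_AT", "GC_TA", "GC_CG", "AT_GC", "AT_TA", "AT_CG")
  if (!setequal(names(spectrum), cls) ||
      abs(sum(spectrum) - 1) > 1e-8 || any(spectrum < 0)) {
    abort("spectrum must be a probability vector over the six substitution classes")
  }
  structure(list(n_f2 = as.integer(n_f2), depth = depth,
                 error_rate = error_rate, mutation_rate = mutation_rate,
                 spectrum = spectrum[cls], seed = seed),
            class = "cross_config")
}

#' Canonical EMS substitution spectrum
#'
#' @param gc_at Probability mass on G:C->A:T transitions (default 0.87); the
#'   remainder is split uniformly over the other five classes.
#' @return Named probability vector.
#' @export
ems_spectrum <- function(gc_at = 0.87) {
  rest <- (1 - gc_at) / 5
  c(GC_AT = gc_at, GC_TA = rest, GC_CG = rest, AT_GC = rest, AT_TA = rest,
    AT_CG = rest)
}

#' Construct a mutant strain
#'
#' A homozygous EMS-derived strain: its induced variant set and the identity
#' of the phenotype-causing variant. The causal variant must be among the
#' induced variants.
#'
#' @param strain_id Strain name.
#' @param variants Tibble of homozygous variants (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param causal_chrom,causal_pos Location of the causal variant.
#' @return A list of class `mutant_strain`.
#' @export
mutant_strain <- function(strain_id, variants, causal_chrom, causal_pos) {
  variants <- as_tibble(variants)
  hit <- variants$chrom == causal_chrom & variants$pos == causal_pos
  if (!any(hit)) abort("causal variant is not among the strain's variants")
  structure(list(strain_id = strain_id, variants = variants,
                 causal = list(chrom = causal_chrom, pos = causal_pos)),
            class = "mutant_strain")
}

# map substitution class + ref base -> alt base (strand-symmetric pairs)
.subst_alt <- list(
  GC_AT = c(G = "A", C = "T"), GC_TA = c(G = "T", C = "A"),
  GC_CG = c(G = "C", C = "G"), AT_GC = c(A = "G", T = "C"),
  AT_TA = c(A = "T", T = "A"), AT_CG = c(A = "C", T = "G"))

#' Simulate EMS mutagenesis of a strain
#'
#' Draws a Poisson(`mutation_rate` x genome size) number of point mutations,
#' assigns each a substitution class from the configured spectrum, and
#' places it uniformly among genome positions whose reference base is
#' compatible with that class (G/C for `GC_*`, A/T for `AT_*`). One variant
#' is designated causal; with `causal_in_cds = TRUE` the causal variant is
#' chosen among (or, if none, added to) positions inside a CDS of the
#' supplied gene models.
#'
#' @param genome A [genome_build()] with sequences.
#' @param config A [cross_config()].
#' @param strain_id Strain name for the result.
#' @param causal_in_cds Constrain the causal variant to coding sequence?
#' @param genes Gene models (required if `causal_in_cds`).
#' @return A [mutant_strain()].
#' @export
mutagenize <- function(genome, config, strain_id = "strain1",
                       causal_in_cds = FALSE, genes = NULL) {
  if (!genome_has_sequence(genome)) abort("mutagenize needs genome sequence")
  if (!is.null(config$seed)) set.seed(config$seed)
  gsize <- sum(genome$chromosomes$length)
  n_var <- rpois(1, config$mutation_rate * gsize)
  if (n_var == 0 && !causal_in_cds) {
    abort("no variants induced; cannot designate a causal variant")
  }
  # base-category index per chromosome, computed once
  base_pos <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    b <- strsplit(genome$chromosomes$sequence[i], "")[[1]]
    list(GC = which(b %in% c("G", "C")), AT = which(b %in% c("A", "T")))
  })
  names(base_pos) <- genome$chromosomes$name
  draw_variants <- function(n) {
    if (n == 0) {
      return(tibble(chrom = character(), pos = numeric(), ref = character(),
                    alt = character()))
    }
    cls <- sample(names(config$spectrum), n, replace = TRUE,
                  prob = config$spectrum)
    cat2 <- substr(cls, 1, 2)  # "GC" or "AT"
    chrom_i <- sample.int(nrow(genome$chromosomes), n, replace = TRUE,
                          prob = genome$chromosomes$length)
    pos <- vapply(seq_len(n), function(k) {
      cand <- base_pos[[chrom_i[k]]][[cat2[k]]]
      if (length(cand) == 0) return(NA_real_)
      cand[sample.int(length(cand), 1)]
    }, numeric(1))
    chrom <- genome$chromosomes$name[chrom_i]
    ref <- ref_base_at(genome, chrom, pos)
    alt <- vapply(seq_len(n), function(k) .subst_alt[[cls[k]]][[ref[k]]],
                  character(1))
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
  }
  vars <- draw_variants(n_var)
  vars <- distinct(vars, .data$chrom, .data$pos, .keep_all = TRUE)
  vars <- sort_by_chrom_pos(vars, genome$chromosomes$name)
  if (causal_in_cds) {
    if (is.null(genes)) abort("causal_in_cds requires gene models")
    in_cds <- rep(FALSE, nrow(vars))
    for (g in genes) {
      for (i in seq_len(nrow(g$cds))) {
        in_cds <- in_cds | (vars$chrom == g$chrom &
                              vars$pos >= g$cds$start[i] &
                              vars$pos <= g$cds$end[i])
      }
    }
    if (any(in_cds)) {
      ci <- which(in_cds)[sample.int(sum(in_cds), 1)]
    } else {
      g <- genes[[sample.int(length(genes), 1)]]
      row <- g$cds[sample.int(nrow(g$cds), 1), ]
      p <- sample(seq(row$start, row$end), 1)
      ref <- ref_base_at(genome, g$chrom, p)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[sample.int(3, 1)]
      vars <- sort_by_chrom_pos(
        bind_rows(vars, tibble(chrom = g$chrom, pos = p, ref = ref, alt = alt)),
        genome$chromosomes$name)
      ci <- which(vars$chrom == g$chrom & vars$pos == p)
    }
  } else {
    ci <- sample.int(nrow(vars), 1)
  }
  mutant_strain(strain_id, vars, vars$chrom[ci], vars$pos[ci])
}

#' Haldane map function
#'
#' Recombination fraction between two loci `d` centimorgans apart under the
#' no-interference (Poisson crossover) model:
#' `r(d) = (1 - exp(-2 d / 100)) / 2`. This closed form is the expectation
#' against which pooled allele frequencies from [simulate_cross()] are
#' checked.
#'
#' @param d Genetic distance(s), cM; must be >= 0.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 5, 50))
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) abort("genetic distance must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

# Parental origins (0 = parent A, 1 = parent B) for n gametes at the sorted
# genetic positions pos_cm on a chromosome of genetic length len_cm.
# Crossover count ~ Poisson(len_cm/100), positions uniform, start fair coin.
sim_gamete_origins <- function(n, pos_cm, len_cm) {
  p <- length(pos_cm)
  out <- matrix(0L, n, p)
  k <- rpois(n, len_cm / 100)
  start <- sample.int(2L, n, replace = TRUE) - 1L
  xo_all <- runif(sum(k), 0, len_cm)
  idx <- rep.int(seq_len(n), k)
  if (p == 0) return(out)
  for (g in seq_len(n)) {
    if (k[g] == 0) {
      out[g, ] <- start[g]
    } else {
      xo <- sort.int(xo_all[idx == g])
      out[g, ] <- (start[g] + findInterval(pos_cm, xo)) %% 2L
    }
  }
  out
}

#' Simulate a single meiosis
#'
#' Produces one gamete haplotype from a heterozygous F1 over the given
#' positions of one chromosome: crossovers are Poisson with mean equal to
#' the chromosome's genetic length in Morgans, crossover positions are
#' uniform, the starting parent is a fair coin, and parental origin
#' alternates at each crossover (Haldane model, no interference).
#'
#' @param hap_a,hap_b Parental haplotype allele vectors at `pos` (equal
#'   length).
#' @param genome A [genome_build()].
#' @param chrom Chromosome name.
#' @param pos Physical positions (bp) of the tracked sites, sorted.
#' @return Gamete allele vector: `hap_a[i]` where origin is parent A,
#'   `hap_b[i]` where parent B.
#' @export
simulate_meiosis <- function(hap_a, hap_b, genome, chrom, pos) {
  stopifnot(length(hap_a) == length(hap_b), length(pos) == length(hap_a))
  if (length(pos) == 0) return(hap_a[0])
  len_cm <- pos_to_cm(genome, chrom, chrom_length(genome, chrom))
  org <- sim_gamete_origins(1, pos_to_cm(genome, chrom, pos), len_cm)[1, ]
  ifelse(org == 1L, hap_b, hap_a)
}

#' Simulate the mapping cross and phenotype-selected F2 pool
#'
#' The homozygous mutant strain is crossed to the mapping strain; the F1 is
#' heterozygous at every marker and at the causal site. Each F2 is formed
#' from two independent F1 gametes and retained iff homozygous for the
#' mutant (non-mapping) allele at the causal site — the genetic meaning of
#' selecting a recessive phenotype. Exactly `config$n_f2` animals are
#' retained.
#'
#' Genotypes are the per-animal count of mapping-strain alleles (0/1/2) at
#' each marker. At genetic distance `d` from the causal locus the expected
#' pooled mapping-allele frequency is [haldane_r()]`(d)`; on unlinked
#' chromosomes it is 0.5.
#'
#' @param strain A [mutant_strain()].
#' @param markers A [marker_map()].
#' @param genome A [genome_build()].
#' @param config A [cross_config()]; `config$seed` (if set) seeds the draw.
#' @return A list of class `f2_pool`: `genotypes` (N x n_markers integer
#'   matrix of mapping-allele counts), `markers`, `causal`.
#' @export
simulate_cross <- function(strain, markers, genome, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  causal <- strain$causal
  if (!causal$chrom %in% genome$chromosomes$name) {
    abort("causal chromosome absent from genome")
  }
  if (!causal$chrom %in% markers$chrom) {
    abort("selection impossible: no markers on the causal chromosome")
  }
  n <- config$n_f2
  chroms <- unique(markers$chrom)
  geno <- matrix(NA_integer_, n, nrow(markers))

  # causal chromosome: rejection-sample animal gamete pairs that are both
  # mutant (origin 0 = mutant parent) at the causal site
  cc <- causal$chrom
  sel <- which(markers$chrom == cc)
  len_cm <- pos_to_cm(genome, cc, chrom_length(genome, cc))
  pos_cm <- pos_to_cm(genome, cc, c(markers$pos[sel], causal$pos))
  ord <- order(pos_cm)
  causal_idx <- which(ord == length(pos_cm))  # column of causal site
  got <- 0
  acc <- matrix(0L, n, length(sel))
  while (got < n) {
    batch <- max(16L, ceiling((n - got) * 4.4))
    g1 <- sim_gamete_origins(batch, pos_cm[ord], len_cm)
    g2 <- sim_gamete_origins(batch, pos_cm[ord], len_cm)
    ok <- which(g1[, causal_idx] == 0L & g2[, causal_idx] == 0L)
    if (length(ok)) {
      take <- ok[seq_len(min(length(ok), n - got))]
      s <- g1[take, -causal_idx, drop = FALSE] +
        g2[take, -causal_idx, drop = FALSE]
      # undo the position sort to map back onto marker order
      marker_cols <- ord[-causal_idx]
      acc[got + seq_along(take), marker_cols] <- s
      got <- got + length(take)
    }
  }
  geno[, sel] <- acc

  # other chromosomes: unconditioned independent assortment
  for (ch in setdiff(chroms, cc)) {
    idx <- which(markers$chrom == ch)
    len_cm <- pos_to_cm(genome, ch, chrom_length(genome, ch))
    pos_cm <- pos_to_cm(genome, ch, markers$pos[idx])
    g1 <- sim_gamete_origins(n, pos_cm, len_cm)
    g2 <- sim_gamete_origins(n, pos_cm, len_cm)
    geno[, idx] <- g1 + g2
  }
  structure(list(genotypes = geno, markers = markers, causal = causal),
            class = "f2_pool")
}

#' Sorter-style gate on (size, fluorescence) event tables
#'
#' Emulates selecting objects of wild-type size with elevated reporter
#' fluorescence on a worm sorter: keeps events whose size falls inside
#' `size_range` and whose fluorescence is at least `fluor_min`.
#'
#' @param events Data frame with columns `size` and `fluorescence`.
#' @param size_range Length-2 numeric `(min, max)`, closed interval.
#' @param fluor_min Minimum fluorescence.
#' @return Integer indices of selected events, in input order.
#' @export
gate_f2 <- function(events, size_range, fluor_min) {
  events <- as_tibble(events)
  if (nrow(events) == 0) return(integer())
  which(events$size >= size_range[1] & events$size <= size_range[2] &
          events$fluorescence >= fluor_min)
}

#' Simulate pooled sequencing allele depths at the markers
#'
#' Per marker, total depth is Poisson(`depth`); each read carries the
#' mapping allele with probability `f (1 - e) + (1 - f) e`, where `f` is the
#' pool's true mapping-allele frequency and `e` the per-read miscall rate.
#'
#' @param pool An `f2_pool` from [simulate_cross()].
#' @param config A [cross_config()] (depth and error rate; the RNG stream is
#'   assumed already seeded by the caller or by [simulate_cross()]).
#' @return Tibble: `chrom`, `pos`, `ref`, `map_allele`, `ref_count`,
#'   `map_count`, `true_freq`.
#' @export
simulate_pool_readcounts <- function(pool, config) {
  if (config$depth <= 0) abort("depth must be > 0")
  n2 <- 2 * nrow(pool$genotypes)
  f <- colSums(pool$genotypes) / n2
  m <- length(f)
  dp <- rpois(m, config$depth)
  p_obs <- f * (1 - config$error_rate) + (1 - f) * config$error_rate
  map_count <- rbinom(m, dp, p_obs)
  tibble(chrom = pool$markers$chrom, pos = pool$markers$pos,
         ref = pool$markers$ref, map_allele = pool$markers$map_allele,
         ref_count = dp - map_count, map_count = map_count, true_freq = f)
}

#' Write pooled allele depths as a VCF with AD/DP fields
#'
#' @param counts Tibble from [simulate_pool_readcounts()] (or with the same
#'   columns).
#' @param path Output path.
#' @param genome Optional [genome_build()] for contig lines.
#' @param sample Sample name in the VCF column header.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(counts, path, genome = NULL, sample = "pool") {
  header <- vcf_header(
    genome,
    format_lines = c(
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    sample = sample)
  dp <- counts$ref_count + counts$map_count
  body <- paste(counts$chrom, as.integer(counts$pos), ".", counts$ref,
                counts$map_allele, ".", "PASS", ".", "AD:DP",
                paste0(counts$ref_count, ",", counts$map_count, ":", dp),
                sep = "\t")
  write_vcf_lines(header, body, path)
}

#' Read pooled allele depths from a VCF with AD fields
#'
#' Inverse of [write_pool_vcf()]: biallelic SNV records with an AD field
#' become one row each; other records are skipped with a count.
#'
#' @param path VCF path.
#' @return Tibble `chrom`, `pos`, `ref`, `map_allele`, `ref_count`,
#'   `map_count` with attribute `skipped`.
#' @export
read_pool_vcf <- function(path) {
  tbl <- read_vcf_table(path)
  if (!"ad" %in% names(tbl)) abort("VCF has no AD field")
  keep <- is_biallelic_snv(tbl$ref, tbl$alt) & !is.na(tbl$ad)
  skipped <- sum(!keep)
  tbl <- tbl[keep, ]
  ad <- strsplit(tbl$ad, ",", fixed = TRUE)
  out <- tibble(chrom = tbl$chrom, pos = tbl$pos, ref = tbl$ref,
                map_allele = tbl$alt,
                ref_count = as.integer(vapply(ad, `[`, character(1), 1)),
                map_count = as.integer(vapply(ad, `[`, character(1), 2)))
  out <- sort_by_chrom_pos(out)
  attr(out, "skipped") <- skipped
  out
}
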