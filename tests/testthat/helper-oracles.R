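# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# per-point weighted least squares via lm(), the brute-force Loess oracle
oracle_loess <- function(x, y, span, degree) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    nb <- order(d)[seq_len(q)]
    dmax <- max(d[nb])
    w <- if (dmax == 0) rep(1, q) else (1 - (d[nb] / dmax)^3)^3
    df <- data.frame(x = x[nb], y = y[nb], w = w)
    fit <- if (degree == 0) {
      lm(y ~ 1, data = df, weights = w)
    } else {
      lm(y ~ x, data = df, weights = w)
    }
    unname(predict(fit, newdata = data.frame(x = x[i])))
  }, numeric(1))
}

# full-CDS re-translation oracle for effect classes: mutate the complete CDS
# string, translate both with Biostrings, and diff the proteins
oracle_effect_class <- function(cds_seq, cds_pos, alt_base_cds) {
  mt <- cds_seq
  substr(mt, cds_pos, cds_pos) <- alt_base_cds
  tr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "solve"))
  }
  p_ref <- tr(cds_seq)
  p_alt <- tr(mt)
  ci <- ceiling(cds_pos / 3)
  if (ci == 1) return("start_lost")
  if (p_ref == p_alt) return("synonymous")
  aa_ref <- substr(p_ref, ci, ci)
  aa_alt <- substr(p_alt, ci, ci)
  if (aa_ref == "*") return("stop_lost")
  if (aa_alt == "*") return("nonsense")
  if (aa_ref == aa_alt) return("synonymous")
  "missense"
}

# genomic strand-aware wrapper: cds position/allele from genomic coordinates
oracle_effect_genomic <- function(gene, genome_seq, pos, alt) {
  oracle_effect_genomic_batch(gene, genome_seq, pos, alt)
}

# vectorized variant of the re-translation oracle: one translate() call over
# a DNAStringSet of all mutant CDS strings
oracle_effect_genomic_batch <- function(gene, genome_seq, pos, alt) {
  cds <- gene$cds
  lens <- cds$end - cds$start + 1
  cum_before <- cumsum(c(0, lens[-length(lens)]))
  pieces <- vapply(seq_len(nrow(cds)), function(i) {
    substr(genome_seq, cds$start[i], cds$end[i])
  }, character(1))
  s <- paste(pieces, collapse = "")
  total <- sum(lens)
  piece <- vapply(pos, function(p) which(p >= cds$start & p <= cds$end)[1],
                  numeric(1))
  fwd <- cum_before[piece] + (pos - cds$start[piece] + 1)
  if (gene$strand == "+") {
    cds_pos <- fwd
    alt_cds <- alt
  } else {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    cds_pos <- total - fwd + 1
    alt_cds <- chartr("ACGT", "TGCA", alt)
  }
  mutants <- vapply(seq_along(cds_pos), function(i) {
    m <- s
    substr(m, cds_pos[i], cds_pos[i]) <- alt_cds[i]
    m
  }, character(1))
  prots <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(c(s, mutants)), if.fuzzy.codon = "solve"))
  p_ref <- prots[1]
  p_alt <- prots[-1]
  ci <- ceiling(cds_pos / 3)
  vapply(seq_along(ci), function(i) {
    if (ci[i] == 1) return("start_lost")
    if (p_ref == p_alt[i]) return("synonymous")
    aa_ref <- substr(p_ref, ci[i], ci[i])
    aa_alt <- substr(p_alt[i], ci[i], ci[i])
    if (aa_ref == "*") return("stop_lost")
    if (aa_alt == "*") return("nonsense")
    if (aa_ref == aa_alt) return("synonymous")
    "missense"
  }, character(1))
}

# Wilson interval by numeric root-finding on the score equation
oracle_wilson <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  score <- function(p0) (p - p0) / sqrt(p0 * (1 - p0) / n)
  eps <- 1e-12
  lo <- if (p == 0) 0 else uniroot(function(p0) score(p0) - z,
                                   c(eps, min(p, 1 - eps)), tol = 1e-12)$root
  hi <- if (p == 1) 1 else uniroot(function(p0) score(p0) + z,
                                   c(max(p, eps), 1 - eps), tol = 1e-12)$root
  c(lo, hi)
}

# two-sided Fisher exact p by hypergeometric enumeration with choose()
oracle_fisher_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  hyper <- function(x) {
    choose(n1, x) * choose(n2, m - x) / choose(n1 + n2, m)
  }
  xs <- max(0, m - n2):min(n1, m)
  probs <- vapply(xs, hyper, numeric(1))
  p_obs <- hyper(k1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
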