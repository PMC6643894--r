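test_that("Haldane map function matches its closed form and bounds", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(50), (1 - exp(-1)) / 2)
  expect_lte(haldane_r(1e6), 0.5)
  expect_gt(haldane_r(1e6), 0.4999)
  expect_lt(haldane_r(300), 0.5)
  d <- seq(0, 200, by = 0.5)
  r <- haldane_r(d)
  expect_true(all(diff(r) > 0))
  expect_error(haldane_r(-1), ">= 0")
})

test_that("cross_config enforces its invariants", {
  expect_error(cross_config(error_rate = 0.5), "error_rate")
  expect_error(cross_config(depth = 0), "depth")
  expect_error(cross_config(n_f2 = 0), "n_f2")
  bad <- ems_spectrum(); bad[1] <- bad[1] + 0.2
  expect_error(cross_config(spectrum = bad), "probability")
})

test_that("mutagenesis follows the configured substitution spectrum", {
  g <- toy_genome(n_chrom = 1, len = 2e4)
  only_gc_at <- c(GC_AT = 1, GC_TA = 0, GC_CG = 0, AT_GC = 0, AT_TA = 0,
                  AT_CG = 0)
  cfg <- cross_config(mutation_rate = 2e-3, spectrum = only_gc_at, seed = 5)
  st <- mutagenize(g, cfg)
  expect_gt(nrow(st$variants), 5)
  expect_true(all(paste0(st$variants$ref, st$variants$alt) %in% c("GA", "CT")))
  # positions unique, causal among the variants, ref matches the sequence
  expect_false(any(duplicated(paste(st$variants$chrom, st$variants$pos))))
  expect_true(any(st$variants$chrom == st$causal$chrom &
                    st$variants$pos == st$causal$pos))
  seq_ref <- vapply(st$variants$pos, function(p) {
    substr(g$chromosomes$sequence[1], p, p)
  }, character(1))
  expect_identical(seq_ref, st$variants$ref)
})

test_that("mutagenesis variant count has the Poisson mean", {
  g <- toy_genome(n_chrom = 1, len = 2e5, seed = 3)
  mu <- 5e-5  # mean 10 variants on 200 kb
  set.seed(77)
  counts <- vapply(1:300, function(i) {
    nrow(mutagenize(g, cross_config(mutation_rate = mu))$variants)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 300))
  # zero-rate degenerate case
  expect_error(mutagenize(g, cross_config(mutation_rate = 0)), "causal")
})

test_that("meioses produce recombinant gametes at the Haldane rate", {
  g <- genome_build(data.frame(name = "chrI", length = 1e7), cm_per_mb = 5)
  # markers 20 cM apart (4 Mb at 5 cM/Mb)
  pos <- c(1e6, 5e6)
  hap_a <- c(0L, 0L)
  hap_b <- c(1L, 1L)
  set.seed(21)
  rec <- vapply(1:10000, function(i) {
    gam <- simulate_meiosis(hap_a, hap_b, g, "chrI", pos)
    gam[1] != gam[2]
  }, logical(1))
  r <- haldane_r(20)
  se <- sqrt(r * (1 - r) / 10000)
  expect_lt(abs(mean(rec) - r), 3 * se)
  # each gamete position comes from one of the parents
  gam <- simulate_meiosis(c(5L, 7L), c(8L, 9L), g, "chrI", pos)
  expect_true(all(gam %in% c(5L, 7L, 8L, 9L)))
  # identical parents: gamete equals them regardless of crossovers
  expect_equal(simulate_meiosis(c(1L, 1L), c(1L, 1L), g, "chrI", pos),
               c(1L, 1L))
  # empty chromosome gives an empty haplotype
  expect_length(simulate_meiosis(integer(), integer(), g, "chrI",
                                 numeric()), 0)
})

test_that("F2 selection zeroes the mapping allele at the causal site", {
  g <- genome_build(data.frame(name = c("chrI", "chrII"),
                               length = c(1e7, 1e7)), cm_per_mb = 5)
  mk <- marker_map(tibble::tibble(
    chrom = c("chrI", "chrI", "chrII"), pos = c(2e6, 6e6, 5e6),
    ref = "A", map_allele = "T"))
  st <- mutant_strain("m1", data.frame(chrom = "chrI", pos = 2e6,
                                       ref = "A", alt = "G"), "chrI", 2e6)
  cfg <- cross_config(n_f2 = 40, depth = 50, error_rate = 0, seed = 31)
  pool <- simulate_cross(st, mk, g, cfg)
  expect_equal(dim(pool$genotypes), c(40, 3))
  # marker coincident with the causal site: selection forces frequency 0
  expect_equal(sum(pool$genotypes[, 1]), 0)
  # selection impossible without markers on the causal chromosome
  st2 <- mutant_strain("m2", data.frame(chrom = "chrIII", pos = 100,
                                        ref = "A", alt = "G"), "chrIII", 100)
  expect_error(simulate_cross(st2, mk, g, cfg), "impossible|absent")
})

test_that("pooled frequency follows r(d) on the causal chromosome and 0.5 off it", {
  g <- genome_build(data.frame(name = c("chrI", "chrII"),
                               length = c(2e7, 2e7)), cm_per_mb = 5)
  d_cm <- 10
  mk <- marker_map(tibble::tibble(
    chrom = c("chrI", "chrII"), pos = c(1e6 + d_cm / 5 * 1e6, 1e7),
    ref = "A", map_allele = "T"))
  st <- mutant_strain("m1", data.frame(chrom = "chrI", pos = 1e6,
                                       ref = "A", alt = "G"), "chrI", 1e6)
  cfg <- cross_config(n_f2 = 50, depth = 30, error_rate = 0)
  set.seed(87)
  freqs <- t(vapply(1:100, function(i) {
    pool <- simulate_cross(st, mk, g, cfg)
    colSums(pool$genotypes) / (2 * nrow(pool$genotypes))
  }, numeric(2)))
  r <- haldane_r(d_cm)
  se_linked <- sd(freqs[, 1]) / sqrt(100)
  se_unl <- sd(freqs[, 2]) / sqrt(100)
  expect_lt(abs(mean(freqs[, 1]) - r), 3 * se_linked)
  expect_lt(abs(mean(freqs[, 2]) - 0.5), 3 * se_unl)
})

test_that("sorter gating equals the brute-force filter", {
  set.seed(13)
  ev <- tibble::tibble(size = runif(500, 0, 100),
                       fluorescence = rlnorm(500, 3, 1))
  sel <- gate_f2(ev, size_range = c(30, 70), fluor_min = 25)
  brute <- which(vapply(seq_len(nrow(ev)), function(i) {
    ev$size[i] >= 30 && ev$size[i] <= 70 && ev$fluorescence[i] >= 25
  }, logical(1)))
  expect_identical(sel, brute)
  expect_identical(gate_f2(ev[0, ], c(0, 1), 0), integer())
  expect_identical(gate_f2(tibble::tibble(size = 50, fluorescence = 1e9),
                           c(0, 100), 0), 1L)
  expect_identical(gate_f2(ev, c(0, 100), Inf), integer())
})

test_that("read counts follow the error-convolved pool frequency", {
  g <- genome_build(data.frame(name = "chrI", length = 2e7), cm_per_mb = 5)
  mk <- marker_map(tibble::tibble(chrom = "chrI", pos = c(1e6, 1.9e7),
                                  ref = "A", map_allele = "T"))
  st <- mutant_strain("m", data.frame(chrom = "chrI", pos = 1e6, ref = "A",
                                      alt = "G"), "chrI", 1e6)
  cfg0 <- cross_config(n_f2 = 30, depth = 40, error_rate = 0, seed = 3)
  pool <- simulate_cross(st, mk, g, cfg0)
  cnt <- simulate_pool_readcounts(pool, cfg0)
  expect_equal(cnt$map_count[1], 0)  # causal marker, no sequencing error
  expect_true(all(cnt$ref_count >= 0 & cnt$map_count >= 0))
  # observed frequency at an unlinked locus stays 0.5 in expectation for
  # any error rate, since f(1-e)+(1-f)e = 0.5 at f = 0.5
  g2 <- genome_build(data.frame(name = c("chrI", "chrII"),
                                length = c(1e6, 1e6)))
  mk2 <- marker_map(tibble::tibble(chrom = "chrII",
                                   pos = seq(2000, 998000, length.out = 500),
                                   ref = "A", map_allele = "T"))
  mk2 <- marker_map(dplyr::bind_rows(
    mk2, tibble::tibble(chrom = "chrI", pos = 500, ref = "A",
                        map_allele = "T")))
  st2 <- mutant_strain("m", data.frame(chrom = "chrI", pos = 500, ref = "A",
                                       alt = "G"), "chrI", 500)
  cfg <- cross_config(n_f2 = 50, depth = 30, error_rate = 0.01, seed = 19)
  pool2 <- simulate_cross(st2, mk2, g2, cfg)
  cnt2 <- simulate_pool_readcounts(pool2, cfg)
  unl <- cnt2$chrom == "chrII" & cnt2$ref_count + cnt2$map_count > 0
  fobs <- cnt2$map_count[unl] / (cnt2$map_count[unl] + cnt2$ref_count[unl])
  # conditional on the pool, E[fobs] = f (1 - e) + (1 - f) e per marker
  expected <- cnt2$true_freq[unl] * (1 - 0.01) + (1 - cnt2$true_freq[unl]) * 0.01
  resid <- fobs - expected
  se <- sd(resid) / sqrt(sum(unl))
  expect_lt(abs(mean(resid)), 3 * se)
})

test_that("identical seeds give bit-identical simulated VCF output", {
  g <- genome_build(data.frame(name = "chrI", length = 1e6), cm_per_mb = 5)
  mk <- marker_map(tibble::tibble(chrom = "chrI",
                                  pos = seq(5e4, 9.5e5, by = 5e4),
                                  ref = "A", map_allele = "T"))
  st <- mutant_strain("m", data.frame(chrom = "chrI", pos = 3e5, ref = "A",
                                      alt = "G"), "chrI", 3e5)
  cfg <- cross_config(n_f2 = 20, depth = 20, seed = 404)
  run_once <- function() {
    pool <- simulate_cross(st, mk, g, cfg)
    cnt <- simulate_pool_readcounts(pool, cfg)
    p <- tempfile(fileext = ".vcf")
    write_pool_vcf(cnt, p, g)
    readLines(p)
  }
  expect_identical(run_once(), run_once())
})
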