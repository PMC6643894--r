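# a hand-designed 30-bp CDS: ATG GCT TGG TCA AAA CCC GGG TTT CAT TAA
#                              M   A   W   S   K   P   G   F   H   *
toy_cds <- "ATGGCTTGGTCAAAACCCGGGTTTCATTAA"

test_that("codon-level classes come out right on hand-translated cases", {
  fx <- toy_coding_gene(toy_cds, offset = 100)
  # TGG -> TGA at codon 3 position 3 (genomic 100 + 9): nonsense W3*
  v <- tibble::tibble(chrom = "chrI", pos = 109, ref = "G", alt = "A")
  ann <- annotate_variants(v, list(fx$gene), fx$genome)
  expect_equal(ann$effect_class, "nonsense")
  expect_equal(ann$protein_change, "W3*")
  # GCT -> GCC at codon 2: synonymous A2A
  v2 <- tibble::tibble(chrom = "chrI", pos = 106, ref = "T", alt = "C")
  ann2 <- annotate_variants(v2, list(fx$gene), fx$genome)
  expect_equal(ann2$effect_class, "synonymous")
  expect_equal(ann2$protein_change, "A2A")
  # TCA -> GCA at codon 4: missense S4A
  v3 <- tibble::tibble(chrom = "chrI", pos = 110, ref = "T", alt = "G")
  ann3 <- annotate_variants(v3, list(fx$gene), fx$genome)
  expect_equal(ann3$effect_class, "missense")
  expect_equal(ann3$protein_change, "S4A")
  # TAA stop codon -> CAA: stop_lost
  v4 <- tibble::tibble(chrom = "chrI", pos = 128, ref = "T", alt = "C")
  expect_equal(annotate_variants(v4, list(fx$gene), fx$genome)$effect_class,
               "stop_lost")
  # any SNV in the initiator codon: start_lost
  v5 <- tibble::tibble(chrom = "chrI", pos = 101, ref = "A", alt = "G")
  expect_equal(annotate_variants(v5, list(fx$gene), fx$genome)$effect_class,
               "start_lost")
})

test_that("variants far from genes are intergenic; REF mismatches error", {
  fx <- toy_coding_gene(toy_cds, offset = 100, flank = 600)
  far <- 100 + nchar(toy_cds) + 500
  ref <- substr(fx$genome$chromosomes$sequence, far, far)
  ann <- annotate_variants(
    tibble::tibble(chrom = "chrI", pos = far, ref = ref,
                   alt = setdiff(c("A", "C", "G", "T"), ref)[1]),
    list(fx$gene), fx$genome)
  expect_equal(ann$effect_class, "intergenic")
  expect_true(is.na(ann$gene_id))
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(
    annotate_variants(tibble::tibble(chrom = "chrI", pos = far, ref = wrong,
                                     alt = ref),
                      list(fx$gene), fx$genome),
    "REF mismatch.*chrI:")
})

test_that("splice-site window covers the first/last 2 intron bases only", {
  g <- toy_genome(n_chrom = 1, len = 2000, seed = 33)
  gene <- gene_model("sp1", "chrI", "+",
                     exons = data.frame(start = c(101, 401),
                                        end = c(250, 550)),
                     cds = data.frame(start = c(101, 401),
                                      end = c(250, 550)))
  at <- function(pos) {
    ref <- substr(g$chromosomes$sequence, pos, pos)
    annotate_variants(
      tibble::tibble(chrom = "chrI", pos = pos, ref = ref,
                     alt = setdiff(c("A", "C", "G", "T"), ref)[1]),
      list(gene), g)$effect_class
  }
  expect_equal(at(251), "splice_site")  # donor +1
  expect_equal(at(252), "splice_site")  # donor +2
  expect_equal(at(253), "intronic")
  expect_equal(at(300), "intronic")
  expect_equal(at(398), "intronic")
  expect_equal(at(399), "splice_site")  # acceptor -2
  expect_equal(at(400), "splice_site")  # acceptor -1
})

test_that("every CDS SNV matches the full-translation oracle on both strands", {
  set.seed(97)
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  body <- paste(sample(codons, 98, replace = TRUE), collapse = "")
  cds300 <- paste0("ATG", body, "TAA")  # 300 bp, internal-stop-free
  for (strand in c("+", "-")) {
    fx <- toy_coding_gene(cds300, offset = 50, strand = strand,
                          gene_id = paste0("g", strand))
    enum <- enumerate_cds_effects(fx$gene, fx$genome)
    expect_equal(nrow(enum), 900)
    want <- oracle_effect_genomic_batch(fx$gene,
                                        fx$genome$chromosomes$sequence,
                                        enum$pos, enum$alt)
    expect_identical(enum$effect_class, want)
    counts <- table(enum$effect_class)
    counts <- counts[order(names(counts))]
    if (strand == "+") fwd_classes <- counts
    if (strand == "-") {
      # strand symmetry: same class multiset either way round
      expect_identical(counts, fwd_classes)
    }
  }
})

test_that("a premature stop in the third exon is classed nonsense", {
  # three-exon gene; the W codon TGG sits wholly in exon 3, and G->A at its
  # third base creates a premature stop
  ex1 <- "ATGGCTAAA"  # M A K
  ex2 <- "CCCGGGACT"  # P G T
  ex3 <- "TGGTTTCATTAA"  # W F H *
  set.seed(61)
  fill <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  seq <- paste0(fill(100), ex1, fill(80), ex2, fill(80), ex3, fill(100))
  s1 <- 101; e1 <- s1 + 8
  s2 <- e1 + 81; e2 <- s2 + 8
  s3 <- e2 + 81; e3 <- s3 + 11
  genome <- genome_from_seq(seq)
  gene <- gene_model("usp48_toy", "chrI", "+",
                     exons = data.frame(start = c(s1, s2, s3),
                                        end = c(e1, e2, e3)),
                     cds = data.frame(start = c(s1, s2, s3),
                                      end = c(e1, e2, e3)))
  stop_pos <- s3 + 2  # third base of the TGG codon in exon 3
  ann <- annotate_variants(
    tibble::tibble(chrom = "chrI", pos = stop_pos, ref = "G", alt = "A"),
    list(gene), genome)
  expect_equal(ann$effect_class, "nonsense")
  expect_equal(ann$protein_change, "W7*")
})

test_that("candidate ranking keeps interval hits ordered by severity", {
  ann <- tibble::tibble(
    chrom = "chrI", pos = c(10, 20, 30, 40, 50),
    ref = "A", alt = "G", gene_id = "g",
    effect_class = c("synonymous", "nonsense", "missense", "intronic",
                     "nonsense"),
    protein_change = NA_character_)
  iv <- tibble::tibble(chrom = "chrI", start = 15, end = 45)
  ranked <- prioritize_candidates(ann, iv)
  expect_equal(ranked$pos, c(20, 30, 40))
  expect_equal(ranked$effect_class[1], "nonsense")
  iv0 <- tibble::tibble(chrom = "chrII", start = 1, end = 5)
  expect_message(out <- prioritize_candidates(ann, iv0), "no candidate")
  expect_equal(nrow(out), 0)
})
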