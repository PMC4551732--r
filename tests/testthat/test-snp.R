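simple_partition_inputs <- function() {
  genes <- tibble::tibble(
    gene_id = "g1", scaffold = "s1", start = 2000L, end = 2300L,
    strand = "+", coding = TRUE,
    cds = list(tibble::tibble(start = 2000L, end = 2300L)))
  scaffolds <- tibble::tibble(id = "s1", length = 10000L)
  dip <- tibble::tibble(scaffold = "s1", start = 0L, end = 10000L)
  list(genes = genes, scaffolds = scaffolds, dip = dip)
}

test_that("partition assigns a single-exon gene and the rest intergenic", {
  x <- simple_partition_inputs()
  part <- partition_regions(x$genes, tibble::tibble(
    scaffold = character(), start = integer(), end = integer()),
    x$scaffolds, x$dip)
  lens <- tapply(part$end - part$start, part$class, sum)
  expect_equal(unname(lens[["exon"]]), 300)
  expect_equal(unname(lens[["intergenic"]]), 9700)
  expect_equal(sum(part$end - part$start), 10000)
})

test_that("precedence: exon beats repeat; intron beats repeat", {
  x <- simple_partition_inputs()
  # gene with an intron, repeat overlapping both exon and intergenic
  x$genes$cds <- list(tibble::tibble(start = c(2000L, 2200L),
                                     end = c(2100L, 2300L)))
  reps <- tibble::tibble(scaffold = "s1", start = 2050L, end = 2500L)
  part <- partition_regions(x$genes, reps, x$scaffolds, x$dip)
  lens <- tapply(part$end - part$start, part$class, sum)
  expect_equal(unname(lens[["exon"]]), 200)
  expect_equal(unname(lens[["intron"]]), 100)
  expect_equal(unname(lens[["repeat"]]), 200)   # 2300..2500 only
  expect_equal(sum(part$end - part$start), 10000)
  expect_error(partition_regions(
    dplyr::mutate(x$genes, scaffold = "nope"), reps, x$scaffolds, x$dip),
    "unknown scaffold")
})

test_that("window_rates anchors windows inside class intervals", {
  part <- tibble::tibble(scaffold = "s1", start = 0L, end = 3000L,
                         class = "intergenic")
  snps <- tibble::tibble(scaffold = "s1", pos = seq(0L, 999L, 100L))
  wr <- window_rates(snps, part, window = 1000L, step = 500L)
  expect_equal(wr$rate[1], 0.01)     # 10 SNPs in the first kb
  expect_equal(wr$start, seq(0L, 2000L, 500L))
  # interval shorter than the window emits nothing
  short <- tibble::tibble(scaffold = "s1", start = 0L, end = 900L,
                          class = "exon")
  expect_equal(nrow(window_rates(snps, short)), 0)
  # non-overlapping windows conserve the SNP count
  wr2 <- window_rates(snps, part, window = 1000L, step = 1000L)
  expect_equal(sum(wr2$rate * 1000), nrow(snps))
})

test_that("snp_free_segments splits at SNPs and reports the max", {
  dip <- tibble::tibble(scaffold = "s1", start = 0L, end = 5000L)
  none <- snp_free_segments(tibble::tibble(scaffold = character(),
                                           pos = integer()), dip)
  expect_equal(none$segments$length, 5000L)
  expect_equal(none$max_length, 5000L)

  one <- snp_free_segments(tibble::tibble(scaffold = "s1", pos = 1500L),
                           dip, min_len = 1000L)
  expect_equal(one$segments$start, c(0L, 1501L))
  expect_equal(one$segments$end, c(1500L, 5000L))
  expect_equal(one$max_length, 3499L)

  # planted free blocks are recovered
  tr <- toy_diploid()   # SNPs only in [5000, 10000)
  snps <- tibble::tibble(scaffold = "s1", pos = tr$snp_positions)
  segs <- snp_free_segments(snps, tibble::tibble(
    scaffold = "s1", start = 0L, end = 20000L), min_len = 1000L)
  expect_true(any(segs$segments$start == 0 & segs$segments$end == 5000))
  expect_equal(segs$max_length, 20000L - 10000L + 39L)
})

test_that("snp effect classification handles both strands", {
  g <- toy_gene("ATGGCTTAA", strand = "+")
  # ATG -> ATA is M -> I
  snp <- list(scaffold = "s1", pos = 12L, ref = substring(
    g$assembly$sequence, 13, 13), alt = "A")
  expect_equal(as.character(classify_snp_effect(snp, g$gene[1, ],
                                                g$assembly$sequence)),
               "nonsynonymous")
  # GCT -> GCC is A -> A
  snp2 <- list(scaffold = "s1", pos = 15L, ref = substring(
    g$assembly$sequence, 16, 16), alt = "C")
  eff2 <- classify_snp_effect(snp2, g$gene[1, ], g$assembly$sequence)
  expect_equal(as.character(eff2), "synonymous")
  expect_equal(attr(eff2, "aa_pos"), 1L)

  # same codons on the minus strand
  gm <- toy_gene("ATGGCTTAA", strand = "-")
  # genomic base at CDS coding position 2 (wobble of codon 1)
  genomic_pos <- gm$gene$end - 1L - 2L
  ref <- substring(gm$assembly$sequence, genomic_pos + 1, genomic_pos + 1)
  alt <- revcomp("A")   # ATG -> ATA on the coding strand
  effm <- classify_snp_effect(
    list(scaffold = "s1", pos = genomic_pos, ref = ref, alt = alt),
    gm$gene[1, ], gm$assembly$sequence)
  expect_equal(as.character(effm), "nonsynonymous")

  # REF inconsistency is an error; outside CDS is noncoding
  bad <- list(scaffold = "s1", pos = 12L,
              ref = setdiff(c("A", "C", "G", "T"),
                            substring(g$assembly$sequence, 13, 13))[1],
              alt = "A")
  expect_error(classify_snp_effect(bad, g$gene[1, ],
                                   g$assembly$sequence), "REF")
  out <- list(scaffold = "s1", pos = 2L,
              ref = substring(g$assembly$sequence, 3, 3), alt = "A")
  expect_equal(as.character(classify_snp_effect(out, g$gene[1, ],
                                                g$assembly$sequence)),
               "noncoding")
})

test_that("substitution_profiles applies disorder masks", {
  g <- toy_gene(paste0("ATG", strrep("GCT", 8), "TAA"), strand = "+")
  seqs <- g$assembly$sequence
  # nonsyn SNP at aa 1 (GCT -> CCT, A -> P) and aa 5
  p1 <- g$gene$start + 3L
  p5 <- g$gene$start + 15L
  snps <- tibble::tibble(
    scaffold = "s1", pos = c(p1, p5),
    ref = substring(seqs, c(p1, p5) + 1, c(p1, p5) + 1),
    alt = "C")
  stopifnot(all(snps$ref == "G"))
  masks <- tibble::tibble(protein_id = "g1", start_aa = 4L, end_aa = 7L)
  pr <- substitution_profiles(snps, g$gene, g$assembly, masks)
  expect_equal(pr$length, 10L)
  expect_equal(pr$n_sub, 2L)
  expect_equal(pr$ordered_length, 7L)
  expect_equal(pr$disordered_length, 3L)
  expect_equal(pr$n_sub_ordered, 1L)   # aa 5 is inside the mask
  expect_equal(pr$ordered_length + pr$disordered_length, pr$length)

  # zero nonsynonymous SNPs
  pr0 <- substitution_profiles(snps[0, ], g$gene, g$assembly, masks)
  expect_equal(pr0$n_sub, 0L)
})

test_that("coding regions carry fewer SNPs than noncoding on genomes
           simulated with that property", {
  # genome where a central 'coding' third has 5x lower SNP rate
  signs <- 0
  for (s in 1:6) {
    hap1 <- lepcompgen:::with_seed(s, lepcompgen:::random_dna(30000))
    rate <- c(rep(0.02, 10000), rep(0.004, 10000), rep(0.02, 10000))
    is_snp <- lepcompgen:::with_seed(100 + s,
                                     stats::runif(30000) < rate)
    snps <- tibble::tibble(scaffold = "s1", pos = which(is_snp) - 1L)
    part <- tibble::tibble(scaffold = "s1",
                           start = c(0L, 10000L, 20000L),
                           end = c(10000L, 20000L, 30000L),
                           class = c("intergenic", "exon", "intergenic"))
    wr <- window_rates(snps, part)
    m <- tapply(wr$rate, wr$region_class, mean)
    signs <- signs + (m[["exon"]] < m[["intergenic"]])
  }
  expect_equal(signs, 6)
})
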