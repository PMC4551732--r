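test_that("simulate_diploid validates inputs and is deterministic", {
  expect_error(simulate_diploid(-5), "positive")
  expect_error(simulate_diploid(1000, free_fraction = 1), "free_fraction")
  a <- simulate_diploid(20000, seed = 3)
  b <- simulate_diploid(20000, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, simulate_diploid(20000, seed = 4)))
})

test_that("snp_positions are exactly the mismatching sites", {
  tr <- simulate_diploid(30000, free_fraction = 0.2, seed = 11)
  h1 <- strsplit(tr$hap1, "")[[1]]
  h2 <- strsplit(tr$hap2, "")[[1]]
  expect_identical(tr$snp_positions, which(h1 != h2) - 1L)
  # free blocks contain no SNPs
  bt <- tr$block_table[tr$block_table$rate_class == "free", ]
  for (i in seq_len(nrow(bt))) {
    expect_equal(sum(tr$snp_positions >= bt$start[i] &
                       tr$snp_positions < bt$end[i]), 0)
  }
  # blocks tile the genome
  expect_equal(tr$block_table$start[-1],
               tr$block_table$end[-nrow(tr$block_table)])
  expect_equal(max(tr$block_table$end), 30000L)
})

test_that("single-component genome realizes the target SNP rate", {
  L <- 1e6
  tr <- simulate_diploid(L, mix_weights = 1, mix_means = 0.025,
                         mix_sds = 0.003, free_fraction = 0,
                         block_len_mean = 5000, seed = 7)
  rate <- length(tr$snp_positions) / L
  # variance: per-site binomial + between-block rate draws (geometric
  # block lengths: E[len^2] ~ 2 mean^2)
  n_blocks <- L / 5000
  se <- sqrt(0.025 * 0.975 / L + 0.003^2 * (2 * 5000^2 * n_blocks) / L^2)
  expect_lt(abs(rate - 0.025), 3 * se)
})

test_that("simulate_reads bookkeeping, errors, determinism", {
  tr <- simulate_diploid(100000, seed = 1)
  rd <- simulate_reads(tr, depth = 60, read_len = 100, seed = 2)
  expect_equal(sum(rd$length), 6e6, tolerance = 0.01)
  expect_error(simulate_reads(tr, 10, read_len = 2e5), "exceeds")
  expect_identical(rd, simulate_reads(tr, depth = 60, read_len = 100,
                                      seed = 2))
  # reads are substrings of one of the haplotypes
  expect_true(all(vapply(rd$sequence[1:20], function(s)
    grepl(s, tr$hap1, fixed = TRUE) || grepl(s, tr$hap2, fixed = TRUE),
    logical(1))))
})

test_that("split assembly emits exactly the planted haplotigs", {
  tr <- toy_diploid()
  # threshold above any realized rate: nothing splits
  sa0 <- simulate_split_assembly(tr, het_split_threshold = 1.0, seed = 1)
  expect_equal(nrow(sa0$truth_merges), 0)
  expect_equal(nrow(sa0$assembly), 1)

  sa <- simulate_split_assembly(tr, het_split_threshold = 0.01, seed = 1)
  expect_equal(nrow(sa$truth_merges), 1)
  expect_equal(sa$truth_merges$target_start, 5000L)
  expect_equal(sa$truth_merges$target_end, 10000L)
  hap <- sa$assembly[sa$assembly$id == sa$truth_merges$haplotig_id, ]
  expect_equal(hap$length, 5000L)
  expect_equal(hap$sequence, substring(tr$hap2, 5001, 10000))

  # haplotig coverage is about half of the primary scaffold's full-depth
  # context
  sd <- sa$scaffold_depths
  prim <- sd$mean_depth[sd$scaffold == "scaffold_1"]
  expect_equal(sd$mean_depth[sd$scaffold == hap$id] / 60, 0.5,
               tolerance = 0.1)
  expect_gt(prim, sd$mean_depth[sd$scaffold == hap$id])
})

test_that("inversion operator reverses order, flips strands, involutes", {
  g <- list(s1 = tibble::tibble(
    family_id = paste0("g", 1:6),
    strand = c("+", "+", "-", "+", "-", "-")))
  inv <- invert_segment(g, "s1", 3, 3)   # genes g3..g5
  expect_equal(inv$s1$family_id, c("g1", "g2", "g5", "g4", "g3", "g6"))
  expect_equal(inv$s1$strand, c("+", "+", "+", "-", "+", "-"))
  expect_equal(invert_segment(inv, "s1", 3, 3), g)
})

test_that("translocation and duplication operators are verifiable", {
  g <- list(s1 = tibble::tibble(family_id = paste0("a", 1:4),
                                strand = rep("+", 4)),
            s2 = tibble::tibble(family_id = paste0("b", 1:3),
                                strand = rep("-", 3)))
  tl <- translocate_segment(g, "s1", 2, 2, "s2", 1)
  expect_equal(tl$s1$family_id, c("a1", "a4"))
  expect_equal(tl$s2$family_id, c("b1", "a2", "a3", "b2", "b3"))
  # inverse translocation restores the parent
  back <- translocate_segment(tl, "s2", 2, 2, "s1", 1)
  expect_equal(back, g)

  dup <- duplicate_gene(g, "s2", 2)
  expect_equal(dup$s2$family_id, c("b1", "b2", "b2", "b3"))
})

test_that("zero rates reproduce the ancestor in every species", {
  got <- simulate_gene_orders(trad_tree(), n_families = 40,
                              n_scaffolds = 3, inversion_rate = 0,
                              seed = 5)
  per_sp <- split(got$genes, got$genes$species)
  ref <- per_sp[[1]][order(per_sp[[1]]$scaffold, per_sp[[1]]$index), ]
  for (g in per_sp) {
    g <- g[order(g$scaffold, g$index), ]
    expect_equal(g$family_id, ref$family_id)
    expect_equal(g$strand, ref$strand)
  }
  expect_equal(nrow(got$event_log), 0)
})

test_that("gene-order simulation is deterministic and caps duplications", {
  tr <- trad_tree()
  a <- simulate_gene_orders(tr, n_families = 60, n_scaffolds = 4,
                            inversion_rate = 3, dup_rate = 2, seed = 9)
  b <- simulate_gene_orders(tr, n_families = 60, n_scaffolds = 4,
                            inversion_rate = 3, dup_rate = 2, seed = 9)
  expect_identical(a$genes, b$genes)
  copies <- dplyr::count(a$genes, species, family_id)
  expect_lte(max(copies$n), 5)
  expect_error(simulate_gene_orders(ape::read.tree(text = "(A,B);"), 10),
               "3 leaves")
})

test_that("substitution profiles realize the planted effect", {
  got <- simulate_sub_profiles(2000, mean_len = 400, p0 = 0.003,
                               enriched_fraction = 0.1, effect_mult = 5,
                               disorder_fraction = 0, disorder_mult = 1,
                               seed = 13)
  pr <- got$profiles
  enr <- pr$protein_id %in% got$enriched_ids
  m_e <- mean(pr$n_sub[enr]); m_0 <- mean(pr$n_sub[!enr])
  # law of large numbers: ratio of mean counts near the 5x effect
  se <- sqrt(stats::var(pr$n_sub[enr]) / sum(enr)) / m_0
  expect_lt(abs(m_e / m_0 - 5), 3 * se + 5 * sqrt(stats::var(
    pr$n_sub[!enr]) / sum(!enr)) / m_0)
  expect_true(all(pr$n_sub <= pr$length))
  expect_equal(pr$ordered_length + (pr$disorder_end - pr$disorder_start),
               pr$length)

  null <- simulate_sub_profiles(100, enriched_fraction = 0, seed = 1)
  expect_length(null$enriched_ids, 0)
})
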