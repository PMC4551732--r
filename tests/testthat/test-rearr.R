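toy_table <- function(...) {
  # rows: species, family, scaffold, strand (gene ids auto-numbered)
  rows <- list(...)
  tibble::tibble(
    species = vapply(rows, `[[`, character(1), 1),
    family_id = vapply(rows, `[[`, character(1), 2),
    scaffold = vapply(rows, `[[`, character(1), 3),
    strand = vapply(rows, `[[`, character(1), 4),
    gene_id = paste0("g", seq_along(rows)),
    start = (seq_along(rows) - 1L) * 1000L)
}

test_that("filter_families enforces universality and the copy cap", {
  tab <- dplyr::bind_rows(
    tidyr::expand_grid(species = c("A", "B"), family_id = "f_ok",
                       scaffold = "s", strand = "+"),
    tidyr::expand_grid(species = c("A", "B"), family_id = "f_four",
                       scaffold = "s", strand = "+",
                       copy = 1:4),
    tidyr::expand_grid(species = "A", family_id = "f_five",
                       scaffold = "s", strand = "+", copy = 1:5),
    tibble::tibble(species = "B", family_id = "f_five",
                   scaffold = "s", strand = "+", copy = 1L),
    tibble::tibble(species = "A", family_id = "f_notB",
                   scaffold = "s", strand = "+"))
  tab$gene_id <- paste0("g", seq_len(nrow(tab)))
  kept <- unique(filter_families(tab)$family_id)
  expect_setequal(kept, c("f_ok", "f_four"))
})

test_that("orientation_state maps the four strand combinations", {
  ga <- function(st) list(gene_id = "ga", scaffold = "s1", strand = st)
  gb <- function(st) list(gene_id = "gb", scaffold = "s1", strand = st)
  expect_equal(orientation_state(ga("+"), gb("+")), "A")
  expect_equal(orientation_state(ga("-"), gb("-")), "B")
  expect_equal(orientation_state(ga("+"), gb("-")), "C")
  expect_equal(orientation_state(ga("-"), gb("+")), "D")
  off <- list(gene_id = "gb", scaffold = "s2", strand = "+")
  expect_true(is.na(orientation_state(ga("+"), off)))
  expect_error(orientation_state(ga("+"), ga("+")), "distinct")
})

test_that("resolvable_pairs needs co-scaffolding in every species", {
  tab <- toy_table(
    c("A", "f1", "s1", "+"), c("A", "f2", "s1", "+"),
    c("B", "f1", "x1", "+"), c("B", "f2", "x1", "-"))
  pr <- resolvable_pairs(tab)
  expect_equal(nrow(pr), 2)   # one pair x two species
  expect_equal(pr$state[pr$species == "A"], "A")
  expect_equal(pr$state[pr$species == "B"], "C")

  # split across scaffolds in one species: excluded
  tab2 <- toy_table(
    c("A", "f1", "s1", "+"), c("A", "f2", "s1", "+"),
    c("B", "f1", "x1", "+"), c("B", "f2", "x2", "+"))
  expect_equal(nrow(resolvable_pairs(tab2)), 0)

  # two-copy family with copies on opposite strands: unresolvable
  tab3 <- toy_table(
    c("A", "f1", "s1", "+"), c("A", "f2", "s1", "+"),
    c("A", "f2", "s1", "-"),
    c("B", "f1", "x1", "+"), c("B", "f2", "x1", "+"))
  expect_equal(nrow(resolvable_pairs(tab3)), 0)

  # two-copy family with consistent placement is resolvable
  tab4 <- toy_table(
    c("A", "f1", "s1", "+"), c("A", "f2", "s1", "-"),
    c("A", "f2", "s1", "-"),
    c("B", "f1", "x1", "+"), c("B", "f2", "x1", "-"))
  pr4 <- resolvable_pairs(tab4)
  expect_equal(unique(pr4$state), "C")
})

test_that("greedy disjoint selection follows sorted order", {
  pairs <- tibble::tibble(
    fam_a = c("f1", "f2", "f3"), fam_b = c("f2", "f3", "f4"),
    species = "A", state = "A")
  sel <- select_disjoint_pairs(pairs)
  expect_equal(sel$fam_a, c("f1", "f3"))
  expect_equal(sel$fam_b, c("f2", "f4"))
  fams <- c(sel$fam_a, sel$fam_b)
  expect_equal(anyDuplicated(fams), 0)

  disj <- tibble::tibble(fam_a = c("a", "c"), fam_b = c("b", "d"),
                         species = "A", state = "B")
  expect_equal(nrow(select_disjoint_pairs(disj)), 2)
})

test_that("hamming distances form a metric on orientation strings", {
  s <- c(sp1 = "AABB", sp2 = "ABBB", sp3 = "AABB")
  d <- hamming_distances(s)
  expect_equal(d["sp1", "sp2"], 1)
  expect_equal(d["sp1", "sp3"], 0)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(sp1 = 0, sp2 = 0, sp3 = 0))

  # triangle inequality on random matrices
  for (s in 1:5) {
    strs <- lepcompgen:::with_seed(s, vapply(1:7, function(i)
      paste(sample(c("A", "B", "C", "D"), 50, TRUE), collapse = ""),
      character(1)))
    names(strs) <- paste0("sp", 1:7)
    d <- hamming_distances(strs)
    for (i in 1:7) for (j in 1:7) for (k in 1:7) {
      expect_lte(d[i, j], d[i, k] + d[k, j])
    }
  }
})

test_that("character matrix export round-trips in relaxed PHYLIP", {
  strs <- c(long_species_name_over_ten = "ABCD", sp2 = "DCBA",
            sp3 = "AAAA")
  f <- withr::local_tempfile(fileext = ".phy")
  export_character_matrix(strs, f)
  expect_equal(readLines(f)[1], "3 4")
  back <- read_character_matrix(f)
  expect_identical(back, strs)
})

test_that("encoding is invariant to position offsets and scaffold names", {
  tab <- toy_table(
    c("A", "f1", "s1", "+"), c("A", "f2", "s1", "-"),
    c("B", "f1", "x1", "+"), c("B", "f2", "x1", "-"))
  base <- resolvable_pairs(tab)
  shifted <- dplyr::mutate(tab, start = start + 5000L)
  renamed <- dplyr::mutate(tab, scaffold = paste0("chr_", scaffold))
  expect_equal(resolvable_pairs(shifted)$state, base$state)
  expect_equal(resolvable_pairs(renamed)$state, base$state)
})

test_that("inverting a segment holding one gene of a pair flips states", {
  g <- list(s1 = tibble::tibble(
    family_id = c("f1", "f2", "f3", "f4"),
    strand = c("+", "+", "-", "+")))
  # states before: (f1,f2)=A, (f3,f4)=D
  inv <- invert_segment(g, "s1", 1, 1)   # flip f1 only
  expect_equal(state_a <- lepcompgen:::state_from_strands(
    inv$s1$strand[inv$s1$family_id == "f1"],
    inv$s1$strand[inv$s1$family_id == "f2"]), "D")   # A -> D
  inv2 <- invert_segment(g, "s1", 3, 1)  # flip f3 only
  expect_equal(lepcompgen:::state_from_strands(
    inv2$s1$strand[inv2$s1$family_id == "f3"],
    inv2$s1$strand[inv2$s1$family_id == "f4"]), "A")  # D -> A
  # flipping the second member instead maps A -> C
  inv3 <- invert_segment(g, "s1", 2, 1)
  expect_equal(lepcompgen:::state_from_strands(
    inv3$s1$strand[inv3$s1$family_id == "f1"],
    inv3$s1$strand[inv3$s1$family_id == "f2"]), "C")
})

test_that("end-to-end pipeline recovers the generating topology", {
  tr <- trad_tree()
  ok <- 0
  for (s in 101:105) {
    g <- simulate_gene_orders(tr, n_families = 2000, n_scaffolds = 16,
                              inversion_rate = 5.5, seg_len_mean = 8,
                              seed = s)
    res <- rearrangement_tree(g$genes)
    expect_gte(res$n_pairs_resolvable, 300)
    ok <- ok + (rf_distance(res$tree, tr) == 0)
  }
  expect_gte(ok, 4)
})
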