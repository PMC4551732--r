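#' Simulate a diploid genome with block-structured heterozygosity
#'
#' The genome is tiled by blocks of geometric length. A fraction of blocks
#' is SNP-free (identity-by-descent); each remaining block draws a per-site
#' SNP probability from a one- or two-component Gaussian mixture (truncated
#' at 0 by resampling) and sites differ between the two haplotypes by
#' independent Bernoulli draws at that rate. This reproduces the observed
#' structure of highly heterozygous butterfly genomes: a low-rate
#' within-population component, a high-rate gene-flow component, and long
#' SNP-free runs.
#'
#' @param length_bp Genome length in bp.
#' @param mix_weights Mixture weights (sum to 1; default equal weights,
#'   matched to the length of `mix_means`).
#' @param mix_means,mix_sds Component means and SDs of the per-site SNP
#'   rate (defaults 0.35 % and 2.5 %, the two observed regimes).
#' @param free_fraction Fraction of blocks that are SNP-free, in `[0, 1)`.
#' @param block_len_mean Mean block length in bp (geometric).
#' @param seed Integer seed; the result is a deterministic function of it.
#' @return A list of class `diploid_truth`: `hap1`, `hap2` (DNA strings),
#'   `snp_positions` (0-based integer vector), `block_table` (tibble with
#'   `start`, `end`, `rate_class` in `{free, low, high}` — component index
#'   for >2 components — and the drawn `rate`).
#' @export
simulate_diploid <- function(length_bp,
                             mix_weights = NULL,
                             mix_means = c(0.0035, 0.025),
                             mix_sds = c(0.001, 0.004),
                             free_fraction = 0.1,
                             block_len_mean = 5000,
                             seed = 1) {
  if (length_bp <= 0) stop("length_bp must be positive")
  k <- length(mix_means)
  if (is.null(mix_weights)) mix_weights <- rep(1 / k, k)
  stopifnot(length(mix_weights) == k, length(mix_sds) == k,
            abs(sum(mix_weights) - 1) < 1e-9, all(mix_means > 0),
            all(mix_sds > 0), free_fraction >= 0, free_fraction < 1,
            block_len_mean >= 1)
  with_seed(seed, {
    # tile the genome with geometric-length blocks
    n_guess <- ceiling(length_bp / block_len_mean * 3) + 10
    lens <- stats::rgeom(n_guess, 1 / block_len_mean) + 1L
    while (sum(lens) < length_bp) {
      lens <- c(lens, stats::rgeom(n_guess, 1 / block_len_mean) + 1L)
    }
    ends <- cumsum(lens)
    lens <- lens[seq_len(which(ends >= length_bp)[1])]
    lens[length(lens)] <- length_bp - sum(lens[-length(lens)])
    lens <- lens[lens > 0]
    nb <- length(lens)
    starts <- cumsum(c(0L, lens[-nb]))

    free <- stats::runif(nb) < free_fraction
    comp <- sample.int(k, nb, replace = TRUE, prob = mix_weights)
    rate <- numeric(nb)
    for (i in which(!free)) {
      r <- stats::rnorm(1, mix_means[comp[i]], mix_sds[comp[i]])
      while (r <= 0) r <- stats::rnorm(1, mix_means[comp[i]],
                                       mix_sds[comp[i]])
      rate[i] <- r
    }
    cls <- ifelse(free, "free",
                  if (k == 2) c("low", "high")[comp]
                  else paste0("comp", comp))

    hap1 <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
    site_rate <- rep(rate * !free, times = lens)
    is_snp <- stats::runif(length_bp) < site_rate
    hap2 <- hap1
    if (any(is_snp)) {
      # alt base drawn uniformly from the three non-reference bases
      idx <- which(is_snp)
      alt <- vapply(hap1[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      hap2[idx] <- alt
    }
    structure(list(
      hap1 = paste(hap1, collapse = ""),
      hap2 = paste(hap2, collapse = ""),
      snp_positions = which(is_snp) - 1L,
      block_table = tibble(start = starts, end = starts + lens,
                           rate_class = cls, rate = rate)
    ), class = "diploid_truth")
  })
}

#' Simulate uniform-coverage error-free reads from a diploid genome
#'
#' Reads start uniformly along the genome and come from either haplotype
#' with probability 1/2, so each haplotype is covered at `depth / 2`.
#'
#' @param truth A `diploid_truth` from [simulate_diploid()].
#' @param depth Total target depth (both haplotypes).
#' @param read_len Read length in bp; must not exceed the genome length.
#' @param seed Integer seed.
#' @return Tibble with `id`, `sequence`, `length`, one row per read.
#' @export
simulate_reads <- function(truth, depth, read_len, seed = 1) {
  stopifnot(inherits(truth, "diploid_truth"), depth > 0)
  glen <- nchar(truth$hap1)
  if (read_len > glen) stop("read_len exceeds genome length")
  n_reads <- round(depth * glen / read_len)
  with_seed(seed, {
    starts <- sample.int(glen - read_len + 1L, n_reads, replace = TRUE)
    hap <- stats::runif(n_reads) < 0.5
    seqs <- character(n_reads)
    seqs[hap] <- substring(truth$hap1, starts[hap],
                           starts[hap] + read_len - 1L)
    seqs[!hap] <- substring(truth$hap2, starts[!hap],
                            starts[!hap] + read_len - 1L)
    tibble(id = paste0("read_", seq_len(n_reads)), sequence = seqs,
           length = read_len)
  })
}

#' Simulate an assembly in which high-heterozygosity blocks split into
#' haplotigs
#'
#' Blocks of the diploid truth whose realized SNP rate exceeds
#' `het_split_threshold` are emitted twice: the first-haplotype copy stays
#' embedded in the long primary scaffold, while the second-haplotype copy
#' becomes a standalone scaffold (a haplotig). Reads from the two
#' haplotypes then map separately, so both copies of a split block receive
#' about half coverage while the rest of the primary scaffold keeps full
#' coverage. Optional decoy scaffolds (unrelated sequence at half depth)
#' exercise the specificity of downstream merging.
#'
#' @param truth A `diploid_truth`.
#' @param het_split_threshold Realized SNP-rate above which a block splits.
#' @param depth Full diploid read depth used for the coverage track.
#' @param window Coverage window size in bp.
#' @param n_decoys Number of unrelated half-depth decoy scaffolds.
#' @param decoy_len Length of each decoy in bp.
#' @param seed Integer seed.
#' @return List: `assembly` (tibble `id`, `sequence`, `length`),
#'   `coverage` (tibble `scaffold`, `start`, `end`, `depth` in `window`-bp
#'   windows), `scaffold_depths` (tibble `scaffold`, `length`,
#'   `mean_depth`), and `truth_merges` (tibble `haplotig_id`, `target_id`,
#'   `target_start`, `target_end`).
#' @export
simulate_split_assembly <- function(truth, het_split_threshold = 0.015,
                                    depth = 60, window = 100L,
                                    n_decoys = 0L, decoy_len = 3000L,
                                    seed = 1) {
  stopifnot(inherits(truth, "diploid_truth"))
  glen <- nchar(truth$hap1)
  bt <- truth$block_table
  pos <- truth$snp_positions
  nsnp <- vapply(seq_len(nrow(bt)), function(i)
    sum(pos >= bt$start[i] & pos < bt$end[i]), integer(1))
  realized <- nsnp / (bt$end - bt$start)
  split <- realized > het_split_threshold

  with_seed(seed, {
    asm <- tibble(id = "scaffold_1", sequence = truth$hap1,
                  length = glen)
    tm <- tibble(haplotig_id = character(), target_id = character(),
                 target_start = integer(), target_end = integer())
    if (any(split)) {
      ids <- paste0("haplotig_", seq_len(sum(split)))
      seqs <- substring(truth$hap2, bt$start[split] + 1L, bt$end[split])
      asm <- dplyr::bind_rows(asm,
        tibble(id = ids, sequence = seqs, length = nchar(seqs)))
      tm <- tibble(haplotig_id = ids, target_id = "scaffold_1",
                   target_start = bt$start[split],
                   target_end = bt$end[split])
    }
    if (n_decoys > 0) {
      asm <- dplyr::bind_rows(asm, tibble(
        id = paste0("decoy_", seq_len(n_decoys)),
        sequence = vapply(seq_len(n_decoys),
                          function(i) random_dna(decoy_len), character(1)),
        length = decoy_len))
    }

    # coverage: half depth inside split blocks and on haplotigs/decoys
    cov <- lapply(seq_len(nrow(asm)), function(i) {
      sl <- asm$length[i]
      st <- seq(0L, sl - 1L, by = window)
      en <- pmin(st + window, sl)
      base <- if (asm$id[i] == "scaffold_1") depth else depth / 2
      d <- rep(base, length(st))
      if (asm$id[i] == "scaffold_1" && any(split)) {
        for (j in which(split)) {
          hit <- st < bt$end[j] & en > bt$start[j]
          d[hit] <- depth / 2
        }
      }
      d <- pmax(0, d + stats::rnorm(length(st), 0, sqrt(base) / 2))
      tibble(scaffold = asm$id[i], start = st, end = en, depth = d)
    })
    cov <- dplyr::bind_rows(cov)
    sd_tbl <- cov %>%
      dplyr::group_by(scaffold = .data$scaffold) %>%
      dplyr::summarise(mean_depth = sum(.data$depth *
                                          (.data$end - .data$start)) /
                         sum(.data$end - .data$start),
                       .groups = "drop") %>%
      dplyr::left_join(asm %>% dplyr::select("id", "length"),
                       by = c(scaffold = "id"))
    list(assembly = asm, coverage = cov, scaffold_depths = sd_tbl,
         truth_merges = tm)
  })
}

# ---- gene-order evolution operators ---------------------------------------

#' Gene-order rearrangement operators
#'
#' A genome here is a named list of scaffolds, each a tibble with columns
#' `family_id` and `strand`. `invert_segment()` reverses the gene order of
#' a contiguous segment and flips its strands; applying the same inversion
#' twice restores the input. `translocate_segment()` moves a segment to a
#' position on another (or the same) scaffold. `duplicate_gene()` copies
#' one gene in place.
#'
#' @param genome Named list of scaffold tibbles (`family_id`, `strand`).
#' @param scaffold,from,to Scaffold names.
#' @param start 1-based index of the first gene of the segment.
#' @param len Number of genes in the segment.
#' @param at Insertion point on the target scaffold: the segment is placed
#'   after gene `at` (0 = at the front).
#' @param idx Index of the gene to duplicate.
#' @return The modified genome.
#' @export
invert_segment <- function(genome, scaffold, start, len) {
  s <- genome[[scaffold]]
  stopifnot(start >= 1, start + len - 1 <= nrow(s))
  sel <- start:(start + len - 1)
  seg <- s[rev(sel), ]
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  s[sel, ] <- seg
  genome[[scaffold]] <- s
  genome
}

#' @rdname invert_segment
#' @export
translocate_segment <- function(genome, from, start, len, to, at) {
  s <- genome[[from]]
  stopifnot(start >= 1, start + len - 1 <= nrow(s))
  sel <- start:(start + len - 1)
  seg <- s[sel, ]
  s <- s[-sel, ]
  genome[[from]] <- s
  t <- genome[[to]]
  stopifnot(at >= 0, at <= nrow(t))
  genome[[to]] <- dplyr::bind_rows(
    if (at > 0) t[1:at, ] else t[0, ], seg,
    if (at < nrow(t)) t[(at + 1):nrow(t), ] else t[0, ])
  genome
}

#' @rdname invert_segment
#' @export
duplicate_gene <- function(genome, scaffold, idx) {
  s <- genome[[scaffold]]
  stopifnot(idx >= 1, idx <= nrow(s))
  genome[[scaffold]] <- dplyr::bind_rows(
    s[seq_len(idx), ], s[idx, ],
    if (idx < nrow(s)) s[(idx + 1):nrow(s), ] else s[0, ])
  genome
}

#' Evolve gene orders along a species tree
#'
#' An ancestral arrangement of `n_families` single-copy genes across
#' `n_scaffolds` scaffolds (random order and strands) evolves along each
#' branch of `species_tree` by Poisson numbers of inversions,
#' translocations and in-place duplications (rates per unit branch
#' length). Duplications cap family size at 5 copies per species.
#'
#' @param species_tree An `ape::phylo` with branch lengths (unit lengths
#'   assumed where absent) and >= 3 leaves.
#' @param n_families Number of gene families (>= 4).
#' @param n_scaffolds Number of scaffolds.
#' @param inversion_rate,transloc_rate,dup_rate Expected events per unit
#'   branch length.
#' @param seg_len_mean Mean segment length (genes) of inversions and
#'   translocations (geometric).
#' @param seed Integer seed.
#' @return A list of class `gene_order_truth`: `species_tree`, `genes`
#'   (tibble `species`, `gene_id`, `family_id`, `scaffold`, `index`,
#'   `start`, `strand`), and `event_log` (tibble `branch`, `event`,
#'   `scaffold`, `start`, `len`).
#' @export
simulate_gene_orders <- function(species_tree, n_families = 400,
                                 n_scaffolds = 5, inversion_rate = 5,
                                 transloc_rate = 0, dup_rate = 0,
                                 seg_len_mean = 5, seed = 1) {
  stopifnot(inherits(species_tree, "phylo"))
  if (length(species_tree$tip.label) < 3) stop("tree must have >= 3 leaves")
  stopifnot(n_families >= 4, inversion_rate >= 0, transloc_rate >= 0,
            dup_rate >= 0)
  bl <- species_tree$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(species_tree$edge))

  with_seed(seed, {
    fams <- sample(paste0("fam", sprintf("%04d", seq_len(n_families))))
    chunk <- sort(rep_len(seq_len(n_scaffolds), n_families))
    anc <- lapply(seq_len(n_scaffolds), function(s) tibble(
      family_id = fams[chunk == s],
      strand = sample(c("+", "-"), sum(chunk == s), replace = TRUE)))
    names(anc) <- paste0("scf", seq_len(n_scaffolds))

    ntip <- length(species_tree$tip.label)
    root <- ntip + 1L
    states <- vector("list", ntip + species_tree$Nnode)
    states[[root]] <- anc
    log <- list()
    # preorder edge traversal: parents before children
    ord <- order(species_tree$edge[, 1])
    ord <- ord[order(match(species_tree$edge[ord, 1],
                           c(root, species_tree$edge[, 2])))]
    for (e in ord) {
      par <- species_tree$edge[e, 1]; chd <- species_tree$edge[e, 2]
      g <- states[[par]]
      blen <- bl[e]
      ev <- c(rep("inversion", stats::rpois(1, inversion_rate * blen)),
              rep("translocation", stats::rpois(1, transloc_rate * blen)),
              rep("duplication", stats::rpois(1, dup_rate * blen)))
      if (length(ev) > 1) ev <- sample(ev)
      for (type in ev) {
        sizes <- vapply(g, nrow, integer(1))
        occ <- names(g)[sizes > 0]
        scf <- sample(occ, 1)
        n <- nrow(g[[scf]])
        if (type == "duplication") {
          idx <- sample.int(n, 1)
          fam <- g[[scf]]$family_id[idx]
          copies <- sum(vapply(g, function(s)
            sum(s$family_id == fam), integer(1)))
          if (copies >= 5) next   # family size capped at 5
          g <- duplicate_gene(g, scf, idx)
          log[[length(log) + 1]] <- tibble(branch = chd, event = type,
                                           scaffold = scf, start = idx,
                                           len = 1L)
          next
        }
        len <- min(n, 1L + stats::rgeom(1, 1 / seg_len_mean))
        start <- sample.int(n - len + 1L, 1)
        if (type == "inversion") {
          g <- invert_segment(g, scf, start, len)
        } else {
          to <- sample(names(g), 1)
          at <- sample.int(nrow(g[[to]]) + 1L, 1) - 1L
          if (to == scf && at >= start - 1 && at <= start + len - 1) {
            at <- max(0L, start - 1L)   # keep insertion point valid
          }
          g <- translocate_segment(g, scf, start, len, to, at)
        }
        log[[length(log) + 1]] <- tibble(branch = chd, event = type,
                                         scaffold = scf, start = start,
                                         len = len)
      }
      states[[chd]] <- g
    }

    genes <- lapply(seq_len(ntip), function(tip) {
      g <- states[[tip]]
      sp <- species_tree$tip.label[tip]
      dplyr::bind_rows(lapply(names(g), function(scf) {
        s <- g[[scf]]
        if (nrow(s) == 0) return(NULL)
        tibble(species = sp,
               gene_id = paste0(sp, "_", scf, "_", seq_len(nrow(s))),
               family_id = s$family_id,
               scaffold = paste0(sp, "_", scf),
               index = seq_len(nrow(s)),
               start = (seq_len(nrow(s)) - 1L) * 1000L,
               strand = s$strand)
      }))
    })
    structure(list(
      species_tree = species_tree,
      genes = dplyr::bind_rows(genes),
      event_log = if (length(log)) dplyr::bind_rows(log) else
        tibble(branch = integer(), event = character(),
               scaffold = character(), start = integer(), len = integer())
    ), class = "gene_order_truth")
  })
}

#' Simulate per-protein substitution profiles with a planted enriched set
#'
#' Substitution counts are binomial per site at base rate `p0`; a planted
#' fraction of proteins is enriched by `effect_mult`, and a contiguous
#' disordered segment of each protein accumulates substitutions at
#' `disorder_mult` times its protein's rate.
#'
#' @param n_proteins Number of proteins.
#' @param mean_len Mean protein length (aa, Poisson).
#' @param p0 Baseline per-site (per amino acid) substitution
#'   probability. The default 0.007 matches a genome with a ~1 % coding
#'   SNP rate of which about a quarter of coding SNPs are non-synonymous
#'   (3 nt/codon x 0.96 % x ~25 %).
#' @param enriched_fraction Fraction of proteins planted as enriched.
#' @param effect_mult Rate multiplier for enriched proteins.
#' @param disorder_fraction Fraction of each protein that is disordered.
#' @param disorder_mult Extra rate multiplier inside disordered segments.
#' @param seed Integer seed.
#' @return A list of class `sub_profile_truth`: `profiles` (tibble
#'   `protein_id`, `length`, `disorder_start`, `disorder_end` (0-based
#'   half-open aa), `ordered_length`, `n_sub`, `n_sub_ordered`) and
#'   `enriched_ids` (character vector).
#' @export
simulate_sub_profiles <- function(n_proteins, mean_len = 400, p0 = 0.007,
                                  enriched_fraction = 0.05, effect_mult = 5,
                                  disorder_fraction = 0.2,
                                  disorder_mult = 2, seed = 1) {
  stopifnot(n_proteins >= 1, p0 > 0, p0 < 1, effect_mult > 0,
            enriched_fraction >= 0, enriched_fraction <= 1,
            disorder_fraction >= 0, disorder_fraction < 1)
  with_seed(seed, {
    ids <- paste0("prot", sprintf("%05d", seq_len(n_proteins)))
    len <- pmax(50L, stats::rpois(n_proteins, mean_len))
    n_enr <- round(enriched_fraction * n_proteins)
    enr <- if (n_enr > 0) sample(ids, n_enr) else character()
    rate <- ifelse(ids %in% enr, p0 * effect_mult, p0)
    dlen <- round(disorder_fraction * len)
    dstart <- vapply(len - dlen, function(m) sample.int(m + 1L, 1) - 1L,
                     integer(1))
    olen <- len - dlen
    m_ord <- stats::rbinom(n_proteins, olen, pmin(1, rate))
    m_dis <- stats::rbinom(n_proteins, dlen, pmin(1, rate * disorder_mult))
    structure(list(
      profiles = tibble(protein_id = ids, length = len,
                        disorder_start = dstart,
                        disorder_end = dstart + dlen,
                        ordered_length = olen,
                        n_sub = m_ord + m_dis, n_sub_ordered = m_ord),
      enriched_ids = enr), class = "sub_profile_truth")
  })
}
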