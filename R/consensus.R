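unrooted_splits <- function(tree, ref) {
  # splits as tip-label sets normalized to the side NOT containing `ref`;
  # trivial splits (singletons / complements) are dropped
  labs <- tree$tip.label
  n <- length(labs)
  pp <- ape::prop.part(tree)
  out <- character()
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(sort(side), collapse = "\r"))
    }
  }
  unique(out)
}

#' Majority-rule consensus of a tree sample
#'
#' Retains exactly the bipartitions present in more than `threshold` of
#' the input trees (strict, so a split in exactly half of the trees is
#' excluded at the default 0.5); non-majority regions collapse to
#' polytomies. Split support fractions are stored as node labels.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) on one leaf set.
#' @param threshold Strict retention threshold in `[0.5, 1)`.
#' @return An unrooted `phylo` with `node.label` giving supports.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1, threshold >= 0.5, threshold < 1)
  labs <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), labs)) {
      stop("all trees must share one leaf set")
    }
  }
  ref <- labs[1]
  counts <- table(unlist(lapply(trees, unrooted_splits, ref = ref)))
  freq <- as.numeric(counts) / length(trees)
  kept <- names(counts)[freq > threshold]
  support <- freq[freq > threshold]
  sets <- lapply(strsplit(kept, "\r", fixed = TRUE), identity)

  ord <- order(lengths(sets), decreasing = TRUE)
  sets <- sets[ord]; support <- support[ord]

  # nest each split under the smallest kept set strictly containing it
  parent <- integer(length(sets))   # 0 = root
  for (i in seq_along(sets)) {
    parent[i] <- 0L
    for (j in seq_along(sets)) {
      if (j == i) next
      if (length(sets[[j]]) > length(sets[[i]]) &&
          all(sets[[i]] %in% sets[[j]])) {
        if (parent[i] == 0L ||
            length(sets[[j]]) < length(sets[[parent[i]]])) parent[i] <- j
      }
    }
  }
  build <- function(node_id, members) {
    kids <- which(parent == node_id)
    covered <- character()
    parts <- character()
    for (k in kids) {
      parts <- c(parts, paste0(build(k, sets[[k]]),
                               sprintf("%.10g", support[k]), ":1"))
      covered <- c(covered, sets[[k]])
    }
    loose <- setdiff(members, covered)
    parts <- c(parts, paste0(sort(loose), ":1"))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(build(0L, labs), ";")
  tr <- ape::read.tree(text = txt)
  ape::unroot(tr)
}

#' Robinson-Foulds distance
#'
#' Number of bipartitions present in exactly one of the two unrooted
#' trees.
#'
#' @param t1,t2 `phylo` objects on one leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Classify a 7-taxon butterfly tree against the two published topologies
#'
#' The traditional arrangement places the swallowtail lineage (Pgl)
#' closer to the nymphalid clade than the skipper (Lac):
#' `(((((Mci,Hme),Dpl),Pgl),Lac),Bmo,Pxy)`. The alternate arrangement
#' swaps Pgl and Lac: `(((((Mci,Hme),Dpl),Lac),Pgl),Bmo,Pxy)`. Anything
#' else (e.g. Pgl and Lac as sisters) is `other`.
#'
#' @param tree A `phylo` with tip labels
#'   `{Mci, Hme, Dpl, Pgl, Lac, Bmo, Pxy}`.
#' @return `"traditional"`, `"alternate"`, or `"other"`.
#' @export
topology_report <- function(tree) {
  refs <- c(
    traditional = "(((((Mci,Hme),Dpl),Pgl),Lac),Bmo,Pxy);",
    alternate = "(((((Mci,Hme),Dpl),Lac),Pgl),Bmo,Pxy);")
  need <- c("Mci", "Hme", "Dpl", "Pgl", "Lac", "Bmo", "Pxy")
  if (!setequal(tree$tip.label, need)) {
    stop("tree must have tip labels ", paste(need, collapse = ", "))
  }
  for (nm in names(refs)) {
    if (rf_distance(tree, ape::read.tree(text = refs[[nm]])) == 0) {
      return(nm)
    }
  }
  "other"
}

#' Columns consistently asserted by two alignments
#'
#' A column of the global MSA is kept iff every homology it asserts —
#' every pair of (sequence, residue-index) entries in the column — is
#' also asserted by the second input. The second input is either another
#' MSA of the same sequences or a set of pairwise aligned residue pairs.
#' Columns asserting no pair (all-gap or single-residue columns) are kept
#' vacuously.
#'
#' @param msa_global Named character vector of equal-length aligned
#'   sequences (gap `-`).
#' @param aln_local Either an MSA like `msa_global` (same names) or a
#'   tibble of pairwise aligned residues with columns `seq_a`, `pos_a`,
#'   `seq_b`, `pos_b` (0-based residue indices).
#' @return Integer vector of kept column indices (1-based).
#' @export
consistent_columns <- function(msa_global, aln_local) {
  g <- do.call(rbind, strsplit(msa_global, ""))
  rownames(g) <- names(msa_global)
  idx_g <- t(apply(g != "-", 1, cumsum))
  idx_g[g == "-"] <- NA

  if (is.character(aln_local)) {
    stopifnot(setequal(names(aln_local), names(msa_global)))
    l <- do.call(rbind, strsplit(aln_local[rownames(g)], ""))
    rownames(l) <- rownames(g)
    idx_l <- t(apply(l != "-", 1, cumsum))
    idx_l[l == "-"] <- NA
    # pos2col[s, a] = column of aln_local where sequence s has residue a
    pos2col <- lapply(rownames(g), function(s) {
      cols <- which(!is.na(idx_l[s, ]))
      stats::setNames(cols, idx_l[s, cols])
    })
    names(pos2col) <- rownames(g)
    keep <- vapply(seq_len(ncol(g)), function(cc) {
      present <- which(!is.na(idx_g[, cc]))
      if (length(present) < 2) return(TRUE)
      cols2 <- vapply(present, function(s)
        pos2col[[s]][as.character(idx_g[s, cc])], numeric(1))
      !anyNA(cols2) && length(unique(cols2)) == 1
    }, logical(1))
  } else {
    pk <- function(sa, pa, sb, pb) paste(sa, pa, sb, pb, sep = "\r")
    pairs <- unique(c(
      pk(aln_local$seq_a, aln_local$pos_a, aln_local$seq_b,
         aln_local$pos_b),
      pk(aln_local$seq_b, aln_local$pos_b, aln_local$seq_a,
         aln_local$pos_a)))
    keep <- vapply(seq_len(ncol(g)), function(cc) {
      present <- which(!is.na(idx_g[, cc]))
      if (length(present) < 2) return(TRUE)
      cmb <- utils::combn(present, 2)
      all(pk(rownames(g)[cmb[1, ]], idx_g[cbind(cmb[1, ], cc)] - 1L,
             rownames(g)[cmb[2, ]], idx_g[cbind(cmb[2, ], cc)] - 1L)
          %in% pairs)
    }, logical(1))
  }
  which(keep)
}

#' Randomly partition alignment columns into near-equal groups
#'
#' Each repetition draws a fresh uniform permutation of the columns and
#' splits it into `n_groups` contiguous chunks whose sizes differ by at
#' most one (the first `n_columns mod n_groups` chunks get the extra
#' column). With 570,686 columns and 100 groups this gives 86 groups of
#' 5,707 and 14 of 5,706 per repetition; 10 repetitions yield 1,000
#' groups in total.
#'
#' @param n_columns Number of columns.
#' @param n_groups Groups per repetition.
#' @param n_reps Repetitions.
#' @param seed Integer seed.
#' @return List of `n_groups * n_reps` integer vectors of 1-based column
#'   indices; within each repetition the groups partition all columns.
#' @export
sample_column_groups <- function(n_columns, n_groups = 100L,
                                 n_reps = 10L, seed = 1) {
  stopifnot(n_columns >= n_groups, n_groups >= 1, n_reps >= 1)
  sizes <- rep(n_columns %/% n_groups, n_groups)
  extra <- n_columns %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  with_seed(seed, {
    out <- vector("list", n_groups * n_reps)
    for (rep in seq_len(n_reps)) {
      perm <- sample.int(n_columns)
      ends <- cumsum(sizes)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      for (gidx in seq_len(n_groups)) {
        out[[(rep - 1L) * n_groups + gidx]] <-
          perm[starts[gidx]:ends[gidx]]
      }
    }
    out
  })
}
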