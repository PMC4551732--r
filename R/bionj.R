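#' BioNJ distance-based tree reconstruction
#'
#' Neighbor joining with the variance-weighted reduction of Gascuel's
#' BioNJ. Pair selection uses the standard NJ criterion
#' `Q(i,j) = (r - 2) d(i,j) - S_i - S_j`; branch lengths come from the NJ
#' two-point formulas; the reduction
#' `d(u,k) = lambda d(i,k) + (1 - lambda) d(j,k) - lambda b_i -
#' (1 - lambda) b_j` uses the lambda that minimizes the variance of the
#' reduced matrix, clamped to `[0, 1]` (plain NJ's `lambda = 1/2` when the
#' pair variance is zero). Ties in Q are broken by lexicographic
#' taxon-pair order, so the result is deterministic. On additive matrices
#' the generating tree is recovered exactly for any lambda.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal and
#'   taxon dimnames (or a `dist`).
#' @return An unrooted `ape::phylo` (trifurcating root).
#' @export
bionj <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix is not symmetric")
  }
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  D <- unname(d)
  V <- D
  # node bookkeeping: each active row carries a tree (newick fragment)
  # and a sort key (smallest descendant label) for deterministic ties
  frag <- labels
  key <- labels

  fmt <- function(x) sprintf("%.12g", x)

  while (nrow(D) > 3) {
    r <- nrow(D)
    S <- rowSums(D)
    Q <- (r - 2) * D - outer(S, S, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      k2 <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k2, collapse = "\r")
    })
    best <- cand[order(pair_key)[1], ]
    i <- best[1]; j <- best[2]

    dij <- D[i, j]
    bi <- dij / 2 + (S[i] - S[j]) / (2 * (r - 2))
    bj <- dij - bi
    vij <- V[i, j]
    others <- setdiff(seq_len(r), c(i, j))
    lambda <- if (vij > 0) {
      0.5 + sum(V[j, others] - V[i, others]) / (2 * (r - 2) * vij)
    } else 0.5
    lambda <- min(1, max(0, lambda))

    d_new <- lambda * (D[i, others] - bi) + (1 - lambda) *
      (D[j, others] - bj)
    v_new <- lambda * V[i, others] + (1 - lambda) * V[j, others] -
      lambda * (1 - lambda) * vij

    new_frag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":",
                       fmt(bj), ")")
    new_key <- min(key[i], key[j])

    keep <- others
    D2 <- D[keep, keep, drop = FALSE]
    V2 <- V[keep, keep, drop = FALSE]
    D <- rbind(cbind(D2, d_new), c(d_new, 0))
    V <- rbind(cbind(V2, v_new), c(v_new, 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }

  # final three nodes: closed-form lengths, joined at the unrooted root
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ord <- order(key)
  b <- c(b1, b2, b3)[ord]
  fr <- frag[ord]
  txt <- paste0("(", fr[1], ":", fmt(b[1]), ",", fr[2], ":", fmt(b[2]),
                ",", fr[3], ":", fmt(b[3]), ");")
  ape::read.tree(text = txt)
}
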