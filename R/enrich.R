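#' Binomial upper-tail probability
#'
#' `P[X >= m]` for `X ~ Binomial(N, p)`, computed through
#' [stats::pbinom()] (regularized incomplete beta), so it is numerically
#' stable far into the tail. `m = 0` returns exactly 1.
#'
#' @param m Observed count(s), `0 <= m <= N`.
#' @param N Number of trials.
#' @param p Success probability in `(0, 1)`.
#' @return Upper-tail probability in `(0, 1]`; vectorized over `m`, `N`.
#' @export
binomial_upper_tail <- function(m, N, p) {
  if (any(m > N)) stop("m > N")
  stopifnot(all(m >= 0), all(p > 0), all(p < 1))
  stats::pbinom(m - 1, N, p, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment with a significance flag
#'
#' Step-up BH q-values via [stats::p.adjust()]; units with `q` strictly
#' below `q_threshold` are flagged enriched (the maximal-FDR reading of
#' "Q-value smaller than 0.1").
#'
#' @param p_values Named or unnamed numeric vector of p-values.
#' @param q_threshold Strict flagging threshold on the q-value.
#' @param unit_id Optional ids (defaults to names or index).
#' @return Tibble `unit_id`, `p_value`, `q_value`, `enriched`.
#' @export
bh_fdr <- function(p_values, q_threshold = 0.1, unit_id = NULL) {
  if (is.null(unit_id)) {
    unit_id <- if (!is.null(names(p_values))) names(p_values) else
      as.character(seq_along(p_values))
  }
  q <- stats::p.adjust(p_values, method = "BH")
  tibble(unit_id = unit_id, p_value = unname(p_values),
         q_value = unname(q), enriched = unname(q) < q_threshold)
}

#' Test proteins for substitution enrichment
#'
#' The background rate is the average per-site substitution rate over all
#' proteins (total substitutions / total length) computed in the same mode
#' as the tests; each protein's count is then tested against
#' `Binomial(N_i, p_bar)` one-sided upward, followed by BH-FDR at 0.1.
#' In `ordered_only` mode, masked (disordered) positions are excluded from
#' both counts and lengths, which removes the inflation that disordered
#' segments cause.
#'
#' @param profiles Tibble with `protein_id`, `length`, `n_sub` and (for
#'   `ordered_only`) `ordered_length`, `n_sub_ordered`, as produced by
#'   [substitution_profiles()] or [simulate_sub_profiles()].
#' @param mode `"all"` or `"ordered_only"`.
#' @param q_threshold Strict BH flagging threshold.
#' @return Tibble `unit_id`, `m`, `N`, `p_value`, `q_value`, `enriched`,
#'   with the background rate as attribute `p_bar`.
#' @export
test_proteins <- function(profiles, mode = c("all", "ordered_only"),
                          q_threshold = 0.1) {
  mode <- match.arg(mode)
  if (mode == "ordered_only") {
    m <- profiles$n_sub_ordered
    N <- profiles$ordered_length
  } else {
    m <- profiles$n_sub
    N <- profiles$length
  }
  keep <- N > 0
  p_bar <- sum(m[keep]) / sum(N[keep])
  if (p_bar <= 0 || p_bar >= 1) stop("degenerate background rate: ", p_bar)
  pv <- binomial_upper_tail(m[keep], N[keep], p_bar)
  out <- bh_fdr(pv, q_threshold, unit_id = profiles$protein_id[keep])
  out <- dplyr::mutate(out, m = m[keep], N = N[keep],
                       .after = "unit_id")
  attr(out, "p_bar") <- p_bar
  out
}

#' GO-term enrichment among substitution-enriched proteins
#'
#' For each term, `P` is the fraction of universe proteins annotated with
#' it, `m` the number of enriched proteins carrying it and `N` the number
#' of enriched proteins; the binomial upper tail is BH-adjusted across
#' terms. Annotations are treated as flat sets (no propagation up the
#' ontology).
#'
#' @param enriched_ids Character vector of enriched protein ids (must be a
#'   non-empty subset of `universe_ids`).
#' @param go_annotations Tibble `protein_id`, `term_id`.
#' @param universe_ids All tested protein ids.
#' @param q_threshold Strict BH flagging threshold.
#' @return Tibble `unit_id` (term), `m`, `N`, `term_freq`, `p_value`,
#'   `q_value`, `enriched`.
#' @export
go_enrichment <- function(enriched_ids, go_annotations, universe_ids,
                          q_threshold = 0.1) {
  if (length(enriched_ids) == 0) stop("empty enriched set")
  if (!all(enriched_ids %in% universe_ids)) {
    stop("enriched set is not a subset of the universe")
  }
  ann <- go_annotations[go_annotations$protein_id %in% universe_ids, ,
                        drop = FALSE]
  ann <- dplyr::distinct(ann, .data$protein_id, .data$term_id)
  nu <- length(unique(universe_ids))
  N <- length(unique(enriched_ids))
  per_term <- ann %>%
    dplyr::group_by(term_id = .data$term_id) %>%
    dplyr::summarise(n_universe = dplyr::n(),
                     m = sum(.data$protein_id %in% enriched_ids),
                     .groups = "drop") %>%
    dplyr::mutate(term_freq = .data$n_universe / nu)
  # a term carried by every universe protein has upper tail exactly 1
  pv <- ifelse(per_term$term_freq >= 1, 1,
               binomial_upper_tail(per_term$m, N,
                                   pmin(per_term$term_freq,
                                        1 - 1e-12)))
  out <- bh_fdr(pv, q_threshold, unit_id = per_term$term_id)
  dplyr::mutate(out, m = per_term$m, N = N,
                term_freq = per_term$term_freq, .after = "unit_id")
}

#' Combine a term's enrichment significance across two species
#'
#' The combined score for a shared term is the product of its enrichment
#' p-values in the two genomes (smaller = jointly more significant).
#'
#' @param p_a,p_b P-values in `(0, 1]`; vectorized.
#' @return `p_a * p_b`.
#' @export
combine_species_significance <- function(p_a, p_b) {
  stopifnot(all(p_a > 0), all(p_a <= 1), all(p_b > 0), all(p_b <= 1))
  p_a * p_b
}

#' Significance of the overlap between two enriched-term sets
#'
#' Hypergeometric upper tail: drawing `|B|` terms from the universe with
#' `|A|` marked, the probability of at least `|A intersect B|` hits.
#'
#' @param terms_a,terms_b Character vectors of term ids.
#' @param term_universe All candidate terms (supersets both).
#' @return P-value of an overlap at least as large as observed.
#' @export
overlap_significance <- function(terms_a, terms_b, term_universe) {
  a <- unique(terms_a); b <- unique(terms_b); u <- unique(term_universe)
  if (!all(a %in% u) || !all(b %in% u)) {
    stop("term sets must be subsets of the universe")
  }
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), length(u) - length(a), length(b),
                lower.tail = FALSE)
}
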