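#' Semi-global alignment of a haplotig against a target scaffold
#'
#' The whole query aligns to the best-matching local region of the target
#' (free end gaps on the target), scored match = 1, mismatch = -2,
#' gap = -2, via [Biostrings::pairwiseAlignment()]. Identity is matches
#' over aligned columns; query coverage is the fraction of query bases
#' aligned to target bases (not opposite gaps).
#'
#' @param query,target Non-empty DNA strings.
#' @param query_id,target_id Sequence ids recorded in the hit.
#' @param match,mismatch,gap Alignment scores.
#' @return One-row tibble: `query_id`, `target_id`, `query_length`,
#'   `query_cov_fraction`, `query_uncovered_bp`, `identity`,
#'   `target_start`, `target_end` (0-based half-open), `score`.
#' @export
semiglobal_align <- function(query, target, query_id = "query",
                             target_id = "target", match = 1,
                             mismatch = -2, gap = -2) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = target, type = "global-local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  qlen <- nchar(query)
  cov <- (nm + nmm) / qlen
  tibble(query_id = query_id, target_id = target_id, query_length = qlen,
         query_cov_fraction = cov,
         query_uncovered_bp = as.integer(round((1 - cov) * qlen)),
         identity = nm / cols,
         target_start = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
         target_end = BiocGenerics::end(Biostrings::subject(aln)),
         score = BiocGenerics::score(aln))
}

#' Identify half-coverage haplotig candidates
#'
#' Short scaffolds at about half the homozygous depth are the coverage
#' signature of unmerged haplotypes: candidates are scaffolds whose mean
#' depth lies in `[0.3, 0.75]` times `hom_depth` and whose length is below
#' the assembly N50.
#'
#' @param scaffold_depths Tibble with `scaffold`, `length`, `mean_depth`.
#' @param hom_depth Homozygous (diploid) depth, e.g. the modal window
#'   depth from [scaffold_coverage()].
#' @param depth_range Multiples of `hom_depth` bounding candidate depth.
#' @return Character vector of candidate scaffold ids.
#' @export
classify_candidates <- function(scaffold_depths, hom_depth,
                                depth_range = c(0.3, 0.75)) {
  stopifnot(hom_depth > 0)
  thr <- n50(scaffold_depths$length)
  ok <- scaffold_depths$mean_depth >= depth_range[1] * hom_depth &
    scaffold_depths$mean_depth <= depth_range[2] * hom_depth &
    scaffold_depths$length < thr
  scaffold_depths$scaffold[ok]
}

#' Decide whether a haplotig merges into a target region
#'
#' The merge rule: the haplotig must be fully aligned (coverage > 90 % and
#' uncovered region < 500 bp) to a significantly less covered region of a
#' longer scaffold with high sequence identity (> 95 %). All inequalities
#' are strict. "Significantly less covered" is quantified as target-region
#' depth below `depth_frac` times the homozygous depth (the factor is
#' configurable because the rule targets the half-coverage signature).
#'
#' @param hit One-row tibble from [semiglobal_align()] with a
#'   `target_region_depth` column.
#' @param hom_depth Homozygous depth.
#' @param candidate_ok Whether the query passed [classify_candidates()].
#' @param cov_thresh,unc_thresh,id_thresh,depth_frac Thresholds.
#' @return One-row tibble: the hit columns plus the five flags and
#'   `merge` (their conjunction).
#' @export
merge_decision <- function(hit, hom_depth, candidate_ok = TRUE,
                           cov_thresh = 0.90, unc_thresh = 500,
                           id_thresh = 0.95, depth_frac = 0.75) {
  if (cov_thresh < 0 || cov_thresh > 1 || id_thresh < 0 || id_thresh > 1 ||
      depth_frac < 0 || depth_frac > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  stopifnot("target_region_depth" %in% names(hit))
  dplyr::mutate(hit,
    candidate_ok = candidate_ok,
    coverage_ok = .data$query_cov_fraction > cov_thresh,
    uncovered_ok = .data$query_uncovered_bp < unc_thresh,
    identity_ok = .data$identity > id_thresh,
    target_depth_ok = .data$target_region_depth < depth_frac * hom_depth,
    merge = .data$candidate_ok & .data$coverage_ok & .data$uncovered_ok &
      .data$identity_ok & .data$target_depth_ok)
}

#' Apply merge decisions to an assembly
#'
#' Each merged haplotig is removed from the scaffold set. When one
#' haplotig has several positive decisions the highest identity wins, ties
#' broken by longer target then lexicographic target id. Haplotigs are
#' processed in lexicographic order and a scaffold already consumed cannot
#' serve as a target. Mutual (circular) merge requests are an error.
#'
#' @param assembly Tibble `id`, `sequence`, `length`.
#' @param decisions Tibble of [merge_decision()] rows.
#' @return List: `assembly` (merged) and `report` (tibble `haplotig`,
#'   `target`, `target_start`, `target_end`, `identity`,
#'   `query_cov_fraction`).
#' @export
apply_merges <- function(assembly, decisions) {
  pos <- decisions[decisions$merge, , drop = FALSE]
  if (nrow(pos) == 0) {
    return(list(assembly = assembly,
                report = tibble(haplotig = character(),
                                target = character(),
                                target_start = integer(),
                                target_end = integer(),
                                identity = numeric(),
                                query_cov_fraction = numeric())))
  }
  tlen <- stats::setNames(assembly$length, assembly$id)
  pos <- pos[order(pos$query_id, -pos$identity,
                   -tlen[pos$target_id], pos$target_id), , drop = FALSE]
  best <- pos[!duplicated(pos$query_id), , drop = FALSE]
  mutual <- merge(best[, c("query_id", "target_id")],
                  best[, c("query_id", "target_id")],
                  by.x = c("query_id", "target_id"),
                  by.y = c("target_id", "query_id"))
  if (nrow(mutual) > 0) stop("circular merge request: ",
                             mutual$query_id[1], " <-> ",
                             mutual$target_id[1])
  consumed <- character()
  report <- list()
  for (q in sort(unique(pos$query_id))) {
    opts <- pos[pos$query_id == q & !(pos$target_id %in% consumed), ,
                drop = FALSE]
    if (nrow(opts) == 0) next
    b <- opts[1, ]
    consumed <- c(consumed, q)
    report[[length(report) + 1]] <- tibble(
      haplotig = q, target = b$target_id,
      target_start = b$target_start, target_end = b$target_end,
      identity = b$identity, query_cov_fraction = b$query_cov_fraction)
  }
  list(assembly = assembly[!(assembly$id %in% consumed), , drop = FALSE],
       report = dplyr::bind_rows(report))
}

#' Haplotig-merging pipeline
#'
#' Runs the full assembly-improvement rule: find half-coverage candidate
#' scaffolds, align each against every longer scaffold, score the merge
#' rule, and remove merged haplotigs.
#'
#' @param assembly Tibble `id`, `sequence`, `length`.
#' @param coverage Windowed coverage track (`scaffold`, `start`, `end`,
#'   `depth`).
#' @param hom_depth Homozygous depth. By default it is the modal window
#'   depth over scaffolds of at least N50 length: the long-scaffold
#'   backbone sets the expected diploid coverage, and excluding the short
#'   scaffolds keeps the estimate away from the half-coverage haplotig
#'   peak even when haplotigs are abundant.
#' @inheritParams merge_decision
#' @return List: `assembly` (merged), `decisions` (all scored hits),
#'   `report` (applied merges), `candidates`.
#' @export
merge_haplotigs <- function(assembly, coverage, hom_depth = NULL,
                            cov_thresh = 0.90, unc_thresh = 500,
                            id_thresh = 0.95, depth_frac = 0.75) {
  sc <- scaffold_coverage(coverage)
  if (is.null(hom_depth)) {
    backbone <- sc$scaffolds$scaffold[
      sc$scaffolds$length >= n50(sc$scaffolds$length)]
    hom_depth <- scaffold_coverage(
      coverage[coverage$scaffold %in% backbone, , drop = FALSE]
    )$modal_depth
  }
  depths <- sc$scaffolds
  cand <- classify_candidates(depths, hom_depth)
  decisions <- list()
  for (q in cand) {
    qseq <- assembly$sequence[assembly$id == q]
    qlen <- assembly$length[assembly$id == q]
    targets <- assembly$id[assembly$length > qlen]
    for (t in targets) {
      hit <- semiglobal_align(qseq, assembly$sequence[assembly$id == t],
                              query_id = q, target_id = t)
      win <- coverage[coverage$scaffold == t &
                        coverage$start < hit$target_end &
                        coverage$end > hit$target_start, , drop = FALSE]
      hit$target_region_depth <- if (nrow(win) == 0) NA_real_ else
        sum(win$depth * (win$end - win$start)) / sum(win$end - win$start)
      decisions[[length(decisions) + 1]] <-
        merge_decision(hit, hom_depth, candidate_ok = TRUE,
                       cov_thresh = cov_thresh, unc_thresh = unc_thresh,
                       id_thresh = id_thresh, depth_frac = depth_frac)
    }
  }
  decisions <- if (length(decisions)) dplyr::bind_rows(decisions) else
    tibble(query_id = character(), target_id = character(),
           merge = logical())
  res <- apply_merges(assembly, decisions)
  list(assembly = res$assembly, decisions = decisions,
       report = res$report, candidates = cand)
}
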