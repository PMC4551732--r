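iranges_from_bed <- function(bed) {
  # internal 0-based half-open -> IRanges 1-based inclusive
  IRanges::IRanges(start = bed$start + 1L, end = bed$end)
}

bed_from_iranges <- function(ir, scaffold) {
  tibble(scaffold = scaffold, start = BiocGenerics::start(ir) - 1L,
         end = BiocGenerics::end(ir))
}

#' Partition diploid regions into exons, introns, repeats and intergenic
#'
#' Features are resolved with precedence exon > intron > repeat >
#' intergenic and everything is intersected with the diploid-coverage
#' regions, so the class lengths sum exactly to the diploid length.
#'
#' @param genes Gene-model tibble from [read_gff3()].
#' @param repeats Repeat intervals (tibble `scaffold`, `start`, `end`);
#'   may be empty.
#' @param scaffolds Assembly tibble (`id`, `length`).
#' @param diploid_bed Diploid-coverage intervals (tibble `scaffold`,
#'   `start`, `end`), e.g. from [diploid_regions()].
#' @return Tibble `scaffold`, `start`, `end`, `class` with `class` in
#'   `{exon, intron, repeat, intergenic}`.
#' @export
partition_regions <- function(genes, repeats, scaffolds, diploid_bed) {
  bad <- setdiff(genes$scaffold, scaffolds$id)
  if (length(bad) > 0) stop("gene on unknown scaffold: ", bad[1])
  out <- list()
  for (sc in unique(diploid_bed$scaffold)) {
    dip <- IRanges::reduce(iranges_from_bed(
      diploid_bed[diploid_bed$scaffold == sc, ]))
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    ex <- if (nrow(g) > 0) IRanges::reduce(iranges_from_bed(
      dplyr::bind_rows(g$cds))) else IRanges::IRanges()
    spans <- if (nrow(g) > 0) IRanges::reduce(
      IRanges::IRanges(g$start + 1L, g$end)) else IRanges::IRanges()
    intr <- IRanges::setdiff(spans, ex)
    rp <- repeats[repeats$scaffold == sc, , drop = FALSE]
    rep_ir <- if (nrow(rp) > 0) IRanges::reduce(iranges_from_bed(rp)) else
      IRanges::IRanges()
    rep_ir <- IRanges::setdiff(rep_ir, IRanges::union(ex, intr))
    genic <- IRanges::union(IRanges::union(ex, intr), rep_ir)
    inter <- IRanges::setdiff(dip, genic)
    cls <- list(exon = IRanges::intersect(ex, dip),
                intron = IRanges::intersect(intr, dip),
                `repeat` = IRanges::intersect(rep_ir, dip),
                intergenic = inter)
    for (nm in names(cls)) {
      if (length(cls[[nm]]) > 0) {
        out[[length(out) + 1]] <- dplyr::mutate(
          bed_from_iranges(cls[[nm]], sc), class = nm)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(scaffold = character(), start = integer(),
                  end = integer(), class = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$scaffold, .data$start)
}

#' Windowed SNP-rate track
#'
#' SNP rates in overlapping windows (1000 bp every 100 bp by default)
#' anchored within each region-class interval. Windows never straddle
#' class boundaries: an interval shorter than `window` emits no windows.
#'
#' @param snps SNP tibble (`scaffold`, `pos`).
#' @param partition Region partition from [partition_regions()] (or any
#'   tibble `scaffold`, `start`, `end`, `class`).
#' @param window Window size in bp.
#' @param step Anchor step in bp.
#' @return Tibble `scaffold`, `start`, `rate`, `region_class`.
#' @export
window_rates <- function(snps, partition, window = 1000L, step = 100L) {
  stopifnot(window >= 1, step >= 1)
  out <- list()
  for (sc in unique(partition$scaffold)) {
    p <- sort(snps$pos[snps$scaffold == sc])
    part <- partition[partition$scaffold == sc, , drop = FALSE]
    for (i in seq_len(nrow(part))) {
      if (part$end[i] - part$start[i] < window) next
      anchors <- seq(part$start[i], part$end[i] - window, by = step)
      cnt <- findInterval(anchors + window - 0.5, p) -
        findInterval(anchors - 0.5, p)
      out[[length(out) + 1]] <- tibble(
        scaffold = sc, start = as.integer(anchors),
        rate = cnt / window, region_class = part$class[i])
    }
  }
  if (length(out) == 0) {
    return(tibble(scaffold = character(), start = integer(),
                  rate = numeric(), region_class = character()))
  }
  dplyr::bind_rows(out)
}

#' SNP-free segments within diploid regions
#'
#' Maximal sub-intervals of the diploid regions that contain no SNP and
#' are at least `min_len` bp long, plus the global maximum length. Long
#' SNP-free runs are the signature of identity-by-descent between the two
#' haplotypes.
#'
#' @param snps SNP tibble (`scaffold`, `pos`).
#' @param diploid_bed Tibble `scaffold`, `start`, `end`.
#' @param min_len Minimum reported segment length (bp).
#' @return List: `segments` (tibble `scaffold`, `start`, `end`, `length`)
#'   and `max_length` (0 when no segment qualifies).
#' @export
snp_free_segments <- function(snps, diploid_bed, min_len = 1000L) {
  segs <- list()
  for (i in seq_len(nrow(diploid_bed))) {
    sc <- diploid_bed$scaffold[i]
    a <- diploid_bed$start[i]; b <- diploid_bed$end[i]
    p <- sort(snps$pos[snps$scaffold == sc & snps$pos >= a &
                         snps$pos < b])
    starts <- c(a, p + 1L)
    ends <- c(p, b)
    keep <- ends - starts >= min_len
    if (any(keep)) {
      segs[[length(segs) + 1]] <- tibble(
        scaffold = sc, start = starts[keep], end = ends[keep],
        length = ends[keep] - starts[keep])
    }
  }
  segments <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble(scaffold = character(), start = integer(), end = integer(),
           length = integer())
  list(segments = segments,
       max_length = if (nrow(segments)) max(segments$length) else 0L)
}

spliced_cds <- function(gene, scaffold_seq) {
  cds <- gene$cds[[1]]
  paste(substring(scaffold_seq, cds$start + 1L, cds$end), collapse = "")
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify a coding SNP as synonymous or non-synonymous
#'
#' Locates the SNP's codon by CDS coordinate arithmetic (minus-strand
#' genes are read on the coding strand after reverse complementation) and
#' compares the translated amino acids under the standard genetic code.
#'
#' @param snp One-row tibble or list with `scaffold`, `pos` (0-based),
#'   `ref`, `alt`.
#' @param gene One gene-model row from [read_gff3()] (coding, CDS length
#'   divisible by 3).
#' @param scaffold_seq The gene's scaffold sequence.
#' @return `"synonymous"`, `"nonsynonymous"`, or `"noncoding"` when the
#'   SNP falls outside the CDS. The codon position (0-based aa index) is
#'   attached as attribute `aa_pos` for coding SNPs.
#' @export
classify_snp_effect <- function(snp, gene, scaffold_seq) {
  stopifnot(snp$scaffold == gene$scaffold)
  cds <- gene$cds[[1]]
  total <- sum(cds$end - cds$start)
  if (total %% 3L != 0L) stop("CDS length of ", gene$gene_id,
                              " not divisible by 3")
  hit <- which(snp$pos >= cds$start & snp$pos < cds$end)
  if (length(hit) == 0) return("noncoding")
  if (substring(scaffold_seq, snp$pos + 1L, snp$pos + 1L) != snp$ref) {
    stop("REF base disagrees with scaffold sequence at ", snp$scaffold,
         ":", snp$pos)
  }
  before <- if (hit > 1) sum(cds$end[seq_len(hit - 1)] -
                               cds$start[seq_len(hit - 1)]) else 0L
  cds_pos <- before + (snp$pos - cds$start[hit])   # 0-based, + orientation
  seq_fwd <- spliced_cds(gene, scaffold_seq)
  if (gene$strand == "-") {
    coding_pos <- total - 1L - cds_pos
    coding_seq <- revcomp(seq_fwd)
    alt <- revcomp(snp$alt)
  } else {
    coding_pos <- cds_pos
    coding_seq <- seq_fwd
    alt <- snp$alt
  }
  ci <- coding_pos %/% 3L
  codon <- substring(coding_seq, ci * 3L + 1L, ci * 3L + 3L)
  mutated <- codon
  substr(mutated, coding_pos %% 3L + 1L, coding_pos %% 3L + 1L) <- alt
  res <- if (translate_codon(codon) == translate_codon(mutated))
    "synonymous" else "nonsynonymous"
  attr(res, "aa_pos") <- ci
  res
}

#' Per-protein substitution profiles
#'
#' Maps non-synonymous SNPs to amino-acid positions per coding gene and
#' applies disorder masks to give ordered-region lengths and counts.
#'
#' @param snps SNP tibble (`scaffold`, `pos`, `ref`, `alt`).
#' @param genes Gene-model tibble from [read_gff3()].
#' @param assembly Assembly tibble (`id`, `sequence`).
#' @param disorder_masks Tibble `protein_id`, `start_aa`, `end_aa`
#'   (0-based half-open, protein coordinates); proteins absent from the
#'   table are fully ordered.
#' @return Tibble `protein_id`, `length` (aa), `n_sub`, `ordered_length`,
#'   `disordered_length`, `n_sub_ordered`.
#' @export
substitution_profiles <- function(snps, genes, assembly,
                                  disorder_masks = NULL) {
  if (is.null(disorder_masks)) {
    disorder_masks <- tibble(protein_id = character(),
                             start_aa = integer(), end_aa = integer())
  }
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$coding) next
    seq <- assembly$sequence[assembly$id == g$scaffold]
    if (length(seq) == 0) stop("gene on unknown scaffold: ", g$scaffold)
    aa_len <- sum(g$cds[[1]]$end - g$cds[[1]]$start) %/% 3L
    mask <- disorder_masks[disorder_masks$protein_id == g$gene_id, ,
                           drop = FALSE]
    dis <- rep(FALSE, aa_len)
    for (j in seq_len(nrow(mask))) {
      sel <- seq.int(mask$start_aa[j] + 1L, mask$end_aa[j])
      dis[sel[sel >= 1 & sel <= aa_len]] <- TRUE
    }
    s <- snps[snps$scaffold == g$scaffold & snps$pos >= g$start &
                snps$pos < g$end, , drop = FALSE]
    aa_hit <- integer()
    for (j in seq_len(nrow(s))) {
      eff <- classify_snp_effect(s[j, ], g, seq)
      if (identical(as.character(eff), "nonsynonymous")) {
        aa_hit <- c(aa_hit, attr(eff, "aa_pos"))
      }
    }
    out[[length(out) + 1]] <- tibble(
      protein_id = g$gene_id, length = aa_len,
      n_sub = length(aa_hit),
      ordered_length = sum(!dis), disordered_length = sum(dis),
      n_sub_ordered = sum(!dis[aa_hit + 1L]))
  }
  if (length(out) == 0) {
    return(tibble(protein_id = character(), length = integer(),
                  n_sub = integer(), ordered_length = integer(),
                  disordered_length = integer(),
                  n_sub_ordered = integer()))
  }
  dplyr::bind_rows(out)
}
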