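#' Canonical k-mer frequency histogram
#'
#' Counts canonical k-mers (the lexicographically smaller of a k-mer and
#' its reverse complement, via 2-bit encoding) across a set of reads and
#' tabulates how many distinct k-mers occur at each multiplicity. In a
#' diploid genome sequenced at depth `c`, k-mers from homozygous regions
#' peak near multiplicity `c` and k-mers overlapping heterozygous sites
#' near `c / 2`, so the histogram is a direct readout of heterozygosity.
#'
#' @param reads Tibble with a `sequence` column (as from
#'   [simulate_reads()] or [read_fasta()]) or a character vector.
#' @param k Odd k-mer size in `[3, 31]`; 17 is the conventional choice for
#'   genome surveys.
#' @return A tibble of class `kmer_histogram` with columns `multiplicity`
#'   and `count`, plus attribute `k`.
#' @export
kmer_histogram <- function(reads, k = 17L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  h <- .kmer_hist_cpp(seqs, as.integer(k))
  out <- as_tibble(h)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_histogram", class(out))
  out
}

smooth_counts <- function(mult, count, window = 3L) {
  # centered moving average on the dense multiplicity grid
  grid <- seq(min(mult), max(mult))
  dense <- numeric(length(grid))
  dense[match(mult, grid)] <- count
  half <- (window - 1L) %/% 2L
  sm <- stats::filter(dense, rep(1 / window, window), sides = 2)
  sm[is.na(sm)] <- dense[is.na(sm)]
  tibble(multiplicity = grid, smoothed = as.numeric(sm))
}

#' Detect heterozygous and homozygous coverage peaks
#'
#' Smooths the multiplicity histogram with a centered moving average
#' (window 3) and returns the two largest local maxima at multiplicity
#' `>= min_depth`; the left peak is the heterozygous (half-coverage) peak
#' and the right peak the homozygous one. The ratio of the two peak
#' heights indicates the heterozygosity level. With fewer than two peaks
#' the single peak is reported as homozygous and the het fields are `NA`.
#'
#' @param hist A `kmer_histogram`.
#' @param min_depth Multiplicities below this are ignored (error k-mers).
#' @param min_height_frac Minimum height of the secondary peak relative
#'   to the tallest one; smaller bumps are counting noise, not a
#'   coverage peak.
#' @return A list of class `peak_call`: `het_depth`, `hom_depth`,
#'   `het_height`, `hom_height`, `height_ratio`, `n_peaks`.
#' @export
detect_peaks <- function(hist, min_depth = 3L, min_height_frac = 0.05) {
  stopifnot(nrow(hist) > 0)
  sm <- smooth_counts(hist$multiplicity, hist$count)
  sm <- sm[sm$multiplicity >= min_depth, ]
  y <- sm$smoothed
  n <- length(y)
  if (n < 3) stop("histogram too narrow for peak detection")
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- sm[is_max, ]
  peaks <- peaks[order(peaks$smoothed, decreasing = TRUE), ]
  if (nrow(peaks) == 0) {
    # monotone histogram: take the global max as the single peak
    peaks <- sm[which.max(sm$smoothed), ]
  }
  # separation rule: local maxima within a factor min_sep in multiplicity
  # of an already-accepted (taller) peak are ripples of the same peak,
  # not a distinct half-coverage peak (which sits at a factor 2)
  min_sep <- 1.5
  peaks <- peaks[peaks$smoothed >= min_height_frac * peaks$smoothed[1], ,
                 drop = FALSE]
  acc <- integer()
  for (i in seq_len(nrow(peaks))) {
    m <- peaks$multiplicity[i]
    if (all(pmax(m, peaks$multiplicity[acc]) /
              pmin(m, peaks$multiplicity[acc]) >= min_sep)) {
      acc <- c(acc, i)
    }
    if (length(acc) == 2) break
  }
  peaks <- peaks[acc, , drop = FALSE]
  if (nrow(peaks) < 2) {
    out <- list(het_depth = NA_integer_, hom_depth = peaks$multiplicity[1],
                het_height = NA_real_, hom_height = peaks$smoothed[1],
                height_ratio = NA_real_, n_peaks = 1L)
  } else {
    two <- peaks[1:2, ]
    two <- two[order(two$multiplicity), ]
    out <- list(het_depth = two$multiplicity[1],
                hom_depth = two$multiplicity[2],
                het_height = two$smoothed[1], hom_height = two$smoothed[2],
                height_ratio = two$smoothed[1] / two$smoothed[2],
                n_peaks = 2L)
  }
  structure(out, class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat("k-mer coverage peaks:\n")
  cat("  homozygous peak:  depth", x$hom_depth, "\n")
  if (x$n_peaks == 2) {
    cat("  heterozygous peak: depth", x$het_depth,
        sprintf("(height ratio het/hom = %.3f)\n", x$height_ratio))
  } else {
    cat("  no heterozygous peak detected\n")
  }
  invisible(x)
}

#' Per-scaffold mean depth and the diploid coverage interval
#'
#' The modal window depth (rounded to the nearest integer, weighted by
#' window length) defines the expected diploid coverage; the diploid
#' interval is `[0.75, 1.25]` times the mode, a symmetric bracket that
#' excludes the half-coverage haplotig peak at 0.5x.
#'
#' @param track Tibble with `scaffold`, `start`, `end`, `depth` (windowed
#'   coverage).
#' @return List: `modal_depth`, `diploid_interval` (length-2 numeric),
#'   `scaffolds` (tibble `scaffold`, `length`, `mean_depth`,
#'   `in_diploid_interval`).
#' @export
scaffold_coverage <- function(track) {
  if (is.null(track) || nrow(track) == 0) stop("empty coverage track")
  w <- track$end - track$start
  d <- round(track$depth)
  tab <- tapply(w, d, sum)
  modal <- as.numeric(names(tab))[which.max(tab)]
  interval <- c(0.75, 1.25) * modal
  sc <- track %>%
    dplyr::group_by(scaffold = .data$scaffold) %>%
    dplyr::summarise(
      length = sum(.data$end - .data$start),
      mean_depth = sum(.data$depth * (.data$end - .data$start)) /
        sum(.data$end - .data$start),
      .groups = "drop") %>%
    dplyr::mutate(in_diploid_interval = .data$mean_depth >= interval[1] &
                    .data$mean_depth <= interval[2])
  list(modal_depth = modal, diploid_interval = interval, scaffolds = sc)
}

#' Diploid-coverage regions as a BED-style tibble
#'
#' Maximal runs of adjacent windows whose depth falls inside the diploid
#' interval of [scaffold_coverage()].
#'
#' @inheritParams scaffold_coverage
#' @param interval Optional length-2 numeric overriding the computed
#'   diploid interval.
#' @return Tibble `scaffold`, `start`, `end` (0-based half-open).
#' @export
diploid_regions <- function(track, interval = NULL) {
  if (is.null(interval)) {
    interval <- scaffold_coverage(track)$diploid_interval
  }
  ok <- track$depth >= interval[1] & track$depth <= interval[2]
  merge_window_runs(track[ok, , drop = FALSE])
}

merge_window_runs <- function(win) {
  if (nrow(win) == 0) {
    return(tibble(scaffold = character(), start = integer(),
                  end = integer()))
  }
  win <- win[order(win$scaffold, win$start), ]
  new_run <- c(TRUE, win$scaffold[-1] != win$scaffold[-nrow(win)] |
                 win$start[-1] != win$end[-nrow(win)])
  run <- cumsum(new_run)
  win %>%
    dplyr::mutate(run = run) %>%
    dplyr::group_by(.data$run) %>%
    dplyr::summarise(scaffold = .data$scaffold[1],
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop") %>%
    dplyr::select("scaffold", "start", "end")
}

#' Flag repeat-like high-coverage regions
#'
#' Maximal runs of windows with depth greater than `factor` times the
#' modal depth — the coverage signature of collapsed repeats.
#'
#' @inheritParams scaffold_coverage
#' @param factor Multiple of the modal depth above which a window is
#'   flagged.
#' @return Tibble `scaffold`, `start`, `end` (0-based half-open; adjacent
#'   flagged windows merged).
#' @export
flag_high_coverage <- function(track, factor = 4) {
  modal <- scaffold_coverage(track)$modal_depth
  merge_window_runs(track[track$depth > factor * modal, , drop = FALSE])
}

#' Plot a k-mer multiplicity histogram
#'
#' @param object A `kmer_histogram`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.kmer_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$multiplicity, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = sprintf("%d-mer multiplicity", attr(object, "k")),
                  y = "distinct k-mers") +
    ggplot2::theme_minimal()
}
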