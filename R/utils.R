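#' @useDynLib lepcompgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
#' @keywords internal
"_PACKAGE"

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scaffold N50
#'
#' Length such that scaffolds of at least that length together contain half
#' of the assembly.
#'
#' @param lengths Numeric vector of scaffold lengths.
#' @return N50 length in bp.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  l <- sort(lengths, decreasing = TRUE)
  l[which(cumsum(l) >= sum(l) / 2)[1]]
}

check_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop("sequence contains unsupported characters (only A/C/G/T",
         if (allow_n) "/N", " allowed)")
  }
  invisible(x)
}

# seed scoping: run code under a seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# random DNA string of given length
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
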