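#' Filter ortholog families to universal, low-duplication families
#'
#' A family is kept iff it has at least 1 and at most `max_copies` copies
#' in every species of the table, removing both non-universal families
#' and families with extensive duplication.
#'
#' @param genes Long ortholog table: tibble with `species`, `gene_id`,
#'   `family_id`, `scaffold`, `strand` (e.g. `simulate_gene_orders()$genes`).
#' @param max_copies Maximum copies per species.
#' @return The table restricted to passing families.
#' @export
filter_families <- function(genes, max_copies = 4L) {
  n_species <- length(unique(genes$species))
  counts <- genes %>%
    dplyr::count(.data$family_id, .data$species, name = "copies")
  ok <- counts %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::summarise(universal = dplyr::n() == n_species,
                     max_c = max(.data$copies), .groups = "drop") %>%
    dplyr::filter(.data$universal, .data$max_c <= max_copies)
  genes[genes$family_id %in% ok$family_id, , drop = FALSE]
}

state_from_strands <- function(sa, sb) {
  # fixed letter map in canonical family order:
  # A = (+,+), B = (-,-), C = (+,-), D = (-,+)
  dplyr::case_when(
    sa == "+" & sb == "+" ~ "A",
    sa == "-" & sb == "-" ~ "B",
    sa == "+" & sb == "-" ~ "C",
    sa == "-" & sb == "+" ~ "D")
}

#' Relative orientation state of two co-scaffolded genes
#'
#' With the pair in canonical order (first family id lexicographically
#' smaller), the four possible strand combinations map to four character
#' states: A = `[a+, b+]`, B = `[a-, b-]`, C = `[a+, b-]`, D = `[a-, b+]`.
#' Genes on different scaffolds are undetermined (`NA`).
#'
#' @param gene_a,gene_b One-row tibbles (or lists) with `gene_id`,
#'   `scaffold`, `strand`; `gene_a` belongs to the lexicographically
#'   smaller family.
#' @return `"A"`, `"B"`, `"C"`, `"D"`, or `NA_character_`.
#' @export
orientation_state <- function(gene_a, gene_b) {
  if (identical(gene_a$gene_id, gene_b$gene_id)) {
    stop("the two genes must be distinct")
  }
  if (!identical(gene_a$scaffold, gene_b$scaffold)) return(NA_character_)
  state_from_strands(gene_a$strand, gene_b$strand)
}

#' Family pairs whose relative orientation is determined in every species
#'
#' A family is single-locus resolvable in a species when all of its
#' copies sit on one scaffold with one consistent strand. A pair of
#' families is resolvable when, in every species, both families are
#' resolvable and share a scaffold. All co-scaffolded pairs are
#' enumerated (not only adjacent ones).
#'
#' @param genes Long ortholog table (`species`, `gene_id`, `family_id`,
#'   `scaffold`, `strand`).
#' @return Tibble `fam_a`, `fam_b` (canonical order), `species`, `state`,
#'   one row per pair x species, states all determined.
#' @export
resolvable_pairs <- function(genes) {
  species <- sort(unique(genes$species))
  o <- order(genes$species, genes$family_id)
  sp <- genes$species[o]; fam <- genes$family_id[o]
  scf <- genes$scaffold[o]; str <- genes$strand[o]
  n <- length(sp)
  gid <- cumsum(c(TRUE, sp[-1] != sp[-n] | fam[-1] != fam[-n]))
  first <- which(!duplicated(gid))
  # a (species, family) locus is resolvable iff every copy matches the
  # first copy's scaffold and strand
  ok_row <- scf == scf[first][gid] & str == str[first][gid]
  size <- tabulate(gid)
  ok_cnt <- tabulate(gid[ok_row], nbins = max(gid))
  resolv <- ok_cnt == size
  loci <- tibble(species = sp[first], family_id = fam[first],
                 scaffold = scf[first], strand = str[first])[resolv, ]
  # families resolvable in every species
  fam_n <- table(loci$family_id)
  loci <- loci[loci$family_id %in%
                 names(fam_n)[fam_n == length(species)], , drop = FALSE]
  if (nrow(loci) == 0) {
    return(tibble(fam_a = character(), fam_b = character(),
                  species = character(), state = character()))
  }
  # two families are co-scaffolded in every species iff their per-species
  # scaffold signatures are identical
  loci <- dplyr::arrange(loci, .data$family_id, .data$species)
  fams <- unique(loci$family_id)
  strand_mat <- matrix(loci$strand, nrow = length(species),
                       dimnames = list(species, fams))
  sig <- apply(matrix(loci$scaffold, nrow = length(species)), 2, paste,
               collapse = "\r")
  out <- list()
  for (sg in split(fams, sig)) {
    if (length(sg) < 2) next
    pr <- utils::combn(sort(sg), 2)
    npair <- ncol(pr)
    sa <- strand_mat[, pr[1, ], drop = FALSE]   # species x pairs
    sb <- strand_mat[, pr[2, ], drop = FALSE]
    out[[length(out) + 1]] <- tibble(
      fam_a = rep(pr[1, ], each = length(species)),
      fam_b = rep(pr[2, ], each = length(species)),
      species = rep(species, npair),
      state = state_from_strands(as.vector(sa), as.vector(sb)))
  }
  if (length(out) == 0) {
    return(tibble(fam_a = character(), fam_b = character(),
                  species = character(), state = character()))
  }
  dplyr::bind_rows(out)
}

#' Restrict pairs so each family participates in only one pair
#'
#' Deterministic greedy maximal matching: pairs are visited in sorted
#' `(fam_a, fam_b)` order and accepted iff neither family is already used.
#'
#' @param pairs Tibble with `fam_a`, `fam_b` (long per-species rows are
#'   fine; the pair set is deduplicated).
#' @return The input restricted to the selected pairs.
#' @export
select_disjoint_pairs <- function(pairs) {
  uniq <- dplyr::distinct(pairs, .data$fam_a, .data$fam_b) %>%
    dplyr::arrange(.data$fam_a, .data$fam_b)
  used <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(nrow(uniq))
  fa <- uniq$fam_a; fb <- uniq$fam_b
  for (i in seq_along(fa)) {
    if (is.null(used[[fa[i]]]) && is.null(used[[fb[i]]])) {
      keep[i] <- TRUE
      used[[fa[i]]] <- TRUE
      used[[fb[i]]] <- TRUE
    }
  }
  sel <- uniq[keep, , drop = FALSE]
  dplyr::semi_join(pairs, sel, by = c("fam_a", "fam_b"))
}

#' Encode pairs as per-species orientation strings
#'
#' Pairs are ordered by `(fam_a, fam_b)` and each species' states are
#' concatenated into one string over the alphabet `{A, B, C, D}`.
#'
#' @param pairs Long tibble from [resolvable_pairs()] (after
#'   [select_disjoint_pairs()] if desired), all states determined.
#' @return A list of class `orientation_matrix`: `species` (character),
#'   `strings` (named character vector, equal lengths), `pairs` (tibble
#'   `fam_a`, `fam_b` in column order).
#' @export
orientation_matrix <- function(pairs) {
  stopifnot(!any(is.na(pairs$state)))
  species <- sort(unique(pairs$species))
  key <- dplyr::distinct(pairs, .data$fam_a, .data$fam_b) %>%
    dplyr::arrange(.data$fam_a, .data$fam_b)
  wide <- tidyr::pivot_wider(pairs, names_from = "species",
                             values_from = "state")
  wide <- dplyr::left_join(key, wide, by = c("fam_a", "fam_b"))
  if (anyNA(wide[species])) {
    stop("states must be determined in every species")
  }
  strings <- vapply(species, function(s)
    paste(wide[[s]], collapse = ""), character(1))
  structure(list(species = species, strings = strings, pairs = key),
            class = "orientation_matrix")
}

#' Hamming distances between orientation strings
#'
#' The number of differing positions between each pair of per-species
#' strings, used directly as evolutionary distances.
#'
#' @param x An `orientation_matrix`, or a named character vector of
#'   equal-length strings.
#' @return Symmetric numeric matrix with species dimnames.
#' @export
hamming_distances <- function(x) {
  strings <- if (inherits(x, "orientation_matrix")) x$strings else x
  stopifnot(length(unique(nchar(strings))) == 1)
  chars <- do.call(rbind, strsplit(strings, ""))
  n <- length(strings)
  d <- matrix(0, n, n, dimnames = list(names(strings), names(strings)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
    }
  }
  d
}

#' Export / read an orientation matrix in relaxed PHYLIP format
#'
#' First line `n_species n_chars`, then one `name string` row per
#' species. The A-D states are amino-acid-alphabet letters, so downstream
#' Bayesian phylogenetics tools accept the file as-is. Names longer than
#' 10 characters are preserved (relaxed dialect).
#'
#' @param x An `orientation_matrix` (or named character vector).
#' @param path Output path.
#' @export
export_character_matrix <- function(x, path) {
  strings <- if (inherits(x, "orientation_matrix")) x$strings else x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(strings), nchar(strings[[1]])), con)
  writeLines(paste(names(strings), strings), con)
  invisible(path)
}

#' @rdname export_character_matrix
#' @return `read_character_matrix()`: a named character vector.
#' @export
read_character_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- strsplit(trimws(lines[-1][nzchar(trimws(lines[-1]))]), "\\s+")
  stopifnot(length(rows) == hdr[1])
  out <- vapply(rows, `[[`, character(1), 2)
  names(out) <- vapply(rows, `[[`, character(1), 1)
  stopifnot(all(nchar(out) == hdr[2]))
  out
}

#' Gene-rearrangement phylogeny pipeline
#'
#' Runs family filtering, pair resolution, the one-pair-per-family greedy
#' restriction, orientation encoding, Hamming distances and BioNJ in one
#' call.
#'
#' @param genes Long ortholog table.
#' @param max_copies Family-size filter.
#' @return List: `tree` (`phylo`), `dist`, `matrix`
#'   (`orientation_matrix`), `n_pairs_resolvable`, `n_pairs_used`.
#' @export
rearrangement_tree <- function(genes, max_copies = 4L) {
  filt <- filter_families(genes, max_copies)
  pairs <- resolvable_pairs(filt)
  n_res <- nrow(dplyr::distinct(pairs, .data$fam_a, .data$fam_b))
  disj <- select_disjoint_pairs(pairs)
  m <- orientation_matrix(disj)
  d <- hamming_distances(m)
  list(tree = bionj(d), dist = d, matrix = m,
       n_pairs_resolvable = n_res, n_pairs_used = nrow(m$pairs))
}
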