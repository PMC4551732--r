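#' Merge ortholog families that share a closest reference homolog
#'
#' Each family's closest reference entry is the modal entry over its
#' member proteins (ties broken by the lexicographically smallest entry).
#' Families sharing a modal entry are joined into connected components
#' and merged; the merged family keeps the lexicographically smallest
#' member family id.
#'
#' @param families Tibble `family_id`, `protein_id`.
#' @param closest_hit Tibble `protein_id`, `reference_id`; proteins
#'   absent from `families` are ignored with a warning.
#' @return Tibble `family_id` (merged id), `protein_id`,
#'   `original_family`.
#' @export
merge_families_by_closest_hit <- function(families, closest_hit) {
  orphan <- setdiff(closest_hit$protein_id, families$protein_id)
  if (length(orphan) > 0) {
    warning(length(orphan), " protein(s) in no family ignored")
  }
  hits <- dplyr::inner_join(families, closest_hit, by = "protein_id")
  modal <- hits %>%
    dplyr::count(.data$family_id, .data$reference_id) %>%
    dplyr::arrange(.data$family_id, dplyr::desc(.data$n),
                   .data$reference_id) %>%
    dplyr::distinct(.data$family_id, .keep_all = TRUE) %>%
    dplyr::select("family_id", modal_ref = "reference_id")
  fam_ids <- sort(unique(families$family_id))
  modal <- dplyr::left_join(tibble(family_id = fam_ids), modal,
                            by = "family_id")
  # bipartite family--reference graph; merged families = components
  has_ref <- !is.na(modal$modal_ref)
  g <- igraph::graph_from_data_frame(
    data.frame(from = modal$family_id[has_ref],
               to = paste0("\rref\r", modal$modal_ref[has_ref])),
    directed = FALSE,
    vertices = data.frame(name = c(
      fam_ids, unique(paste0("\rref\r", modal$modal_ref[has_ref])))))
  comp <- igraph::components(g)$membership
  fam_comp <- comp[fam_ids]
  merged_id <- stats::ave(fam_ids, fam_comp, FUN = min)
  map <- stats::setNames(merged_id, fam_ids)
  dplyr::transmute(families,
                   original_family = .data$family_id,
                   family_id = unname(map[.data$family_id]),
                   protein_id = .data$protein_id) %>%
    dplyr::select("family_id", "protein_id", "original_family")
}

#' Test a family for gene expansion in a focal species
#'
#' A family counts as expanded when both the copy number and the total
#' protein length in the focal species are strictly more than `ratio`
#' times the averages over the other species.
#'
#' @param family Tibble `species`, `protein_id`, `length` (aa) for one
#'   family; needs members in at least two non-focal species.
#' @param focal_species Species to test.
#' @param ratio Strict ratio threshold on both criteria.
#' @return One-row tibble: `focal_count`, `focal_total_len`,
#'   `other_mean_count`, `other_mean_len`, `count_ratio`, `length_ratio`,
#'   `expanded`.
#' @export
expansion_test <- function(family, focal_species, ratio = 1.5) {
  per_sp <- family %>%
    dplyr::group_by(species = .data$species) %>%
    dplyr::summarise(n = dplyr::n(), total_len = sum(.data$length),
                     .groups = "drop")
  other <- per_sp[per_sp$species != focal_species, , drop = FALSE]
  if (nrow(other) < 2) stop("need members in >= 2 non-focal species")
  focal <- per_sp[per_sp$species == focal_species, , drop = FALSE]
  fc <- if (nrow(focal)) focal$n else 0L
  fl <- if (nrow(focal)) focal$total_len else 0
  oc <- mean(other$n); ol <- mean(other$total_len)
  tibble(focal_count = fc, focal_total_len = fl,
         other_mean_count = oc, other_mean_len = ol,
         count_ratio = fc / oc, length_ratio = fl / ol,
         expanded = fc / oc > ratio & fl / ol > ratio)
}

#' Count ortholog families per sharing category
#'
#' Families are assigned, in order, to: `1:1:1` (single copy in every
#' species), `N:N:N` (present in every species, multi-copy somewhere),
#' one of the configured clade-specific categories (present in exactly
#' the clade's species set), `patchy` (more than one but not all
#' species), and `species-specific` (one species, at least two members).
#' Single-member single-species entries are counted as `unclustered`.
#'
#' @param genes Tibble `species`, `family_id` (one row per gene).
#' @param all_species Character vector of every species in the study.
#' @param clades Named list of character vectors, in assignment order,
#'   e.g. `list(Obtectomera = c(...), Rhopalocera = c(...))`.
#' @return Tibble `category`, `n_families`; the counts sum to the number
#'   of families.
#' @export
ortholog_categories <- function(genes, all_species = NULL,
                                clades = list()) {
  if (is.null(all_species)) all_species <- sort(unique(genes$species))
  per <- genes %>%
    dplyr::count(.data$family_id, .data$species) %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::summarise(n_species = dplyr::n(), max_copies = max(.data$n),
                     total = sum(.data$n),
                     sp_set = paste(sort(.data$species), collapse = "\r"),
                     .groups = "drop")
  all_key <- paste(sort(all_species), collapse = "\r")
  clade_keys <- vapply(clades, function(x)
    paste(sort(x), collapse = "\r"), character(1))
  cat_of <- function(i) {
    p <- per[i, ]
    if (p$sp_set == all_key && p$max_copies == 1) return("1:1:1")
    if (p$sp_set == all_key) return("N:N:N")
    hit <- which(clade_keys == p$sp_set)
    if (length(hit) == 1) return(names(clades)[hit])
    if (p$n_species > 1) return("patchy")
    if (p$total >= 2) return("species-specific")
    "unclustered"
  }
  cats <- vapply(seq_len(nrow(per)), cat_of, character(1))
  lev <- unique(c("1:1:1", "N:N:N", names(clades), "patchy",
                  "species-specific", "unclustered"))
  tibble(category = factor(cats, levels = lev)) %>%
    dplyr::count(.data$category, name = "n_families",
                 .drop = FALSE) %>%
    dplyr::mutate(category = as.character(.data$category))
}
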