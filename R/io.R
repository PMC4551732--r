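#' Read a FASTA file of scaffolds
#'
#' Sequences are uppercased and validated against the `{A,C,G,T,N}`
#' alphabet; other IUPAC ambiguity codes are rejected so that downstream
#' codon arithmetic stays total.
#'
#' @param path Path to a FASTA file (plain text; CRLF tolerated).
#' @return A tibble with columns `id`, `sequence`, `length` (bp), one row
#'   per record in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(tibble(id = character(), sequence = character(),
                  length = integer()))
  }
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(id = character(), sequence = character(),
                  length = integer()))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    stop("malformed FASTA: line 1 does not start with '>'")
  }
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header at line ", which(hdr)[!nzchar(ids)][1])
  }
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               ids[duplicated(ids)][1])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out <- character(length(ids))
  out[as.integer(names(seqs))] <- seqs
  check_dna(out)
  tibble(id = ids, sequence = out, length = nchar(out))
}

#' Write scaffolds to FASTA
#'
#' @param assembly Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(assembly))) {
    writeLines(paste0(">", assembly$id[i]), con)
    s <- assembly$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features. GFF3 coordinates (1-based inclusive) are
#' converted to the package-wide 0-based half-open convention. When a gene
#' has several mRNA isoforms, the isoform with the longest total CDS is
#' retained. A gene whose total CDS length is not divisible by 3 is kept
#' but flagged non-coding with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `scaffold`, `start`,
#'   `end` (0-based half-open), `strand`, `coding` (logical), and `cds`
#'   (list-column of tibbles with 0-based half-open `start`, `end`, sorted,
#'   non-overlapping).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  cdss  <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path)
  cds_parent <- vapply(cdss$Parent, function(p) as.character(p)[1],
                       character(1))
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$ID
    iso <- mrnas[vapply(mrnas$Parent,
                        function(p) gid %in% as.character(p), logical(1)), ,
                 drop = FALSE]
    if (nrow(iso) == 0) {
      cds_g <- cdss[cds_parent == gid, , drop = FALSE]
    } else {
      cds_by_iso <- lapply(iso$ID, function(mid)
        cdss[cds_parent == mid, , drop = FALSE])
      tot <- vapply(cds_by_iso, function(x) sum(x$width), numeric(1))
      cds_g <- cds_by_iso[[which.max(tot)]]
    }
    cds_tbl <- tibble(start = as.integer(cds_g$start - 1L),
                      end = as.integer(cds_g$end))
    cds_tbl <- cds_tbl[order(cds_tbl$start), ]
    g0 <- as.integer(g$start - 1L); g1 <- as.integer(g$end)
    if (nrow(cds_tbl) > 0 &&
        (min(cds_tbl$start) < g0 || max(cds_tbl$end) > g1)) {
      stop("CDS outside parent gene ", gid)
    }
    coding <- nrow(cds_tbl) > 0
    if (coding && sum(cds_tbl$end - cds_tbl$start) %% 3L != 0L) {
      warning("gene ", gid, ": CDS length not divisible by 3; ",
              "marked non-coding")
      coding <- FALSE
    }
    out[[i]] <- tibble(
      gene_id = gid, scaffold = as.character(g$seqnames),
      start = g0, end = g1, strand = as.character(g$strand),
      coding = coding, cds = list(cds_tbl))
  }
  dplyr::bind_rows(out)
}

#' Read biallelic SNPs from a VCF file
#'
#' Only biallelic single-nucleotide rows are used; indel and multiallelic
#' rows are skipped with a counted warning. POS is converted from 1-based
#' to the internal 0-based convention. Zygosity is taken from the first
#' sample's GT field when present (`het` for 0/1-style genotypes, `hom`
#' otherwise); rows without genotypes default to `het`.
#'
#' @param path Path to an uncompressed VCF 4.x file.
#' @return Tibble with columns `scaffold`, `pos` (0-based), `ref`, `alt`,
#'   `zygosity`.
#' @export
read_vcf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0) stop("missing #CHROM header in ", path)
  body <- lines[seq_along(lines) > hdr[1] & !grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(tibble(scaffold = character(), pos = integer(), ref = character(),
                  alt = character(), zygosity = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  ncol_min <- min(lengths(f))
  if (ncol_min < 5) stop("VCF rows with fewer than 5 columns")
  chrom <- vapply(f, `[[`, character(1), 1)
  pos <- as.integer(vapply(f, `[[`, character(1), 2))
  ref <- vapply(f, `[[`, character(1), 4)
  alt <- vapply(f, `[[`, character(1), 5)
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    warning(n_skip, " non-biallelic-SNP row(s) skipped")
  }
  gt <- vapply(f, function(x) {
    if (length(x) >= 10) sub(":.*$", "", x[[10]]) else NA_character_
  }, character(1))
  zyg <- ifelse(is.na(gt), "het",
                ifelse(grepl("^(0[/|]1|1[/|]0)", gt), "het", "hom"))
  tibble(scaffold = chrom[keep], pos = pos[keep] - 1L, ref = ref[keep],
         alt = alt[keep], zygosity = zyg[keep])
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] kept so
#' that all external formats enter and leave through one module.
#'
#' @param path Path to a Newick file.
#' @return `read_newick()`: an [ape::phylo] object (or `multiPhylo` when
#'   the file holds several trees).
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` (or `multiPhylo`) object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path Path to a 3+ column BED (0-based half-open) file,
#'   tab-separated, no header.
#' @return Tibble with `scaffold`, `start`, `end` (plus `name` if a 4th
#'   column is present).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("scaffold", "start", "end", "name",
                                        "score", "strand")[1:max(3,
                            length(strsplit(readLines(path, n = 1),
                                            "\t")[[1]]))],
                          fill = TRUE)
  as_tibble(df)
}

#' Write intervals to BED
#'
#' @param bed Tibble with `scaffold`, `start`, `end` columns (0-based
#'   half-open).
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
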