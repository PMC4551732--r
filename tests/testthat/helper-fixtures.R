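# shared fixtures built in code

trad_tree <- function(unit_lengths = TRUE) {
  tr <- ape::read.tree(text = "(((((Mci,Hme),Dpl),Pgl),Lac),Bmo,Pxy);")
  if (unit_lengths) tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# hand-built diploid truth: one high-het block in an otherwise SNP-free
# genome, with SNPs planted every `every` bp inside the block
toy_diploid <- function(len = 20000L, block = c(5000L, 10000L),
                        every = 40L, seed = 42) {
  hap1 <- lepcompgen:::with_seed(seed,
    lepcompgen:::random_dna(len))
  pos <- seq(block[1], block[2] - 1L, by = every)
  h2 <- strsplit(hap1, "")[[1]]
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  h2[pos + 1L] <- flip[h2[pos + 1L]]
  structure(list(
    hap1 = hap1, hap2 = paste(h2, collapse = ""),
    snp_positions = pos,
    block_table = tibble::tibble(
      start = c(0L, block[1], block[2]),
      end = c(block[1], block[2], len),
      rate_class = c("free", "high", "free"),
      rate = c(0, 1 / every, 0))), class = "diploid_truth")
}

write_toy_gff3 <- function(path, lines) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

write_toy_vcf <- function(path, rows) {
  writeLines(c("##fileformat=VCFv4.2",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\t",
                      "FORMAT\tS1"),
               rows), path)
  path
}

# one-gene assembly + gene model with the given CDS on the given strand
toy_gene <- function(cds_seq, strand = "+", flank = 10L, seed = 5) {
  left <- lepcompgen:::with_seed(seed, lepcompgen:::random_dna(flank))
  right <- lepcompgen:::with_seed(seed + 1, lepcompgen:::random_dna(flank))
  genomic <- if (strand == "+") cds_seq else lepcompgen::revcomp(cds_seq)
  seqs <- paste0(left, genomic, right)
  gene <- tibble::tibble(
    gene_id = "g1", scaffold = "s1", start = flank,
    end = flank + nchar(cds_seq), strand = strand, coding = TRUE,
    cds = list(tibble::tibble(start = flank,
                              end = flank + nchar(cds_seq))))
  list(assembly = tibble::tibble(id = "s1", sequence = seqs,
                                 length = nchar(seqs)),
       gene = gene)
}
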