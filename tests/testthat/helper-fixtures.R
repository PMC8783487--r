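# shared fixture builders (everything generated in code; no stored data)

tiny_assembly <- function(..., genome_id = "g") {
  contigs <- c(...)
  genome_assembly(genome_id, contigs)
}

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

# minimal gene-record table for pangenome tests that need only proteins
protein_records <- function(ids, genomes, aa) {
  data.frame(gene_id = ids, genome_id = genomes, contig_id = "c1",
             start = 1L, end = 3L * nchar(aa) + 3L, strand = "+",
             type = "CDS", product = "", nt_seq = "", aa_seq = aa,
             stringsAsFactors = FALSE)
}

random_protein <- function(n, seed) {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  set.seed(seed)
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# patristic matrix of a random unrooted binary tree (additive by construction)
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  list(tree = ape::unroot(tr), d = stats::cophenetic(tr))
}
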