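test_that("FASTA reading uppercases, parses header tokens and validates", {
  path <- write_tmp_fasta(list(c1 = "acgt", "c2 extra descr" = "GGGG"))
  g <- read_genome_fasta(path, genome_id = "t")
  expect_identical(names(g$contigs), c("c1", "c2"))
  expect_identical(unname(g$contigs), c("ACGT", "GGGG"))
  expect_identical(unname(nchar(g$contigs)), c(4L, 4L))
})

test_that("degenerate FASTA inputs error informatively", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_genome_fasta(empty), "no sequences")
  dup <- write_tmp_fasta(list(c1 = "ACGT"))
  cat(">c1\nTTTT\n", file = dup, append = TRUE)
  expect_error(read_genome_fasta(dup), "duplicate contig_id")
  badchar <- write_tmp_fasta(list(c1 = "ACGJT"))
  expect_error(read_genome_fasta(badchar), "non-IUPAC character 'J'.*position 4")
})

test_that("write/read round-trips a generated multi-contig assembly", {
  g <- random_genome(50000, gc = 0.55, n_contigs = 5, seed = 101)
  path <- tempfile(fileext = ".fasta")
  write_genome_fasta(g, path)
  g2 <- read_genome_fasta(path, genome_id = g$genome_id)
  expect_identical(g2$contigs, g$contigs)
})

test_that("assembly stats: size exact, GC over unambiguous bases only", {
  expect_equal(assembly_stats(tiny_assembly(c1 = "ATGC"))$gc_percent, 50.0)
  expect_equal(assembly_stats(tiny_assembly(c1 = "AAAA"))$gc_percent, 0.0)
  st <- assembly_stats(tiny_assembly(c1 = "ATGC", c2 = "NNGC"))
  expect_equal(st$size_bp, 8L)
  expect_equal(st$gc_percent, round(100 * 4 / 6, 1))  # Ns excluded
  expect_error(assembly_stats(tiny_assembly(c1 = "NNNN")), "undefined")
})

test_that("assembly stats invariant under contig reordering and splitting", {
  g <- random_genome(20400, gc = 0.4, n_contigs = 2, seed = 7)
  st <- assembly_stats(g)
  rev_g <- genome_assembly("r", rev(g$contigs))
  expect_equal(assembly_stats(rev_g)[c("size_bp", "gc_percent")],
               st[c("size_bp", "gc_percent")])
  s <- g$contigs[[1]]
  split_g <- genome_assembly("s", c(a = substr(s, 1, 5000),
                                    b = substr(s, 5001, nchar(s)),
                                    c = g$contigs[[2]]))
  expect_equal(assembly_stats(split_g)[c("size_bp", "gc_percent")],
               st[c("size_bp", "gc_percent")])
})

test_that("annotation records extract strand-oriented sequences with bounds checks", {
  g <- tiny_assembly(c1 = "ATGAAATAAGG", c2 = "TTACAT")
  tab <- data.frame(gene_id = c("g1", "g2"), contig_id = c("c1", "c2"),
                    start = c(1L, 1L), end = c(9L, 6L),
                    strand = c("+", "-"), type = "CDS", product = "",
                    stringsAsFactors = FALSE)
  rec <- taxgenomics:::gene_records(tab, g)
  expect_identical(rec$nt_seq, c("ATGAAATAA", "ATGTAA"))

  bad <- tab
  bad$end[1] <- 12L
  expect_error(taxgenomics:::gene_records(bad, g), "outside contig.*'g1'")
  bad2 <- tab
  bad2$contig_id[2] <- "nope"
  expect_error(taxgenomics:::gene_records(bad2, g), "unknown contig_id 'nope'")
})

test_that("annotation files (delimited and GFF3) are parsed equivalently", {
  g <- tiny_assembly(c1 = "ATGAAATAAGGCCTTACATGG")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcontig_id\tstart\tend\tstrand\tproduct",
               "g1\tc1\t1\t9\t+\tdemo protein"), tsv)
  rec <- read_annotation(tsv, g)
  expect_identical(rec$nt_seq, "ATGAAATAA")
  expect_identical(rec$product, "demo protein")

  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsim\tCDS\t1\t9\t.\t+\t0\tID=g1;product=demo protein",
               "c1\tsim\ttRNA\t10\t21\t.\t-\t.\tID=t1"), gff)
  rec2 <- read_annotation(gff, g)
  expect_identical(rec2$nt_seq[rec2$gene_id == "g1"], "ATGAAATAA")
  expect_identical(sort(rec2$type), c("CDS", "tRNA"))
})

test_that("translation uses the bacterial code with strict stop policy", {
  expect_identical(translate_cds("ATGAAATAA"), "MK")
  expect_identical(translate_cds("ATG"), "M")
  expect_error(translate_cds("ATGTAAAAA"), "internal stop at codon 2")
  expect_identical(translate_cds("ATGTAAAAA", internal_stop = "x"), "MXK")
  expect_error(translate_cds("ATGA"), "not divisible by 3")
  expect_identical(translate_cds("ATGNNNTAA"), "MX")
  # table 11: GTG codes valine internally
  expect_identical(translate_cds("ATGGTGTAA"), "MV")
})

test_that("minus-strand genes translate like the reverse complement of the plus slice", {
  sim <- simulate_pangenome(n_genomes = 2, n_core_families = 50,
                            n_private_per_genome = 0, p = 0, seed = 33)
  genes <- sim$genes
  asm <- sim$assemblies
  names(asm) <- vapply(asm, function(a) a$genome_id, "")
  checked <- 0L
  for (i in seq_len(nrow(genes))) {
    a <- asm[[genes$genome_id[i]]]
    plus_slice <- substr(a$contigs[[genes$contig_id[i]]], genes$start[i],
                         genes$end[i])
    oriented <- if (genes$strand[i] == "+") plus_slice else
      taxgenomics:::cpp_revcomp(plus_slice)
    expect_identical(translate_cds(unname(oriented)),
                     translate_cds(genes$nt_seq[i]))
    checked <- checked + 1L
  }
  expect_gte(checked, 100L)
})
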