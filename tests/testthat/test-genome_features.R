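make_ann <- function(genome_id, cds_lens, n_rrna = 0, n_trna = 0) {
  n <- length(cds_lens) + n_rrna + n_trna
  starts <- cumsum(c(1, rep(2000, n - 1)))
  lens <- c(cds_lens, rep(100, n_rrna), rep(80, n_trna))
  data.frame(gene_id = sprintf("%s_g%02d", genome_id, seq_len(n)),
             genome_id = genome_id, contig_id = "c1", start = starts,
             end = starts + lens - 1, strand = "+",
             type = c(rep("CDS", length(cds_lens)), rep("rRNA", n_rrna),
                      rep("tRNA", n_trna)),
             product = "", nt_seq = "", stringsAsFactors = FALSE)
}

test_that("the feature table reports counts and the lower-median CDS length", {
  g <- random_genome(102000, gc = 0.5, n_contigs = 1, seed = 3)
  ann <- make_ann(g$genome_id, c(300, 900, 600), n_rrna = 2, n_trna = 5)
  ft <- feature_table(list(g), list(ann))
  expect_equal(ft$n_cds, 3L)
  expect_equal(ft$n_rrna, 2L)
  expect_equal(ft$n_trna, 5L)
  expect_equal(ft$median_cds_len, 600L)
  expect_equal(ft$size_mbp, 0.1)

  even <- make_ann(g$genome_id, c(300, 600, 900, 1200))
  expect_equal(feature_table(list(g), list(even))$median_cds_len, 600L)

  # invariant under record reordering
  shuf <- ann[sample(nrow(ann)), ]
  expect_equal(feature_table(list(g), list(shuf)), ft)

  expect_warning(ft0 <- feature_table(list(g), list(NULL)), "no annotation")
  expect_true(is.na(ft0$n_cds))
})

test_that("feature counts recover a simulated genome's planted annotation", {
  sim <- simulate_pangenome(1, 20, 5, p = 0, seed = 13)
  ft <- feature_table(sim$assemblies, list(sim$genes))
  expect_equal(ft$n_cds, 25L)
  expect_equal(ft$median_cds_len,
               taxgenomics:::lower_median(sim$genes$end - sim$genes$start + 1L))
})

test_that("OLS regression matches hand-computed values and conventions", {
  r <- ols_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)

  expect_equal(ols_regression(c(1, 2, 3), c(5, 5, 5))$r_squared, 0)
  expect_error(ols_regression(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(ols_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("OLS agrees with the normal-equations solution on random instances", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    x <- rnorm(n)
    y <- 2 + 3 * x + rnorm(n)
    r <- ols_regression(x, y)
    # brute-force normal equations
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(r$intercept, beta[1], tolerance = 1e-10)
    expect_equal(r$slope, beta[2], tolerance = 1e-10)
    expect_equal(r$r_squared, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("trait screening matches products, symbols, and records evidence", {
  genes <- data.frame(
    gene_id = c("peg1", "peg2", "ppxgppA", "peg4"),
    genome_id = c("gA", "gA", "gA", "gB"),
    contig_id = "c1", start = 1, end = 3, strand = "+", type = "CDS",
    product = c("anthranilate synthase component I",
                "1-aminocyclopropane-1-carboxylate deaminase",
                "exopolyphosphatase", "hypothetical protein"),
    nt_seq = "", stringsAsFactors = FALSE)
  tm <- trait_screen(genes)
  expect_true(tm$presence["trpE", "gA"])
  expect_true(tm$presence["acc", "gA"])
  expect_true(tm$presence["ppx-gppA", "gA"])  # symbol and product both match
  expect_false(any(tm$presence[, "gB"]))
  ev <- tm$evidence
  expect_true(all(c("trpE", "acc") %in% ev$trait))
  expect_true("peg1" %in% ev$gene_id[ev$trait == "trpE"])
})

test_that("trait screening is monotone under added records and empty input is all-absent", {
  none <- data.frame(gene_id = character(0), genome_id = character(0),
                     contig_id = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     type = character(0), product = character(0),
                     nt_seq = character(0), stringsAsFactors = FALSE)
  tm0 <- trait_screen(rbind(none, data.frame(
    gene_id = "x", genome_id = "gA", contig_id = "c1", start = 1, end = 3,
    strand = "+", type = "CDS", product = "hypothetical",
    nt_seq = "", stringsAsFactors = FALSE)))
  expect_false(any(tm0$presence))

  base <- data.frame(gene_id = "p1", genome_id = "gA", contig_id = "c1",
                     start = 1, end = 3, strand = "+", type = "CDS",
                     product = "chitinase", nt_seq = "",
                     stringsAsFactors = FALSE)
  more <- rbind(base, data.frame(gene_id = "p2", genome_id = "gA",
                                 contig_id = "c1", start = 10, end = 12,
                                 strand = "+", type = "CDS",
                                 product = "glucoamylase", nt_seq = "",
                                 stringsAsFactors = FALSE))
  t1 <- trait_screen(base)$presence
  t2 <- trait_screen(more)$presence
  expect_true(all(t2[t1]))  # nothing present became absent
})

test_that("malformed catalog patterns fail naming the trait", {
  genes <- data.frame(gene_id = "p1", genome_id = "gA", contig_id = "c1",
                      start = 1, end = 3, strand = "+", type = "CDS",
                      product = "x", nt_seq = "", stringsAsFactors = FALSE)
  cat <- data.frame(trait = "broken", symbols = "zzz", patterns = "([bad",
                    stringsAsFactors = FALSE)
  expect_error(trait_screen(genes, cat), "malformed pattern.*broken")
})

test_that("trait matrix writes Table-S4-style +/- cells", {
  genes <- data.frame(gene_id = "p1", genome_id = "gA", contig_id = "c1",
                      start = 1, end = 3, strand = "+", type = "CDS",
                      product = "chitinase", nt_seq = "",
                      stringsAsFactors = FALSE)
  tm <- trait_screen(genes)
  path <- tempfile(fileext = ".tsv")
  write_trait_matrix(tm, path)
  back <- read.delim(path, check.names = FALSE)
  expect_identical(back$gA[back$trait == "chitinase"], "+")
  expect_identical(back$gA[back$trait == "trpA"], "-")
})
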