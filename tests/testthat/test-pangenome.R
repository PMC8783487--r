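test_that("identical proteins across genomes hit with identity 1 in both directions", {
  p <- random_protein(120, seed = 1)
  genes <- protein_records(c("a1", "b1"), c("gA", "gB"), c(p, p))
  hits <- all_vs_all_search(genes)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$identity_fraction == 1))
  expect_true(all(hits$query_coverage == 1))
})

test_that("proteins sharing no k-mers produce no hits; missing aa_seq errors", {
  genes <- protein_records(c("a1", "b1"), c("gA", "gB"),
                           c(strrep("AR", 60), strrep("GW", 60)))
  expect_equal(nrow(all_vs_all_search(genes)), 0L)
  genes$aa_seq[2] <- NA
  expect_error(all_vs_all_search(genes), "lacking aa_seq.*b1")
})

test_that("prefiltered search reproduces the brute-force oracle on a simulated set", {
  sim <- simulate_pangenome(3, 12, 2, p = 0.05, seed = 7)
  fast <- all_vs_all_search(sim$genes, prefilter = TRUE)
  slow <- all_vs_all_search(sim$genes, prefilter = FALSE)
  # prefilter soundness: hit set is a subset
  key <- function(h) paste(h$query_gene, h$subject_gene)
  expect_true(all(key(fast) %in% key(slow)))
  # top hits agree
  tf <- taxgenomics:::top_hits(fast)
  ts <- taxgenomics:::top_hits(slow)
  cols <- c("query_gene", "subject_genome", "subject_gene")
  expect_identical(tf[cols], ts[cols])
})

test_that("reciprocal pairing requires bidirectional top hits with deterministic ties", {
  hit <- function(q, s, qg, sg, score, id = score / 100)
    data.frame(query_gene = q, subject_gene = s, query_genome = qg,
               subject_genome = sg, score = score, identities = 1L,
               columns = 1L, identity_fraction = id, query_coverage = 1,
               stringsAsFactors = FALSE)
  # a1 <-> b1 mutual top
  h <- rbind(hit("a1", "b1", "gA", "gB", 500),
             hit("b1", "a1", "gB", "gA", 500))
  expect_identical(reciprocal_best_pairs(h)$gene_a, "a1")

  # a1's top is b1, but b1's top is a2: no pair involving a1
  h2 <- rbind(hit("a1", "b1", "gA", "gB", 500),
              hit("b1", "a1", "gB", "gA", 400),
              hit("b1", "a2", "gB", "gA", 600),
              hit("a2", "b1", "gA", "gB", 600))
  p2 <- reciprocal_best_pairs(h2)
  expect_false("a1" %in% c(p2$gene_a, p2$gene_b))
  expect_true("a2" %in% p2$gene_a)

  # equal score and identity: lexicographic winner b1, pair iff b1 reciprocates
  h3 <- rbind(hit("a1", "b1", "gA", "gB", 500),
              hit("a1", "b2", "gA", "gB", 500),
              hit("b1", "a1", "gB", "gA", 500),
              hit("b2", "a1", "gB", "gA", 500))
  p3 <- reciprocal_best_pairs(h3)
  expect_identical(p3$gene_b, "b1")
})

test_that("POGs are connected components under single linkage", {
  pairs <- data.frame(gene_a = c("a1", "b1"), gene_b = c("b1", "c1"),
                      genome_a = c("gA", "gB"), genome_b = c("gB", "gC"),
                      stringsAsFactors = FALSE)
  pogs <- build_pogs(pairs)
  expect_equal(length(unique(pogs$pog_id)), 1L)
  expect_setequal(pogs$gene_id, c("a1", "b1", "c1"))
  expect_identical(unique(pogs$pog_id), "POG_a1")

  disjoint <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                         genome_a = "gA", genome_b = "gB",
                         stringsAsFactors = FALSE)
  expect_equal(length(unique(build_pogs(disjoint)$pog_id)), 2L)

  # pair-only rule never merges
  po <- build_pogs(pairs, merge_rule = "pair_only")
  expect_equal(length(unique(po$pog_id)), 1L)  # b1 consumed by first pair
  expect_setequal(po$gene_id, c("a1", "b1"))
})

test_that("partial genes attach at >= 95% identity, inclusively", {
  centroid <- random_protein(100, seed = 5)
  genes <- protein_records(c("a1", "b1"), c("gA", "gB"),
                           c(centroid, centroid))
  pogs <- build_pogs(data.frame(gene_a = "a1", gene_b = "b1",
                                genome_a = "gA", genome_b = "gB",
                                stringsAsFactors = FALSE))
  mutate_at <- function(s, pos) {
    x <- strsplit(s, "")[[1]]
    x[pos] <- ifelse(x[pos] == "A", "V", "A")
    paste(x, collapse = "")
  }
  half <- substr(centroid, 1, 50)   # partial gene, 50 aa
  p96 <- mutate_at(half, c(10, 20))          # 48/50 = 0.96
  p94 <- mutate_at(half, c(10, 20, 30))      # 47/50 = 0.94
  p95 <- mutate_at(substr(centroid, 1, 40), c(10, 20))  # 38/40 = 0.95
  un <- protein_records(c("x96", "x94", "x95"), "gC", c(p96, p94, p95))
  res <- attach_partial_genes(pogs, un, rbind(genes, un))
  attached <- res$pogs$gene_id[res$pogs$pog_id == "POG_a1"]
  expect_true(all(c("x96", "x95") %in% attached))
  expect_identical(res$unassigned, "x94")
})

test_that("partitioning separates core, accessory and strain-specific genes", {
  sim <- simulate_pangenome(3, 30, 5, p = 0.03, seed = 19)
  hits <- all_vs_all_search(sim$genes)
  pogs <- build_pogs(reciprocal_best_pairs(hits))
  part <- partition_pangenome(pogs, sim$genes)
  expect_equal(unname(part$per_genome[, "core"]), rep(30L, 3))
  expect_equal(unname(part$per_genome[, "strain_specific"]), rep(5L, 3))
  # conservation: classes partition the gene universe
  expect_identical(sort(names(part$gene_class)), sort(sim$genes$gene_id))
  expect_equal(sum(part$per_genome), nrow(sim$genes))
  # a gene belongs to at most one POG
  expect_identical(anyDuplicated(pogs$gene_id), 0L)

  solo <- partition_pangenome(pogs[0, ],
                              sim$genes[sim$genes$genome_id == "sg1", ])
  expect_true(all(solo$gene_class == "strain_specific"))
  expect_equal(length(solo$core_pog_ids), 0L)

  # POG in 2 of 3 genomes is accessory, not core
  two <- data.frame(gene_a = "sg1_f001", gene_b = "sg2_f001",
                    genome_a = "sg1", genome_b = "sg2",
                    stringsAsFactors = FALSE)
  p2 <- partition_pangenome(build_pogs(two), sim$genes)
  expect_identical(unname(p2$gene_class["sg1_f001"]), "accessory")
})

test_that("ortholog recovery stays near-perfect at low divergence and degrades at high", {
  rec <- function(p, seed) {
    sim <- simulate_pangenome(3, 20, 0, p = p, seed = seed)
    pairs <- reciprocal_best_pairs(all_vs_all_search(sim$genes))
    truth <- sim$truth$families
    fam <- split(truth$gene_id, truth$family_id)
    expected <- unlist(lapply(fam, function(g) {
      cmb <- t(combn(sort(g), 2)); paste(cmb[, 1], cmb[, 2])
    }), use.names = FALSE)
    got <- paste(pairs$gene_a, pairs$gene_b)
    mean(expected %in% got)
  }
  lo <- rec(0.025, seed = 23)  # ~5% pairwise nucleotide divergence
  hi <- rec(0.20, seed = 23)
  expect_gte(lo, 0.95)
  expect_lte(hi, lo)
})

test_that("category frequencies count core and pan partitions with planted proportions", {
  sim <- simulate_pangenome(2, 10, 3, p = 0, seed = 29)
  hits <- all_vs_all_search(sim$genes)
  pogs <- build_pogs(reciprocal_best_pairs(hits))
  part <- partition_pangenome(pogs, sim$genes)

  all_e <- data.frame(gene_id = sim$genes$gene_id, category = "E",
                      stringsAsFactors = FALSE)
  fr <- category_frequencies(part, all_e)
  expect_identical(fr$category, "E")
  expect_equal(fr$pan_count, nrow(sim$genes))

  none <- category_frequencies(part, all_e[0, ])
  expect_identical(none$category, "unassigned")
  expect_equal(attr(none, "fraction_assigned_pan"), 0)

  # planted proportions: core genes E, private genes K
  planted <- data.frame(
    gene_id = sim$genes$gene_id,
    category = ifelse(grepl("_f", sim$genes$gene_id), "E", "K"),
    stringsAsFactors = FALSE)
  fp <- category_frequencies(part, planted)
  expect_equal(fp$core_count[fp$category == "E"], 20L)
  expect_equal(fp$pan_count[fp$category == "K"], 6L)
  expect_equal(fp$core_count[fp$category == "K"], 0L)

  bad <- planted; bad$category[1] <- "e"
  expect_error(category_frequencies(part, bad), "unknown category")
})

test_that("the ortholog matrix is symmetric with dominant diagonal", {
  sim <- simulate_pangenome(3, 15, 2, p = 0.02, seed = 37)
  pogs <- build_pogs(reciprocal_best_pairs(all_vs_all_search(sim$genes)))
  genomes <- sort(unique(sim$genes$genome_id))
  m <- ortholog_matrix(pogs, genomes)
  expect_identical(m, t(m))
  expect_true(all(diag(m) >= apply(m, 1, max)))
  # counting oracle from the membership table
  has <- table(pogs$pog_id, pogs$genome_id) > 0
  expect_equal(m["sg1", "sg2"], sum(has[, "sg1"] & has[, "sg2"]))
  expect_equal(m["sg1", "sg1"], sum(pogs$genome_id == "sg1"))

  path <- tempfile(fileext = ".tsv")
  write_ortholog_matrix(m, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(unname(as.matrix(back[, -1])), unname(m))
})

test_that("category maps read delimited files with configurable columns", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# eggNOG-mapper style", "query\tCOG_category",
               "g1\tE", "g2\tEG", "g3\t-"), path)
  m <- read_category_map(path, gene_col = "query",
                         category_col = "COG_category")
  expect_identical(m$gene_id, c("g1", "g2"))
  expect_identical(m$category, c("E", "E"))
  expect_error(read_category_map(path), "columns not found")
})
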