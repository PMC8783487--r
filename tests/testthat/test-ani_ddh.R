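test_that("fragmentation yields exact non-overlapping windows", {
  g <- random_genome(3100 + 1020, gc = 0.5, n_contigs = 1, seed = 2)
  g$contigs[[1]] <- substr(g$contigs[[1]], 1, 3100)
  f <- fragment_genome(g)
  expect_equal(nrow(f), 3L)  # floor(3100 / 1020); 40 bp discarded
  expect_equal(f$offset, c(1L, 1021L, 2041L))
  expect_true(all(nchar(f$seq) == 1020L))

  short <- tiny_assembly(c1 = strrep("A", 1019))
  expect_warning(f0 <- fragment_genome(short), "no fragments")
  expect_equal(nrow(f0), 0L)

  two <- random_genome(4080, gc = 0.5, n_contigs = 2, seed = 3)
  f2 <- fragment_genome(two)
  expect_equal(nrow(f2), 4L)
  expect_equal(f2$contig_id, c("c1", "c1", "c2", "c2"))
})

test_that("fragments dominated by N are dropped with a report", {
  g <- random_genome(3060, gc = 0.5, n_contigs = 1, seed = 4)
  s <- g$contigs[[1]]
  substr(s, 1021, 1021 + 299) <- strrep("N", 300)  # >20% N in fragment 2
  g$contigs[[1]] <- s
  expect_message(f <- fragment_genome(g), "dropped")
  expect_equal(nrow(f), 2L)
  expect_equal(attr(f, "n_dropped"), 1L)
})

test_that("HSP search finds planted exact, reverse-complement and mutated matches", {
  g <- random_genome(20400, gc = 0.5, n_contigs = 1, seed = 6)
  region <- substr(g$contigs[[1]], 5001, 6020)
  h <- find_hsps(region, g)
  expect_gte(nrow(h), 1L)
  expect_equal(h$identities[1], 1020L)
  expect_equal(h$aligned_len[1], 1020L)
  expect_equal(h$strand[1], "+")
  expect_equal(h$sstart[1], 5001L)

  hrc <- find_hsps(unname(taxgenomics:::cpp_revcomp(region)), g)
  expect_equal(hrc$strand[1], "-")
  expect_equal(hrc$identity_fraction[1], 1.0)

  # 51 substitutions planted away from the ends -> 969/1020 identity
  x <- strsplit(region, "")[[1]]
  set.seed(8)
  pos <- sample(30:990, 51)
  x[pos] <- vapply(x[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  hm <- find_hsps(paste(x, collapse = ""), g, min_identity = 0.9)
  expect_equal(hm$identities[1], 969L)
  expect_equal(hm$aligned_len[1], 1020L)
  expect_equal(hm$identity_fraction[1], 969 / 1020)
})

test_that("self-comparison is exact for ANI and dDDH", {
  g <- random_genome(30600, gc = 0.6, n_contigs = 2, seed = 10)
  r <- orthoani(g, g)
  expect_identical(r$ani_percent, 100)
  expect_identical(r$n_reciprocal_pairs, r$n_fragments_a)
  d <- ddh_distance(g, g)
  expect_identical(d$d2, 0)
  expect_false(d$no_homology)
})

test_that("d2 arithmetic follows 1 - sum(identities)/sum(aligned_len)", {
  # two genomes whose only homology is one 1000-bp region with 50 interior
  # substitutions; N runs around the planted copy pin the HSP ends, so each
  # direction contributes exactly one HSP of 950/1000
  base <- random_genome(5100, gc = 0.5, n_contigs = 1, seed = 31)
  other <- random_genome(5100, gc = 0.5, n_contigs = 1, seed = 32)
  shared <- substr(base$contigs[[1]], 2001, 3000)
  x <- strsplit(shared, "")[[1]]
  set.seed(33)
  pos <- sample(30:970, 50)
  x[pos] <- vapply(x[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  mut <- paste(x, collapse = "")
  o <- other$contigs[[1]]
  pad <- strrep("N", 30)
  b <- genome_assembly("b", c(c1 = paste0(substr(o, 1, 1970), pad, mut, pad,
                                          substr(o, 3061, 5100))))
  d <- ddh_distance(base, b)
  expect_equal(d$sum_identities / d$n_hsps, 950)
  expect_equal(d$sum_aligned / d$n_hsps, 1000)
  expect_equal(d$d2, 0.05)
})

test_that("unrelated genomes are flagged as having no homology", {
  a <- random_genome(20400, gc = 0.5, n_contigs = 1, seed = 41)
  b <- random_genome(20400, gc = 0.5, n_contigs = 1, seed = 42)
  d <- ddh_distance(a, b)
  expect_true(d$no_homology)
  expect_identical(d$d2, 1)
})

test_that("ANI estimates track the simulated divergence and stay symmetric", {
  sp <- simulate_genome_pair(102000, gc = 0.5, p = 0.03, seed = 51)
  r <- orthoani(sp$a, sp$b)
  expect_lt(abs(r$ani_percent - 97.0), 0.5)
  expect_lt(abs(r$mean_ab - r$mean_ba), 1.0)  # percentage points
})

test_that("ANI decreases and d2 increases monotonically with divergence", {
  ps <- c(0.01, 0.05, 0.10, 0.20)
  ani <- d2 <- numeric(length(ps))
  for (i in seq_along(ps)) {
    sp <- simulate_genome_pair(61200, gc = 0.5, p = ps[i], seed = 60 + i)
    ani[i] <- orthoani(sp$a, sp$b)$ani_percent
    d2[i] <- ddh_distance(sp$a, sp$b)$d2
  }
  expect_true(all(diff(ani) < 0))
  expect_true(all(diff(d2) > 0))
})

test_that("saturated divergence degrades gracefully", {
  sp <- simulate_genome_pair(30600, gc = 0.5, p = 0.5, seed = 71)
  r <- orthoani(sp$a, sp$b)
  expect_true(r$undefined || r$ani_percent < 70)
})

test_that("the d2-to-DDH mapping is monotone and anchored at the species boundary", {
  cfg <- ddh_config()
  d <- seq(0, 1, by = 0.005)
  y <- map_d2_to_ddh(d, cfg$mapping)
  expect_true(all(diff(y) <= 0))
  expect_gte(map_d2_to_ddh(0, cfg$mapping), 70)   # identical genomes: same species
  expect_equal(map_d2_to_ddh(0.0336, cfg$mapping), 70, tolerance = 0.01)
  expect_error(ddh_config(mapping = list(model = "logistic", intercept = 0,
                                         slope = 5)),
               "monotone")
})

test_that("distance matrices are symmetric, zero-diagonal and round-trip", {
  g <- random_genome(20400, gc = 0.5, n_contigs = 1, seed = 81)
  twin <- g; twin$genome_id <- "twin"
  m0 <- distance_matrix(list(g, twin), metric = "d2")
  expect_identical(unname(m0), matrix(0, 2, 2))

  anc <- random_genome(30600, gc = 0.5, n_contigs = 1, seed = 90)
  gs <- lapply(1:3, function(i) {
    m <- mutate_genome(anc, p = 0.015 * i, seed = 91 + i)$genome
    m$genome_id <- sprintf("derived%d", i)
    m
  })
  m <- distance_matrix(gs, metric = "ani_distance")
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  # matches the per-pair calls exactly
  r12 <- orthoani(gs[[1]], gs[[2]])
  expect_equal(m[1, 2], 1 - r12$ani_percent / 100)

  path <- tempfile(fileext = ".tsv")
  write_distance_matrix(m, path)
  expect_equal(read_distance_matrix(path), m)
})

test_that("species-boundary classification separates published pairs from self-pairs", {
  tab <- published_reference("ani_ddh")
  calls <- classify_species(tab$ani_percent, tab$ddh_percent)
  expect_true(all(calls == "distinct"))
  expect_identical(classify_species(100, map_d2_to_ddh(0)), "same")
  expect_identical(classify_species(96.2, NA), "same")
  expect_identical(classify_species(NA, 81), "same")
  expect_error(classify_species(NA, NA), "at least one measure")
})
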