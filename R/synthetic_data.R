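# Synthetic genome evolution: every generator runs in its own RNG scope
# (seeded explicitly, global .Random.seed restored) so fixtures are
# byte-reproducible and independent of surrounding code.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random genome assembly
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc`, split evenly within the
#' G/C and A/T pairs. Contig lengths are near-equal. Identical seeds
#' reproduce identical assemblies.
#'
#' @param length total genome length in bases; must be at least
#'   `n_contigs * 1020` so every contig can contribute at least one ANI
#'   fragment.
#' @param gc target G+C fraction in `[0, 1]`.
#' @param n_contigs number of contigs.
#' @param seed integer seed.
#' @param genome_id label; default derived from the seed.
#' @return a [genome_assembly()].
#' @export
random_genome <- function(length, gc = 0.5, n_contigs = 1, seed,
                          genome_id = sprintf("sim%d", seed)) {
  if (length < n_contigs * 1020 || n_contigs < 1 || gc < 0 || gc > 1)
    stop("infeasible parameters: need length >= n_contigs * 1020 and gc in [0, 1]")
  with_seed(seed, {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    lens <- rep(length %/% n_contigs, n_contigs)
    extra <- length - sum(lens)
    if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1
    contigs <- vapply(lens, function(L)
      paste(sample(DNA_BASES, L, replace = TRUE, prob = probs),
            collapse = ""), "")
    names(contigs) <- sprintf("c%d", seq_len(n_contigs))
    genome_assembly(genome_id, contigs,
                    source = sprintf("random_genome(length=%d, gc=%g, seed=%d)",
                                     length, gc, seed))
  })
}

#' Evolve a genome under a per-site substitution (and optional indel) model
#'
#' Each unambiguous site is substituted with probability `p` to a uniformly
#' chosen different base. Indels, when enabled, are applied after
#' substitutions with geometric lengths; the substitution-only case (the
#' default) preserves length exactly and has closed-form expected identity
#' `1 - p`.
#'
#' @param ancestor a [genome_assembly()].
#' @param p per-site substitution probability in `[0, 0.75)`.
#' @param indel_rate per-site probability of starting an indel (half
#'   insertions, half deletions).
#' @param mean_indel_len mean indel length in bases.
#' @param seed integer seed.
#' @return list with `genome` (the derived assembly), `expected_identity`
#'   (`1 - p`; closed-form for the substitution-only case) and
#'   `n_substitutions` (realized count).
#' @export
mutate_genome <- function(ancestor, p, indel_rate = 0, mean_indel_len = 3,
                          seed) {
  stopifnot(inherits(ancestor, "genome_assembly"))
  if (p < 0 || p >= 0.75) stop("p must be in [0, 0.75)")
  if (indel_rate < 0) stop("indel_rate must be non-negative")
  with_seed(seed, {
    nsub <- 0L
    contigs <- vapply(ancestor$contigs, function(s) {
      x <- strsplit(s, "", fixed = TRUE)[[1]]
      n <- length(x)
      idx <- which(runif(n) < p & x %in% DNA_BASES)
      if (length(idx)) {
        shift <- sample.int(3L, length(idx), replace = TRUE)
        x[idx] <- DNA_BASES[(match(x[idx], DNA_BASES) - 1L + shift) %% 4L + 1L]
        nsub <<- nsub + length(idx)
      }
      if (indel_rate > 0) {
        ev <- which(runif(length(x)) < indel_rate)
        if (length(ev)) {
          lens <- rgeom(length(ev), 1 / mean_indel_len) + 1L
          del <- runif(length(ev)) < 0.5
          pieces <- character(0)
          prev <- 1L
          for (t in seq_along(ev)) {
            pos <- ev[t]
            if (pos < prev) next
            pieces <- c(pieces, paste(x[prev:pos], collapse = ""))
            if (del[t]) {
              prev <- min(length(x) + 1L, pos + lens[t] + 1L)
            } else {
              pieces <- c(pieces,
                          paste(sample(DNA_BASES, lens[t], replace = TRUE),
                                collapse = ""))
              prev <- pos + 1L
            }
          }
          if (prev <= length(x))
            pieces <- c(pieces, paste(x[prev:length(x)], collapse = ""))
          return(paste(pieces, collapse = ""))
        }
      }
      paste(x, collapse = "")
    }, "")
    names(contigs) <- names(ancestor$contigs)
    g <- genome_assembly(paste0(ancestor$genome_id, "_derived"), contigs,
                         source = sprintf("mutate_genome(p=%g, seed=%d)", p,
                                          seed))
    list(genome = g, expected_identity = 1 - p, n_substitutions = nsub)
  })
}

#' Simulate a genome pair with known expected ANI
#'
#' Draws an ancestor with [random_genome()] and derives a partner by
#' substitution-only evolution at rate `p`, so the expected ANI is
#' `100 * (1 - p)`.
#'
#' @param length genome length (bases).
#' @param gc G+C fraction.
#' @param p per-site substitution probability.
#' @param seed integer seed (the derived genome uses `seed + 1`).
#' @param n_contigs contigs per genome.
#' @return list `a`, `b` (assemblies), `expected_ani_percent`.
#' @export
simulate_genome_pair <- function(length, gc = 0.5, p, seed, n_contigs = 1) {
  a <- random_genome(length, gc, n_contigs, seed,
                     genome_id = sprintf("pairA_%d", seed))
  mb <- mutate_genome(a, p, seed = seed + 1)
  b <- mb$genome
  b$genome_id <- sprintf("pairB_%d", seed)
  list(a = a, b = b, expected_ani_percent = 100 * (1 - p),
       n_substitutions = mb$n_substitutions)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  # start codon + non-stop internals + stop; internal stops excluded by
  # construction
  codons <- character(n_codons)
  codons[1] <- "ATG"
  for (i in seq(2, n_codons - 1)) {
    repeat {
      cd <- paste(sample(DNA_BASES, 3, replace = TRUE), collapse = "")
      if (!(cd %in% STOP_CODONS)) break
    }
    codons[i] <- cd
  }
  codons[n_codons] <- "TAA"
  paste(codons, collapse = "")
}

mutate_cds <- function(nt, p) {
  x <- strsplit(nt, "", fixed = TRUE)[[1]]
  n <- length(x)
  ncod <- n %/% 3
  for (ci in seq_len(ncod)) {
    at <- (ci - 1) * 3 + 1:3
    repeat {
      cd <- x[at]
      hit <- runif(3) < p
      if (any(hit)) {
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        cd[hit] <- DNA_BASES[(match(cd[hit], DNA_BASES) - 1L + shift) %% 4L + 1L]
      }
      # non-terminal codons must not become stops (keeps fixtures translatable)
      if (ci == ncod || !(paste(cd, collapse = "") %in% STOP_CODONS)) {
        x[at] <- cd
        break
      }
    }
  }
  paste(x, collapse = "")
}

#' Simulate a multi-genome pan-genome with known ortholog families
#'
#' Core families are random coding sequences (start codon, no internal
#' stops); each genome receives an independently mutated copy of every
#' family at nucleotide substitution rate `p`, plus `n_private_per_genome`
#' unique random genes. Genes are embedded in random spacer DNA on one
#' contig per genome, on random strands. The returned truth table is the
#' oracle for orthology recovery tests.
#'
#' @param n_genomes number of genomes.
#' @param n_core_families families present in every genome.
#' @param n_private_per_genome unique genes per genome.
#' @param gene_len_range nucleotide length range for genes; rounded to
#'   codons. The default 300-900 bp brackets the median CDS length typical
#'   of actinobacterial genomes (~820-830 bp).
#' @param p per-site substitution probability applied independently to each
#'   family copy (pairwise divergence between copies is therefore about
#'   `2p`).
#' @param seed integer seed.
#' @param spacer_len_range length range of intergenic spacers.
#' @return list with `assemblies` (list of [genome_assembly()]), `genes`
#'   (gene records with `aa_seq`), and `truth` (`families`: family_id /
#'   genome_id / gene_id; `private`: genome_id / gene_id).
#' @export
simulate_pangenome <- function(n_genomes = 4, n_core_families = 50,
                               n_private_per_genome = 5,
                               gene_len_range = c(300, 900), p = 0.05,
                               seed = 1, spacer_len_range = c(100, 300)) {
  stopifnot(n_genomes >= 1, n_core_families >= 0, n_private_per_genome >= 0)
  with_seed(seed, {
    fam_codons <- sample(seq(gene_len_range[1] %/% 3, gene_len_range[2] %/% 3),
                         n_core_families, replace = TRUE)
    fam_seqs <- vapply(fam_codons, random_cds, "")
    assemblies <- vector("list", n_genomes)
    genes_list <- list()
    fam_rows <- list()
    priv_rows <- list()
    for (gi in seq_len(n_genomes)) {
      genome_id <- sprintf("sg%d", gi)
      items <- list()
      for (fi in seq_len(n_core_families)) {
        items[[length(items) + 1]] <- list(
          id = sprintf("%s_f%03d", genome_id, fi),
          seq = if (p > 0) mutate_cds(fam_seqs[fi], p) else fam_seqs[fi],
          family = sprintf("fam%03d", fi))
      }
      for (pi in seq_len(n_private_per_genome)) {
        ncod <- sample(seq(gene_len_range[1] %/% 3, gene_len_range[2] %/% 3), 1)
        items[[length(items) + 1]] <- list(
          id = sprintf("%s_p%03d", genome_id, pi),
          seq = random_cds(ncod), family = NA_character_)
      }
      items <- items[sample.int(length(items))]
      pieces <- character(0)
      pos <- 0L
      tab <- list()
      for (it in items) {
        sp <- paste(sample(DNA_BASES,
                           sample(seq(spacer_len_range[1], spacer_len_range[2]), 1),
                           replace = TRUE), collapse = "")
        pieces <- c(pieces, sp)
        pos <- pos + nchar(sp)
        strand <- sample(c("+", "-"), 1)
        emb <- if (strand == "+") it$seq else cpp_revcomp(it$seq)
        pieces <- c(pieces, emb)
        tab[[length(tab) + 1]] <- data.frame(
          gene_id = it$id, contig_id = "c1", start = pos + 1L,
          end = pos + nchar(emb), strand = strand, type = "CDS",
          product = "simulated protein", stringsAsFactors = FALSE)
        pos <- pos + nchar(emb)
        if (!is.na(it$family))
          fam_rows[[length(fam_rows) + 1]] <- data.frame(
            family_id = it$family, genome_id = genome_id, gene_id = it$id,
            stringsAsFactors = FALSE)
        else
          priv_rows[[length(priv_rows) + 1]] <- data.frame(
            genome_id = genome_id, gene_id = it$id, stringsAsFactors = FALSE)
      }
      tail_sp <- paste(sample(DNA_BASES, spacer_len_range[2], replace = TRUE),
                       collapse = "")
      contig <- paste(c(pieces, tail_sp), collapse = "")
      asm <- genome_assembly(genome_id, c(c1 = contig),
                             source = sprintf("simulate_pangenome(seed=%d)", seed))
      assemblies[[gi]] <- asm
      recs <- gene_records(do.call(rbind, tab), asm)
      genes_list[[gi]] <- recs
    }
    genes <- do.call(rbind, genes_list)
    rownames(genes) <- NULL
    genes <- translate_genes(genes)
    truth <- list(
      families = do.call(rbind, fam_rows),
      private = if (length(priv_rows)) do.call(rbind, priv_rows) else
        data.frame(genome_id = character(0), gene_id = character(0)),
      p = p)
    list(assemblies = assemblies, genes = genes, truth = truth)
  })
}

#' Simulate a marker (16S-like) sequence pair with an exact difference count
#'
#' Exactly `k_differences` distinct positions are substituted, so the true
#' similarity is `100 * (length - k) / length` and a gap-free pairwise
#' alignment must report exactly `k` differences.
#'
#' @param length sequence length.
#' @param k_differences number of substituted positions.
#' @param seed integer seed.
#' @return list `a`, `b` (character sequences), `exact_similarity`,
#'   `n_differences`.
#' @export
simulate_marker_pair <- function(length, k_differences, seed) {
  if (k_differences > length || k_differences < 0)
    stop("k_differences must be in [0, length]")
  with_seed(seed, {
    x <- sample(DNA_BASES, length, replace = TRUE)
    y <- x
    if (k_differences > 0) {
      pos <- sample.int(length, k_differences)
      shift <- sample.int(3L, k_differences, replace = TRUE)
      y[pos] <- DNA_BASES[(match(y[pos], DNA_BASES) - 1L + shift) %% 4L + 1L]
    }
    list(a = paste(x, collapse = ""), b = paste(y, collapse = ""),
         exact_similarity = 100 * (length - k_differences) / length,
         n_differences = k_differences)
  })
}
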