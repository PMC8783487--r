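# Pairwise orthologous groups (POGs): all-vs-all protein search with a
# shared-k-mer prefilter and affine-gap global alignment, reciprocal top
# hits, single-linkage POG construction, >=95%-identity attachment of
# partial genes, core/accessory/strain-specific partitioning and COG
# category profiling.

#' Pan-genome search configuration
#'
#' Defaults: shared 5-mer prefilter (at least `min_shared` common words),
#' global alignment under BLOSUM62 with gap open 11 / extend 1, hits kept
#' at identity >= 0.3 and query coverage >= 0.5.
#'
#' @param k prefilter word size.
#' @param min_shared minimum shared k-mers for a candidate pair.
#' @param gap_open,gap_ext affine gap costs.
#' @param min_identity,min_coverage hit retention floors.
#' @return list of class `pog_config`.
#' @export
pog_config <- function(k = 5L, min_shared = 1L, gap_open = 11L, gap_ext = 1L,
                       min_identity = 0.3, min_coverage = 0.5) {
  structure(as.list(environment()), class = "pog_config")
}

# 128x128 integer substitution lookup built from Biostrings' BLOSUM62;
# letter pairs outside the matrix score like the worst mismatch
blosum62_lookup <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  bl <- env$BLOSUM62
  m <- matrix(min(bl), 128, 128)
  # row/column index = character code + 1, so the C++ kernel can index the
  # flattened matrix directly with (unsigned char) values
  idx <- utf8ToInt(paste(rownames(bl), collapse = "")) + 1L
  for (i in seq_along(idx))
    for (j in seq_along(idx))
      m[idx[i], idx[j]] <- bl[i, j]
  storage.mode(m) <- "integer"
  m
}

the_blosum <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- blosum62_lookup()
    cache
  }
})

#' All-vs-all protein similarity search across genomes
#'
#' For each ordered genome pair, every query gene is searched against the
#' other genome's genes: candidate subjects share at least `min_shared`
#' k-mers with the query (set `prefilter = FALSE` for the brute-force
#' all-pairs search used as an oracle), then each candidate is aligned
#' globally under BLOSUM62 with affine gaps. Hits below the identity or
#' query-coverage floors are dropped; the rest are sorted per query by
#' score (ties by identity, then subject gene id).
#'
#' @param genes gene records with an `aa_seq` column (see
#'   [translate_genes()]); rows from at least two genomes.
#' @param cfg a [pog_config()].
#' @param prefilter use the shared-k-mer prefilter (default) or brute
#'   force.
#' @return data frame of similarity hits: `query_gene`, `subject_gene`,
#'   `query_genome`, `subject_genome`, `score`, `identities`, `columns`,
#'   `identity_fraction`, `query_coverage`.
#' @export
all_vs_all_search <- function(genes, cfg = pog_config(), prefilter = TRUE) {
  cds <- genes[genes$type == "CDS", , drop = FALSE]
  bad <- is.na(cds$aa_seq) | !nzchar(cds$aa_seq)
  if (any(bad))
    stop("gene lacking aa_seq: ", cds$gene_id[bad][1])
  genomes <- unique(cds$genome_id)
  if (length(genomes) < 2) stop("need genes from at least 2 genomes")
  sub <- the_blosum()
  out <- list()
  for (gq in genomes) {
    qi <- which(cds$genome_id == gq)
    for (gs in genomes) {
      if (gs == gq) next
      si <- which(cds$genome_id == gs)
      h <- cpp_protein_search(cds$aa_seq[qi], cds$aa_seq[si], sub,
                              cfg$gap_open, cfg$gap_ext, cfg$k,
                              cfg$min_shared, prefilter)
      if (nrow(h) == 0) next
      df <- data.frame(
        query_gene = cds$gene_id[qi][h$query],
        subject_gene = cds$gene_id[si][h$subject],
        query_genome = gq, subject_genome = gs,
        score = h$score, identities = h$identities, columns = h$columns,
        identity_fraction = h$identities / h$columns,
        query_coverage = h$query_aligned / nchar(cds$aa_seq[qi][h$query]),
        stringsAsFactors = FALSE)
      df <- df[df$identity_fraction >= cfg$min_identity &
                 df$query_coverage >= cfg$min_coverage, , drop = FALSE]
      out[[length(out) + 1]] <- df
    }
  }
  if (length(out) == 0)
    return(data.frame(query_gene = character(0), subject_gene = character(0),
                      query_genome = character(0),
                      subject_genome = character(0), score = integer(0),
                      identities = integer(0), columns = integer(0),
                      identity_fraction = numeric(0),
                      query_coverage = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$query_genome, res$query_gene, -res$score,
                   -res$identity_fraction, res$subject_gene), ]
  rownames(res) <- NULL
  res
}

# highest-scoring hit per (query gene, subject genome); ties broken by
# identity then lexicographic subject id
top_hits <- function(hits) {
  o <- order(hits$query_gene, hits$subject_genome, -hits$score,
             -hits$identity_fraction, hits$subject_gene)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h[c("query_gene", "subject_genome")]), , drop = FALSE]
}

#' Reciprocal top hits between genome pairs
#'
#' A pair `(a, b)` is emitted iff `b` is `a`'s highest-scoring hit in `b`'s
#' genome and `a` is `b`'s highest-scoring hit in `a`'s genome.
#'
#' @param hits similarity hits from [all_vs_all_search()] (both directions
#'   of each genome pair).
#' @return data frame `gene_a`, `gene_b`, `genome_a`, `genome_b`
#'   (`gene_a < gene_b` lexicographically).
#' @export
reciprocal_best_pairs <- function(hits) {
  th <- top_hits(hits)
  key <- paste(th$query_gene, th$subject_gene, sep = "\r")
  rev_key <- paste(th$subject_gene, th$query_gene, sep = "\r")
  recip <- th[key %in% rev_key & th$query_gene < th$subject_gene, ,
              drop = FALSE]
  out <- data.frame(gene_a = recip$query_gene, gene_b = recip$subject_gene,
                    genome_a = recip$query_genome,
                    genome_b = recip$subject_genome,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build pairwise orthologous groups from reciprocal pairs
#'
#' With the default single-linkage rule, POGs are the connected components
#' of the undirected graph whose edges are the reciprocal pairs; with
#' `merge_rule = "pair_only"` pairs are accepted greedily and never merged,
#' so every POG has exactly two members. Singleton genes are excluded at
#' this stage. POG ids derive deterministically from the smallest member
#' gene id.
#'
#' @param pairs reciprocal pairs from [reciprocal_best_pairs()].
#' @param merge_rule `"single_linkage"` (default) or `"pair_only"`.
#' @return data frame `pog_id`, `gene_id`, `genome_id`.
#' @export
build_pogs <- function(pairs, merge_rule = c("single_linkage", "pair_only")) {
  merge_rule <- match.arg(merge_rule)
  empty <- data.frame(pog_id = character(0), gene_id = character(0),
                      genome_id = character(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  genome_of <- c(stats::setNames(pairs$genome_a, pairs$gene_a),
                 stats::setNames(pairs$genome_b, pairs$gene_b))
  genome_of <- genome_of[!duplicated(names(genome_of))]
  if (merge_rule == "single_linkage") {
    g <- igraph::graph_from_data_frame(pairs[c("gene_a", "gene_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    member <- split(names(comp$membership), comp$membership)
  } else {
    used <- character(0)
    member <- list()
    for (i in seq_len(nrow(pairs))) {
      ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
      if (ga %in% used || gb %in% used) next
      member[[length(member) + 1]] <- c(ga, gb)
      used <- c(used, ga, gb)
    }
  }
  member <- lapply(member, sort)
  first <- vapply(member, `[`, "", 1)
  member <- member[order(first)]
  rows <- lapply(seq_along(member), function(i)
    data.frame(pog_id = paste0("POG_", member[[i]][1]),
               gene_id = member[[i]],
               genome_id = unname(genome_of[member[[i]]]),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach partial genes to existing POGs by high-identity clustering
#'
#' Greedy centroid clustering: each POG is represented by its longest
#' member; each unassigned gene (processed in descending length) is aligned
#' to every centroid with a free-end-gap protein alignment and attached to
#' the best centroid whose identity over the shorter sequence's length
#' reaches `identity_threshold` (inclusive). A gene attaches to at most one
#' POG.
#'
#' @param pogs POG membership from [build_pogs()].
#' @param unassigned gene records (with `aa_seq`) not yet in any POG.
#' @param genes full gene records, used to look up member sequences.
#' @param identity_threshold attachment floor in `(0, 1]` (default 0.95).
#' @param cfg a [pog_config()] (gap costs).
#' @return list `pogs` (updated membership) and `unassigned` (remaining
#'   gene ids).
#' @export
attach_partial_genes <- function(pogs, unassigned, genes,
                                 identity_threshold = 0.95,
                                 cfg = pog_config()) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(pogs) == 0 || nrow(unassigned) == 0)
    return(list(pogs = pogs, unassigned = unassigned$gene_id))
  sub <- the_blosum()
  aa <- stats::setNames(genes$aa_seq, genes$gene_id)
  centroid <- vapply(split(pogs$gene_id, pogs$pog_id), function(members) {
    members[which.max(nchar(aa[members]))]
  }, "")
  cen_seq <- aa[centroid]
  ua <- unassigned[order(-nchar(unassigned$aa_seq), unassigned$gene_id), ,
                   drop = FALSE]
  added <- list()
  left <- character(0)
  for (i in seq_len(nrow(ua))) {
    q <- ua$aa_seq[i]
    best_id <- NA_character_; best_frac <- -1
    for (ci in seq_along(cen_seq)) {
      r <- cpp_align_protein(q, cen_seq[[ci]], sub, cfg$gap_open,
                             cfg$gap_ext, "overlap")
      frac <- r$identities / min(nchar(q), nchar(cen_seq[[ci]]))
      if (frac > best_frac) {
        best_frac <- frac
        best_id <- names(centroid)[ci]
      }
    }
    if (!is.na(best_id) && best_frac >= identity_threshold) {
      added[[length(added) + 1]] <- data.frame(
        pog_id = best_id, gene_id = ua$gene_id[i],
        genome_id = ua$genome_id[i], stringsAsFactors = FALSE)
    } else {
      left <- c(left, ua$gene_id[i])
    }
  }
  pogs2 <- rbind(pogs, do.call(rbind, added))
  pogs2 <- pogs2[order(pogs2$pog_id, pogs2$gene_id), , drop = FALSE]
  rownames(pogs2) <- NULL
  list(pogs = pogs2, unassigned = sort(left))
}

#' Partition genes into core, accessory and strain-specific
#'
#' Core genes belong to POGs with at least one member in every genome;
#' strain-specific genes belong to no POG spanning two or more genomes
#' (this includes genes outside all POGs); the rest are accessory.
#'
#' @param pogs POG membership.
#' @param genes full gene records (the gene universe; CDS rows are
#'   partitioned).
#' @param genomes character vector of genome ids; defaults to the genomes
#'   present in `genes`.
#' @return object of class `pangenome_summary`: `n_pogs`, `core_pog_ids`,
#'   `gene_class` (named vector core/accessory/strain_specific per gene),
#'   `per_genome` (count table), `presence` (POG x genome member counts).
#' @export
partition_pangenome <- function(pogs, genes, genomes = NULL) {
  cds <- genes[genes$type == "CDS", , drop = FALSE]
  if (is.null(genomes)) genomes <- sort(unique(cds$genome_id))
  stray <- setdiff(pogs$gene_id, cds$gene_id)
  if (length(stray) > 0)
    stop("POG member not in gene universe: ", stray[1])
  presence <- table(factor(pogs$pog_id, levels = unique(pogs$pog_id)),
                    factor(pogs$genome_id, levels = genomes))
  span <- rowSums(presence > 0)
  core_ids <- rownames(presence)[span == length(genomes)]
  multi_ids <- rownames(presence)[span >= 2]
  pog_of <- stats::setNames(pogs$pog_id, pogs$gene_id)
  cls <- rep("strain_specific", nrow(cds))
  names(cls) <- cds$gene_id
  in_multi <- cds$gene_id %in% pogs$gene_id[pogs$pog_id %in% multi_ids]
  in_core <- cds$gene_id %in% pogs$gene_id[pogs$pog_id %in% core_ids]
  cls[in_multi] <- "accessory"
  cls[in_core] <- "core"
  per_genome <- table(factor(cds$genome_id, levels = genomes),
                      factor(cls, levels = c("core", "accessory",
                                             "strain_specific")))
  structure(list(n_pogs = length(unique(pogs$pog_id)),
                 core_pog_ids = core_ids, gene_class = cls,
                 per_genome = per_genome, presence = presence,
                 genomes = genomes),
            class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat(sprintf("<pangenome_summary> %d POGs (%d core) over %d genomes\n",
              x$n_pogs, length(x$core_pog_ids), length(x$genomes)))
  print(x$per_genome)
  invisible(x)
}

#' COG category frequencies for core and pan partitions
#'
#' Counts genes per one-letter COG functional category, separately for the
#' core partition and for the pan genome (all genes). Genes without a
#' mapping are counted under `unassigned`; the assigned fraction per
#' partition is reported, mirroring the core-versus-pan contrast in
#' functional annotation coverage.
#'
#' @param summary a `pangenome_summary`.
#' @param gene_to_category data frame `gene_id`, `category` (one-letter COG
#'   codes); the mapping may be partial.
#' @return data frame `category`, `core_count`, `pan_count`, with
#'   attributes `fraction_assigned_core` and `fraction_assigned_pan`.
#' @export
category_frequencies <- function(summary, gene_to_category) {
  stopifnot(inherits(summary, "pangenome_summary"))
  cat_map <- stats::setNames(gene_to_category$category,
                             gene_to_category$gene_id)
  bad <- !grepl("^[A-Z]$", cat_map)
  if (any(bad)) stop("unknown category letter: ", cat_map[bad][1])
  all_genes <- names(summary$gene_class)
  core_genes <- all_genes[summary$gene_class == "core"]
  lab <- function(genes) {
    x <- cat_map[genes]
    x[is.na(x)] <- "unassigned"
    x
  }
  core_tab <- table(lab(core_genes))
  pan_tab <- table(lab(all_genes))
  cats <- sort(union(names(core_tab), names(pan_tab)))
  cats <- c(setdiff(cats, "unassigned"),
            intersect("unassigned", cats))
  out <- data.frame(
    category = cats,
    core_count = as.integer(core_tab[cats]),
    pan_count = as.integer(pan_tab[cats]),
    stringsAsFactors = FALSE)
  out$core_count[is.na(out$core_count)] <- 0L
  out$pan_count[is.na(out$pan_count)] <- 0L
  attr(out, "fraction_assigned_core") <-
    if (length(core_genes)) sum(!is.na(cat_map[core_genes])) / length(core_genes) else NA_real_
  attr(out, "fraction_assigned_pan") <-
    if (length(all_genes)) sum(!is.na(cat_map[all_genes])) / length(all_genes) else NA_real_
  out
}

#' Pairwise ortholog matrix
#'
#' Square genome-by-genome matrix whose cell (i, j) counts the POGs with
#' members in both genome i and genome j; the diagonal counts each
#' genome's genes belonging to any POG.
#'
#' @param pogs POG membership.
#' @param genomes genome ids (order of the matrix).
#' @return symmetric integer matrix.
#' @export
ortholog_matrix <- function(pogs, genomes) {
  n <- length(genomes)
  m <- matrix(0L, n, n, dimnames = list(genomes, genomes))
  if (nrow(pogs) == 0) return(m)
  presence <- table(pogs$pog_id, factor(pogs$genome_id, levels = genomes))
  has <- presence > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- if (i == j) sum(presence[, i]) else
        sum(has[, i] & has[, j])
    }
  }
  m
}

#' Write POG outputs as TSV
#'
#' @param pogs POG membership data frame.
#' @param path output file.
#' @export
write_pog_membership <- function(pogs, path) {
  write.table(pogs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pog_membership
#' @param m ortholog matrix from [ortholog_matrix()].
#' @export
write_ortholog_matrix <- function(m, path) {
  df <- data.frame(genome_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-COG-category mapping from a delimited file
#'
#' Two-column TSV by default; column names are configurable so the
#' eggNOG-mapper annotations layout (`query`, `COG_category`) can be
#' consumed directly. Multi-letter category strings are reduced to their
#' first letter; `-` entries are treated as unassigned and dropped.
#'
#' @param path delimited file (`#` comment lines ignored).
#' @param gene_col,category_col column names holding the gene id and the
#'   one-letter category.
#' @return data frame `gene_id`, `category` suitable for
#'   [category_frequencies()].
#' @export
read_category_map <- function(path, gene_col = "gene_id",
                              category_col = "category") {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c(gene_col, category_col) %in% names(tab)))
    stop("columns not found: ", gene_col, ", ", category_col)
  cat <- substr(trimws(tab[[category_col]]), 1, 1)
  keep <- nzchar(cat) & cat != "-"
  data.frame(gene_id = tab[[gene_col]][keep], category = cat[keep],
             stringsAsFactors = FALSE)
}
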