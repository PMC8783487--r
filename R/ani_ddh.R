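# Fragment-based ANI (OrthoANI conventions: 1020-bp fragments, reciprocal
# best pairing, 35% identity / 70% coverage floors, symmetrized mean) and a
# digital DDH distance d2 = 1 - sum(identities) / sum(aligned_len) over
# retained HSPs, mapped to a hybridization percentage by a pluggable,
# monotonicity-checked logistic curve.

#' ANI configuration
#'
#' OrthoANI-style defaults: 1020-bp non-overlapping fragments, exact 13-mer
#' seeds, match +2 / mismatch -3, gap open 5 / extend 2, reciprocal pairs
#' kept at identity >= 0.35 and aligned coverage >= 0.7 of the fragment
#' length. Fragments with more than `max_n_frac` ambiguous bases are
#' dropped.
#'
#' @param fragment_len fragment length in bases.
#' @param k seed k-mer size.
#' @param match,mismatch,gap_open,gap_ext alignment scores (costs for gaps).
#' @param band alignment band half-width around the seeded diagonals.
#' @param min_identity reciprocal-pair identity floor.
#' @param min_coverage reciprocal-pair aligned-coverage floor.
#' @param max_candidates subject fragments aligned per query.
#' @param max_occ seeds occurring more often than this in the subject are
#'   ignored (repeat masking).
#' @param max_n_frac maximum fraction of N per fragment.
#' @return a list of class `ani_config`.
#' @export
ani_config <- function(fragment_len = 1020L, k = 13L, match = 2L,
                       mismatch = -3L, gap_open = 5L, gap_ext = 2L,
                       band = 32L, min_identity = 0.35, min_coverage = 0.7,
                       max_candidates = 4L, max_occ = 64L,
                       max_n_frac = 0.2) {
  structure(as.list(environment()), class = "ani_config")
}

#' Cut a genome into consecutive equal-length fragments
#'
#' Non-overlapping consecutive windows per contig; the trailing remainder
#' shorter than `fragment_len` is discarded, as are fragments whose fraction
#' of ambiguous bases exceeds `max_n_frac` (the dropped count is reported).
#'
#' @param g a [genome_assembly()].
#' @param fragment_len window length (>= 100).
#' @param max_n_frac ambiguity threshold per fragment.
#' @return data frame (class `fragment_set`) with columns `fragment_id`,
#'   `contig_id`, `offset` (1-based start), `seq`; attributes `genome_id`
#'   and `n_dropped`.
#' @export
fragment_genome <- function(g, fragment_len = 1020L, max_n_frac = 0.2) {
  stopifnot(inherits(g, "genome_assembly"))
  if (fragment_len < 100) stop("fragment_len must be >= 100")
  rows <- list()
  for (cid in names(g$contigs)) {
    L <- nchar(g$contigs[[cid]])
    nf <- L %/% fragment_len
    if (nf == 0) next
    starts <- (seq_len(nf) - 1L) * fragment_len + 1L
    rows[[cid]] <- data.frame(
      contig_id = cid, offset = starts,
      seq = substring(g$contigs[[cid]], starts, starts + fragment_len - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning(sprintf("genome '%s' shorter than fragment_len: no fragments",
                    g$genome_id))
    out <- data.frame(fragment_id = character(0), contig_id = character(0),
                      offset = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "genome_id") <- g$genome_id
    attr(out, "n_dropped") <- 0L
    class(out) <- c("fragment_set", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  nonacgt <- nchar(out$seq) - nchar(gsub("[^ACGT]", "", out$seq))
  keep <- nonacgt <= max_n_frac * fragment_len
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("%d fragment(s) with > %g%% ambiguous bases dropped",
                    n_dropped, 100 * max_n_frac))
  out <- out[keep, , drop = FALSE]
  out$fragment_id <- sprintf("%s_frag%05d", g$genome_id, seq_len(nrow(out)))
  out <- out[c("fragment_id", "contig_id", "offset", "seq")]
  rownames(out) <- NULL
  attr(out, "genome_id") <- g$genome_id
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("fragment_set", "data.frame")
  out
}

# best hit of every query fragment against a set of subject fragments
fragment_best_hits <- function(qfrag, sfrag, cfg) {
  hits <- cpp_fragment_best_hits(qfrag$seq, sfrag$seq, cfg$k, cfg$match,
                                 cfg$mismatch, cfg$gap_open, cfg$gap_ext,
                                 cfg$band, cfg$max_candidates, cfg$max_occ)
  hits$identity <- hits$identities / hits$columns
  hits$coverage <- (hits$qend - hits$qstart + 1) / nchar(qfrag$seq)
  hits
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Both genomes are cut into `fragment_len` windows; each fragment of A is
#' aligned to its best-matching fragment of B and vice versa. A fragment
#' pair is reciprocal when each member is the other's best hit with
#' identity >= `min_identity` and aligned coverage >= `min_coverage`. The
#' ANI is 100 times the mean identity over reciprocal pairs, averaging the
#' two alignment directions.
#'
#' @param a,b [genome_assembly()] objects.
#' @param cfg an [ani_config()].
#' @return object of class `ani_result`: `ani_percent` (NA with
#'   `undefined = TRUE` when no reciprocal pair exists), `n_reciprocal_pairs`,
#'   `mean_ab`, `mean_ba`, `n_fragments_a`, `n_fragments_b`.
#' @export
orthoani <- function(a, b, cfg = ani_config()) {
  fa <- fragment_genome(a, cfg$fragment_len, cfg$max_n_frac)
  fb <- fragment_genome(b, cfg$fragment_len, cfg$max_n_frac)
  if (nrow(fa) < 2 || nrow(fb) < 2)
    stop("orthoani needs at least 2 fragments per genome")
  ab <- fragment_best_hits(fa, fb, cfg)
  ba <- fragment_best_hits(fb, fa, cfg)
  ok_ab <- !is.na(ab$subject) & ab$identity >= cfg$min_identity &
    ab$coverage >= cfg$min_coverage
  ok_ba <- !is.na(ba$subject) & ba$identity >= cfg$min_identity &
    ba$coverage >= cfg$min_coverage
  # reciprocal: A fragment i -> B fragment j and B fragment j -> A fragment i
  pair_i <- which(ok_ab)
  pair_j <- ab$subject[pair_i]
  recip <- ok_ba[pair_j] & ba$subject[pair_j] == pair_i
  pi <- pair_i[recip]
  pj <- pair_j[recip]
  n <- length(pi)
  res <- structure(list(
    genome_a = a$genome_id, genome_b = b$genome_id,
    ani_percent = NA_real_, undefined = n == 0,
    n_reciprocal_pairs = n,
    mean_ab = NA_real_, mean_ba = NA_real_,
    n_fragments_a = nrow(fa), n_fragments_b = nrow(fb)),
    class = "ani_result")
  if (n > 0) {
    id_ab <- ab$identity[pi]
    id_ba <- ba$identity[pj]
    res$mean_ab <- 100 * mean(id_ab)
    res$mean_ba <- 100 * mean(id_ba)
    res$ani_percent <- 100 * mean((id_ab + id_ba) / 2)
  }
  res
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s vs %s: ANI = %s%% over %d reciprocal fragment pairs\n",
              x$genome_a, x$genome_b,
              if (x$undefined) "undefined" else sprintf("%.2f", x$ani_percent),
              x$n_reciprocal_pairs))
  invisible(x)
}

#' dDDH configuration
#'
#' HSP search parameters (exact 13-mer seeds, match +2 / mismatch -3, gap
#' open 5 / extend 2, minimum HSP length 100, minimum identity 0.3) and the
#' distance-to-DDH mapping. The default mapping is read from the packaged
#' `ddh_mapping.json` config: a logistic curve anchored at the published
#' species boundary (70% DDH at formula-2 distance 0.0336); it is pluggable
#' and validated only for monotonicity.
#'
#' @param k,match,mismatch,gap_open,gap_ext,band,max_occ alignment
#'   parameters as in [ani_config()].
#' @param max_gap maximum seed gap within one HSP chain.
#' @param min_identity,min_len,min_score HSP retention floors (identity
#'   fraction, aligned columns, alignment score).
#' @param mapping list with elements `model` (`"logistic"`), `intercept`,
#'   `slope`; replace to plug in other published coefficient sets.
#' @return a list of class `ddh_config`.
#' @export
ddh_config <- function(k = 13L, match = 2L, mismatch = -3L, gap_open = 5L,
                       gap_ext = 2L, band = 32L, max_gap = 500L,
                       min_identity = 0.3, min_len = 100L, min_score = 1L,
                       max_occ = 64L, mapping = NULL) {
  if (is.null(mapping)) mapping <- default_ddh_mapping()
  validate_ddh_mapping(mapping)
  structure(as.list(environment()), class = "ddh_config")
}

default_ddh_mapping <- function() {
  path <- system.file("extdata", "ddh_mapping.json", package = "taxgenomics")
  if (nzchar(path) && requireNamespace("jsonlite", quietly = TRUE)) {
    m <- jsonlite::fromJSON(path)
    return(list(model = m$model, intercept = m$intercept, slope = m$slope))
  }
  list(model = "logistic", intercept = 2.1494, slope = -38.754)
}

validate_ddh_mapping <- function(mapping) {
  if (!identical(mapping$model, "logistic"))
    stop("unsupported ddh mapping model: ", mapping$model)
  d <- seq(0, 1, by = 0.01)
  y <- map_d2_to_ddh(d, mapping)
  if (any(diff(y) > 1e-12))
    stop("ddh mapping must be monotone non-increasing in the distance")
  invisible(TRUE)
}

#' Map a formula-2 intergenomic distance to a DDH percentage
#'
#' @param d2 distance in `[0, 1]`.
#' @param mapping mapping list from [ddh_config()].
#' @return DDH percentage.
#' @export
map_d2_to_ddh <- function(d2, mapping = default_ddh_mapping()) {
  100 / (1 + exp(-(mapping$intercept + mapping$slope * d2)))
}

#' Local HSP search of a query sequence against an assembly
#'
#' Seed-and-extend: exact k-mer seeds on both strands, seeds clustered by
#' diagonal proximity, each cluster realigned with a banded affine-gap
#' overlap DP; overlapping HSPs are reduced keeping the higher-identity
#' one. Only HSPs with identity >= `min_identity` and aligned length >=
#' `min_len` are returned, sorted by score.
#'
#' @param query nucleotide sequence (character scalar).
#' @param subject a [genome_assembly()].
#' @param min_identity,min_len retention floors.
#' @param cfg a [ddh_config()] supplying the alignment parameters.
#' @return data frame of HSPs: `contig_id`, `strand`, `qstart`, `qend`,
#'   `sstart`, `send`, `identities`, `aligned_len`, `identity_fraction`,
#'   `score`.
#' @export
find_hsps <- function(query, subject, min_identity = 0.3, min_len = 100L,
                      cfg = ddh_config()) {
  stopifnot(inherits(subject, "genome_assembly"))
  if (!nzchar(query)) stop("empty query")
  h <- cpp_hsp_search(toupper(query), subject$contigs, cfg$k, cfg$match,
                      cfg$mismatch, cfg$gap_open, cfg$gap_ext, cfg$band,
                      cfg$max_gap, min_identity, as.integer(min_len),
                      cfg$max_occ, cfg$min_score)
  data.frame(contig_id = names(subject$contigs)[h$subject],
             strand = h$strand, qstart = h$qstart, qend = h$qend,
             sstart = h$sstart, send = h$send, identities = h$identities,
             aligned_len = h$aligned_len,
             identity_fraction = h$identities / h$aligned_len,
             score = h$score, stringsAsFactors = FALSE)
}

#' Digital DDH distance between two genomes
#'
#' HSPs are collected from an all-contig reciprocal search (every contig of
#' A against B and every contig of B against A). The intergenomic distance
#' is `d2 = 1 - sum(identities) / sum(aligned_len)` over the retained HSPs
#' (the formula preferred for draft genomes, since it does not depend on
#' genome length); `ddh_percent` is obtained through the configured
#' distance-to-DDH mapping.
#'
#' @param a,b [genome_assembly()] objects.
#' @param cfg a [ddh_config()].
#' @return object of class `ddh_result`: `d2`, `ddh_percent`, `n_hsps`,
#'   `sum_identities`, `sum_aligned`, `no_homology` flag, `mapping`.
#' @export
ddh_distance <- function(a, b, cfg = ddh_config()) {
  stopifnot(inherits(a, "genome_assembly"), inherits(b, "genome_assembly"))
  h1 <- cpp_hsp_search(a$contigs, b$contigs, cfg$k, cfg$match, cfg$mismatch,
                       cfg$gap_open, cfg$gap_ext, cfg$band, cfg$max_gap,
                       cfg$min_identity, cfg$min_len, cfg$max_occ,
                       cfg$min_score)
  h2 <- cpp_hsp_search(b$contigs, a$contigs, cfg$k, cfg$match, cfg$mismatch,
                       cfg$gap_open, cfg$gap_ext, cfg$band, cfg$max_gap,
                       cfg$min_identity, cfg$min_len, cfg$max_occ,
                       cfg$min_score)
  sum_id <- sum(h1$identities) + sum(h2$identities)
  sum_len <- sum(h1$aligned_len) + sum(h2$aligned_len)
  no_hom <- sum_len == 0
  d2 <- if (no_hom) 1 else 1 - sum_id / sum_len
  structure(list(genome_a = a$genome_id, genome_b = b$genome_id, d2 = d2,
                 ddh_percent = map_d2_to_ddh(d2, cfg$mapping),
                 n_hsps = nrow(h1) + nrow(h2), sum_identities = sum_id,
                 sum_aligned = sum_len, no_homology = no_hom,
                 mapping = cfg$mapping),
            class = "ddh_result")
}

#' @export
print.ddh_result <- function(x, ...) {
  cat(sprintf("<ddh_result> %s vs %s: d2 = %.4f, dDDH = %.1f%% (%d HSPs%s)\n",
              x$genome_a, x$genome_b, x$d2, x$ddh_percent, x$n_hsps,
              if (x$no_homology) "; no homology detected" else ""))
  invisible(x)
}

#' Symmetric distance matrix over a set of genomes
#'
#' @param genomes list of [genome_assembly()] objects (>= 2).
#' @param metric `"ani_distance"` (`1 - ANI/100`) or `"d2"`.
#' @param cfg configuration passed to [orthoani()] or [ddh_distance()].
#' @return symmetric matrix with zero diagonal, labelled by genome id.
#' @export
distance_matrix <- function(genomes, metric = c("ani_distance", "d2"),
                            cfg = NULL) {
  metric <- match.arg(metric)
  if (length(genomes) < 2) stop("at least 2 genomes required")
  ids <- vapply(genomes, function(g) g$genome_id, "")
  if (anyDuplicated(ids)) stop("genome ids must be unique")
  n <- length(genomes)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (is.null(cfg))
    cfg <- if (metric == "ani_distance") ani_config() else ddh_config()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (metric == "ani_distance") {
        r <- orthoani(genomes[[i]], genomes[[j]], cfg)
        if (r$undefined)
          stop(sprintf("ANI undefined for pair (%s, %s): no reciprocal fragments",
                       ids[i], ids[j]))
        d <- 1 - r$ani_percent / 100
      } else {
        r <- ddh_distance(genomes[[i]], genomes[[j]], cfg)
        d <- r$d2
      }
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

#' Write / read a labelled distance matrix as TSV
#'
#' @param m symmetric labelled matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(genome_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Species-boundary classification from ANI and dDDH
#'
#' Two genomes are called the same species when ANI is at or above the
#' 95-96% boundary (default threshold 95) or dDDH is at or above 70%;
#' otherwise they are distinct. Either measure may be missing.
#'
#' @param ani_percent,ddh_percent numeric vectors (NA allowed).
#' @param ani_threshold,ddh_threshold species boundaries.
#' @return character vector `"same"` / `"distinct"`.
#' @export
classify_species <- function(ani_percent = NA_real_, ddh_percent = NA_real_,
                             ani_threshold = 95, ddh_threshold = 70) {
  n <- max(length(ani_percent), length(ddh_percent))
  ani <- rep_len(ani_percent, n)
  ddh <- rep_len(ddh_percent, n)
  if (all(is.na(ani) & is.na(ddh))) stop("need at least one measure")
  same <- (!is.na(ani) & ani >= ani_threshold) |
    (!is.na(ddh) & ddh >= ddh_threshold)
  ifelse(same, "same", "distinct")
}
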