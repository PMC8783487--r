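# 16S rRNA marker similarity and neighbor-joining distance trees.

iupac_submat <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
               "H", "V", "N")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Pairwise marker-gene similarity with nucleotide-difference counting
#'
#' Semi-global alignment (terminal gaps free; match +1 / mismatch -1 / gap
#' -2 per gap column). Terminal gap columns are excluded from the compared
#' length; `n_differences` counts substitution columns only, internal gap
#' columns are reported separately. The similarity convention is
#' `100 * (aligned_len - n_differences - internal_gap_columns) / aligned_len`,
#' so for gap-free pairs it reduces to `100 * (L - k) / L`.
#'
#' @param a,b nucleotide sequences (character scalars, >= 100 bp).
#' @return object of class `marker_similarity` with fields
#'   `similarity_percent`, `n_differences`, `aligned_len`,
#'   `internal_gap_columns`.
#' @export
pairwise_global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) < 100 || nchar(b) < 100)
    stop("marker sequences must be at least 100 bp")
  for (s in list(a, b)) {
    amb <- nchar(gsub("[ACGT]", "", s))
    if (amb > 0.05 * nchar(s))
      warning(sprintf("sequence has %.1f%% ambiguous bases",
                      100 * amb / nchar(s)))
  }
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap", substitutionMatrix = iupac_submat(),
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # trim any terminal gap columns from the compared region
  gap <- pa == "-" | pb == "-"
  inner <- which(!gap)
  if (length(inner) == 0) stop("no aligned columns")
  keep <- seq(min(inner), max(inner))
  pa <- pa[keep]; pb <- pb[keep]
  gap <- gap[keep]
  ndiff <- sum(!gap & pa != pb)
  ngap <- sum(gap)
  L <- length(pa)
  structure(list(
    similarity_percent = 100 * (L - ndiff - ngap) / L,
    n_differences = ndiff, aligned_len = L, internal_gap_columns = ngap),
    class = "marker_similarity")
}

#' @export
print.marker_similarity <- function(x, ...) {
  cat(sprintf("<marker_similarity> %.2f%% over %d columns (%d differences, %d internal gap columns)\n",
              x$similarity_percent, x$aligned_len, x$n_differences,
              x$internal_gap_columns))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ agglomeration (via ape). Negative branch lengths, which NJ
#' can produce on non-additive input, are clamped to zero with the deficit
#' moved to the sibling branch so patristic distances are preserved as far
#' as possible; additive matrices are recovered exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and >= 3 taxa.
#' @return an [ape::phylo] tree (unrooted).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("at least 3 taxa required")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- sprintf("t%d", seq_len(nrow(d)))
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge[, 2]) != e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib) > 0)
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
  }
  tr
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo` object.
#' @param path output file.
#' @param digits branch-length precision.
#' @export
write_newick <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
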