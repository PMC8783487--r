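# Comparative genome feature table, CDS-count-versus-genome-size
# regression, and the plant-growth-promoting (PGP) gene trait screen.

#' Comparative genome feature table
#'
#' One row per genome: assembly size (Mbp), G+C content, rRNA / tRNA / CDS
#' counts and the median CDS length. The median uses the lower-median
#' convention for even counts. A genome without annotation yields NA counts
#' and a warning.
#'
#' @param assemblies list of [genome_assembly()] objects.
#' @param annotations list of gene-record data frames parallel to
#'   `assemblies` (NULL entries allowed).
#' @return data frame with columns `genome_id`, `size_mbp`, `gc_percent`,
#'   `n_rrna`, `n_trna`, `n_cds`, `median_cds_len`.
#' @export
feature_table <- function(assemblies, annotations) {
  stopifnot(length(assemblies) == length(annotations))
  rows <- lapply(seq_along(assemblies), function(i) {
    g <- assemblies[[i]]
    st <- assembly_stats(g)
    ann <- annotations[[i]]
    if (is.null(ann)) {
      warning(sprintf("genome '%s' has no annotation; counts are NA",
                      g$genome_id))
      return(data.frame(genome_id = g$genome_id,
                        size_mbp = round(st$size_bp / 1e6, 2),
                        gc_percent = st$gc_percent, n_rrna = NA_integer_,
                        n_trna = NA_integer_, n_cds = NA_integer_,
                        median_cds_len = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    cds_len <- ann$end[ann$type == "CDS"] - ann$start[ann$type == "CDS"] + 1L
    data.frame(genome_id = g$genome_id,
               size_mbp = round(st$size_bp / 1e6, 2),
               gc_percent = st$gc_percent,
               n_rrna = sum(ann$type == "rRNA"),
               n_trna = sum(ann$type == "tRNA"),
               n_cds = length(cds_len),
               median_cds_len = lower_median(cds_len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# lower median: for even n the smaller of the two middle order statistics
lower_median <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  sort(x)[floor((length(x) + 1) / 2)]
}

#' Ordinary least squares regression of CDS count on genome size
#'
#' Fits `y = intercept + slope * x` by OLS and reports the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` (0 by convention when `y` is
#' constant).
#'
#' @param x genome sizes (Mbp), at least 3 values, not all equal.
#' @param y CDS counts.
#' @return list of class `regression_result` with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 points required")
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop("zero variance in predictor")
  fit <- lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r_squared = r2,
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.1f + %.1f x, R^2 = %.3f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Read the plant-growth-promoting trait catalog
#'
#' The packaged catalog lists trait genes associated with direct (phosphate
#' solubilization, phytohormone/auxin pathways) and indirect (lytic enzyme
#' and antibiotic synthesis) plant-growth-promoting mechanisms, each with
#' gene symbols and product-description patterns.
#'
#' @param path TSV with columns `trait`, `symbols` (comma-separated),
#'   `patterns` (semicolon-separated case-insensitive regular expressions);
#'   defaults to the packaged catalog.
#' @return data frame.
#' @export
read_trait_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pgp_trait_catalog.tsv",
                        package = "taxgenomics")
  cat <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (anyDuplicated(cat$trait)) stop("duplicate catalog entries")
  cat
}

normalize_symbol <- function(x) gsub("-", "", tolower(x))

#' Screen genomes for trait genes
#'
#' A trait is present in a genome iff any gene record matches one of the
#' trait's gene symbols exactly (after normalization: lowercase, hyphens
#' stripped; matched against the gene id and, when present, a `gene`
#' symbol column) or one of its product-description patterns
#' (case-insensitive). Every presence call records its evidence gene ids,
#' so matches are auditable. Adding records can only turn absences into
#' presences, never the reverse.
#'
#' @param genes gene records for one or more genomes (column `product`
#'   used for pattern matching).
#' @param catalog trait catalog from [read_trait_catalog()].
#' @return object of class `trait_matrix`: `presence` (logical trait x
#'   genome matrix) and `evidence` (data frame trait / genome_id / gene_id /
#'   matched_by).
#' @export
trait_screen <- function(genes, catalog = read_trait_catalog()) {
  genomes <- sort(unique(genes$genome_id))
  presence <- matrix(FALSE, nrow(catalog), length(genomes),
                     dimnames = list(catalog$trait, genomes))
  ev <- list()
  sym_fields <- normalize_symbol(genes$gene_id)
  gene_col <- if (!is.null(genes$gene)) normalize_symbol(genes$gene) else NULL
  for (t in seq_len(nrow(catalog))) {
    trait <- catalog$trait[t]
    syms <- normalize_symbol(strsplit(catalog$symbols[t], ",")[[1]])
    syms <- trimws(syms)
    pats <- trimws(strsplit(catalog$patterns[t], ";")[[1]])
    pats <- pats[nzchar(pats)]
    hit <- sym_fields %in% syms
    if (!is.null(gene_col)) hit <- hit | gene_col %in% syms
    why <- ifelse(hit, "symbol", NA_character_)
    for (p in pats) {
      bad_pattern <- function(cond)
        stop(sprintf("malformed pattern for trait '%s': %s", trait,
                     conditionMessage(cond)), call. = FALSE)
      m <- tryCatch(grepl(p, genes$product, ignore.case = TRUE, perl = TRUE),
                    error = bad_pattern, warning = bad_pattern)
      why[m & !hit] <- paste0("pattern:", p)
      hit <- hit | m
    }
    if (any(hit)) {
      ev[[length(ev) + 1]] <- data.frame(
        trait = trait, genome_id = genes$genome_id[hit],
        gene_id = genes$gene_id[hit], matched_by = why[hit],
        stringsAsFactors = FALSE)
      for (g in unique(genes$genome_id[hit])) presence[trait, g] <- TRUE
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(trait = character(0), genome_id = character(0),
               gene_id = character(0), matched_by = character(0),
               stringsAsFactors = FALSE)
  structure(list(presence = presence, evidence = evidence),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  m <- ifelse(x$presence, "+", "-")
  print(m, quote = FALSE)
  invisible(x)
}

#' Write a trait matrix and its evidence as TSV
#'
#' @param tm a `trait_matrix`.
#' @param path output file for the +/- matrix.
#' @param evidence_path optional output for the evidence table.
#' @export
write_trait_matrix <- function(tm, path, evidence_path = NULL) {
  m <- ifelse(tm$presence, "+", "-")
  df <- data.frame(trait = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(evidence_path))
    write.table(tm$evidence, evidence_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Published reference tables for the Nocardia alni taxonomic study
#'
#' Packaged copies of the published comparison values for strain ncl2^T
#' (Nocardia alni DSM 110931^T) and its phylogenomic neighbours:
#' `"ani_ddh"` returns the pairwise ANI / dDDH percentages against the
#' eight reference type strains, and `"genome_features"` the per-genome
#' feature table (size, G+C, rRNA/tRNA/CDS counts, median CDS length).
#' These tables are inputs for the species-boundary classification and the
#' CDS-count-versus-genome-size regression.
#'
#' @param name which table.
#' @return data frame.
#' @export
published_reference <- function(name = c("ani_ddh", "genome_features")) {
  name <- match.arg(name)
  file <- c(ani_ddh = "nocardia_ani_ddh.tsv",
            genome_features = "nocardia_genome_features.tsv")[[name]]
  path <- system.file("extdata", file, package = "taxgenomics")
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
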