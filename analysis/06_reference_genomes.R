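#!/usr/bin/env Rscript
# Optional integration analysis: reproduces the published pairwise ANI and
# dDDH values for the Nocardia alni type strain against its sequenced
# neighbours. It needs the GenBank assemblies, which are not shipped with
# the package; download them separately and point this script at the
# directory:
#
#   Rscript analysis/06_reference_genomes.R <dir> [<query.fasta>]
#
# <dir> must contain FASTA files whose names start with the accession of
# each reference genome (BDCC00000000 N. vaccinii, BAGB00000000
# N. jiangxiensis, BDBQ00000000 N. miyunensis, JAFQ00000000 N. casuarinae,
# QQBC00000000 N. pseudobrasiliensis); the query defaults to a file
# starting with JAGPOX (the N. alni ncl2^T draft assembly). A 16S
# comparison runs when files named MZ014381*.fasta (query 16S) and
# n_nova_16s*.fasta are present.

suppressPackageStartupMessages(library(taxgenomics))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  message("no assembly directory given; nothing to do (see header comment)")
  quit(status = 0)
}
dir <- args[1]
find_one <- function(prefix) {
  f <- list.files(dir, pattern = paste0("^", prefix, ".*\\.(fa|fasta|fna)$"),
                  full.names = TRUE, ignore.case = TRUE)
  if (length(f) == 0) NULL else f[1]
}

qf <- if (length(args) >= 2) args[2] else find_one("JAGPOX")
if (is.null(qf)) stop("query assembly (JAGPOX*) not found in ", dir)
query <- read_genome_fasta(qf, genome_id = "N_alni_ncl2T")

refs <- c(BDCC = "N_vaccinii", BAGB = "N_jiangxiensis",
          BDBQ = "N_miyunensis", JAFQ = "N_casuarinae",
          QQBC = "N_pseudobrasiliensis")
assemblies <- list()
for (acc in names(refs)) {
  f <- find_one(acc)
  if (is.null(f)) { message("missing ", acc, "; skipped"); next }
  assemblies[[refs[[acc]]]] <- read_genome_fasta(f, genome_id = refs[[acc]])
}
if (length(assemblies) == 0) stop("no reference assemblies found in ", dir)

st <- assembly_stats(query)
cat(sprintf("query assembly: %.2f Mbp, G+C %.1f%% (published: 9.93 Mbp, 67.0%%)\n",
            st$size_bp / 1e6, st$gc_percent))

rep <- taxogenomic_report(query, assemblies)
print(rep)
published <- published_reference("ani_ddh")
outdir <- "results/reference_genomes"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
write.table(rep, file.path(outdir, "pairwise_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("published values for comparison (ANI within ~0.5, dDDH within ~2 expected):\n")
print(published)

q16 <- find_one("MZ014381")
n16 <- find_one("n_nova_16s")
if (!is.null(q16) && !is.null(n16)) {
  a <- as.character(Biostrings::readBStringSet(q16)[[1]])
  b <- as.character(Biostrings::readBStringSet(n16)[[1]])
  ms <- pairwise_global_identity(a, b)
  cat(sprintf("16S vs N. nova: %.1f%% (%d differences); published 98.6%% / 20\n",
              ms$similarity_percent, ms$n_differences))
}
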