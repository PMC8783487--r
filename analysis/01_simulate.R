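#!/usr/bin/env Rscript
# Generates the synthetic datasets used throughout the analysis: genome
# pairs at graded divergence (substitution-only, so expected ANI is
# closed-form), a 4-genome pan-genome with known ortholog families, and a
# 16S-like marker pair with exactly 20 planted differences. Writes FASTA
# and ground-truth tables under results/simulated/.

suppressPackageStartupMessages(library(taxgenomics))
outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# genome pairs: 200 kb, p in {1%, 5%, 10%} (the 5% pair sits near the ANI
# species boundary; 1% is well inside it)
for (p in c(0.01, 0.05, 0.10)) {
  sp <- simulate_genome_pair(200000, gc = 0.5, p = p, seed = 1000 + 100 * p * 100)
  tag <- sprintf("pair_p%02d", round(100 * p))
  write_genome_fasta(sp$a, file.path(outdir, paste0(tag, "_a.fasta")))
  write_genome_fasta(sp$b, file.path(outdir, paste0(tag, "_b.fasta")))
  cat(sprintf("%s: expected ANI %.1f%%, %d substitutions realized\n",
              tag, sp$expected_ani_percent, sp$n_substitutions))
}

# pan-genome: 4 genomes, 50 core families, 5 private genes each, p = 0.05
sim <- simulate_pangenome(n_genomes = 4, n_core_families = 50,
                          n_private_per_genome = 5, p = 0.05, seed = 7)
for (asm in sim$assemblies)
  write_genome_fasta(asm, file.path(outdir, paste0(asm$genome_id, ".fasta")))
write.table(sim$genes[, c("gene_id", "genome_id", "contig_id", "start",
                          "end", "strand", "type", "product")],
            file.path(outdir, "pangenome_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$families, file.path(outdir, "truth_families.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$private, file.path(outdir, "truth_private.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("pan-genome: %d genes over 4 genomes (%d families + private)\n",
            nrow(sim$genes), length(unique(sim$truth$families$family_id))))

# marker pair: 1523 bp with exactly 20 differences (the published 16S
# calibration point: 20 differences over ~1.5 kb is a 98.7% similarity)
mp <- simulate_marker_pair(1523, 20, seed = 11)
writeLines(c(">marker_a", mp$a, ">marker_b", mp$b),
           file.path(outdir, "marker_pair.fasta"))
cat(sprintf("marker pair: %d differences, exact similarity %.2f%%\n",
            mp$n_differences, mp$exact_similarity))
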