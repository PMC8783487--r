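IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Construct a genome assembly
#'
#' A genome assembly is a named, ordered set of contig sequences with a
#' provenance label. Sequences are uppercased and restricted to IUPAC
#' nucleotide codes; contig ids must be unique and sequences non-empty.
#'
#' @param genome_id label for the genome.
#' @param contigs named character vector of nucleotide sequences.
#' @param source free-text provenance (file path, simulator call, ...).
#' @return an object of class `genome_assembly`.
#' @export
genome_assembly <- function(genome_id, contigs, source = "") {
  if (length(contigs) == 0) stop("no sequences")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("all contigs must be named")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig_id: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]),
               collapse = ", "))
  contigs <- toupper(contigs)
  if (any(!nzchar(contigs))) stop("empty contig sequence")
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_NT, collapse = "")), contigs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("non-IUPAC character '%s' in contig '%s' at position %d",
                 substr(contigs[i], bad[i], bad[i]), names(contigs)[i],
                 bad[i]))
  }
  structure(list(genome_id = genome_id, contigs = contigs, source = source),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d contig(s), %s bp\n", x$genome_id,
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Read a genome assembly from a FASTA file
#'
#' One contig per record; the contig id is the header token before the first
#' whitespace. Sequences are uppercased and validated against the IUPAC
#' nucleotide alphabet (an offending character is reported with its
#' position).
#'
#' @param path FASTA file.
#' @param genome_id genome label; defaults to the file name without
#'   extension.
#' @param source provenance string stored on the assembly.
#' @return a [genome_assembly()].
#' @export
read_genome_fasta <- function(path, genome_id = NULL, source = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences")
  ids <- sub("\\s.*$", "", names(set))
  contigs <- as.character(set)
  names(contigs) <- ids
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  genome_assembly(genome_id, contigs, source = source)
}

#' Write a genome assembly to FASTA
#'
#' @param g a [genome_assembly()].
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome_assembly"))
  set <- Biostrings::DNAStringSet(g$contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Basic assembly statistics
#'
#' Genome size, G+C content and contig count. G+C is computed over
#' unambiguous bases only: `100 * (G + C) / (A + C + G + T)`; `N` and other
#' ambiguity codes are excluded from the denominator, and the percentage is
#' reported to one decimal place.
#'
#' @param g a [genome_assembly()].
#' @return data frame with columns `genome_id`, `size_bp`, `gc_percent`,
#'   `n_contigs`.
#' @export
assembly_stats <- function(g) {
  stopifnot(inherits(g, "genome_assembly"))
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(g$contigs))
  tot <- colSums(freq)
  acgt <- tot[c("A", "C", "G", "T")]
  if (sum(acgt) == 0)
    stop("gc_percent undefined: assembly contains no unambiguous bases")
  data.frame(
    genome_id = g$genome_id,
    size_bp = sum(nchar(g$contigs)),
    gc_percent = round(100 * sum(acgt[c("G", "C")]) / sum(acgt), 1),
    n_contigs = length(g$contigs),
    stringsAsFactors = FALSE
  )
}

#' Read gene annotations for a genome
#'
#' Accepts GFF3 (features of type CDS, rRNA and tRNA; attributes `ID` and
#' `product`) or a delimited table with columns `gene_id`, `contig_id`,
#' `start`, `end`, `strand` and optional `product` and `type` columns.
#' Coordinates are 1-based inclusive. Every record is validated against the
#' assembly's contig bounds; the nucleotide sequence is extracted from the
#' assembly, reverse-complemented for minus-strand genes.
#'
#' @param path annotation file.
#' @param genome the [genome_assembly()] the annotation refers to.
#' @return data frame of gene records with columns `gene_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `strand`, `type`, `product`, `nt_seq`.
#' @export
read_annotation <- function(path, genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    grepl("^##gff-version", first)
  if (is_gff) {
    tab <- read_gff3_features(path)
  } else {
    tab <- read_annotation_table(path)
  }
  gene_records(tab, genome)
}

read_gff3_features <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% c("CDS", "rRNA", "tRNA")
    gr <- gr[keep]
    id <- gr$ID
    if (is.null(id)) id <- rep(NA_character_, length(gr))
    if (!is.null(gr$locus_tag)) id <- ifelse(is.na(id), gr$locus_tag, id)
    if (anyNA(id)) id[is.na(id)] <- sprintf("feature_%d", which(is.na(id)))
    prod <- if (is.null(gr$product)) rep("", length(gr)) else
      ifelse(is.na(gr$product), "", gr$product)
    data.frame(gene_id = id,
               contig_id = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               type = as.character(gr$type),
               product = prod, stringsAsFactors = FALSE)
  } else {
    # minimal column reader, used only when rtracklayer is unavailable
    raw <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    raw <- raw[raw[[3]] %in% c("CDS", "rRNA", "tRNA"), ]
    attr_field <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))
      vapply(m, function(z) if (length(z) >= 3) z[3] else "", "")
    }
    id <- attr_field(raw[[9]], "ID")
    id[!nzchar(id)] <- sprintf("feature_%d", which(!nzchar(id)))
    data.frame(gene_id = id, contig_id = raw[[1]], start = raw[[4]],
               end = raw[[5]], strand = raw[[7]], type = raw[[3]],
               product = attr_field(raw[[9]], "product"),
               stringsAsFactors = FALSE)
  }
}

read_annotation_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first)
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    nm <- c("gene_id", "contig_id", "start", "end", "strand", "product",
            "type")
    names(tab) <- nm[seq_len(ncol(tab))]
  }
  if (is.null(tab$product)) tab$product <- ""
  if (is.null(tab$type)) tab$type <- "CDS"
  tab[c("gene_id", "contig_id", "start", "end", "strand", "type", "product")]
}

# validate coordinates against the assembly and extract strand-oriented
# nucleotide sequences
gene_records <- function(tab, genome) {
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  unknown <- !(tab$contig_id %in% names(genome$contigs))
  if (any(unknown))
    stop(sprintf("unknown contig_id '%s' for gene '%s'",
                 tab$contig_id[unknown][1], tab$gene_id[unknown][1]))
  clen <- nchar(genome$contigs)[tab$contig_id]
  bad <- tab$start < 1 | tab$end < tab$start | tab$end > clen
  if (any(bad))
    stop(sprintf("coordinates outside contig for gene '%s' (%d..%d on '%s', contig length %d)",
                 tab$gene_id[bad][1], tab$start[bad][1], tab$end[bad][1],
                 tab$contig_id[bad][1], clen[bad][1]))
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  nt <- substr(genome$contigs[tab$contig_id], tab$start, tab$end)
  minus <- tab$strand == "-"
  if (any(minus)) nt[minus] <- cpp_revcomp(nt[minus])
  out <- data.frame(gene_id = tab$gene_id, genome_id = genome$genome_id,
                    contig_id = tab$contig_id, start = tab$start,
                    end = tab$end, strand = tab$strand, type = tab$type,
                    product = tab$product, nt_seq = unname(nt),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Translate a coding sequence (bacterial code, table 11)
#'
#' The terminal stop codon, when present, is removed. An internal stop is an
#' error under the default strict policy; `internal_stop = "x"` maps it to
#' `X` instead. Codons containing ambiguity codes translate to `X`.
#'
#' @param nt_seq nucleotide sequence whose length is divisible by 3.
#' @param internal_stop `"error"` (default) or `"x"`.
#' @return amino-acid sequence (character scalar).
#' @export
translate_cds <- function(nt_seq, internal_stop = c("error", "x")) {
  internal_stop <- match.arg(internal_stop)
  n <- nchar(nt_seq)
  if (n == 0) stop("empty sequence")
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  code <- Biostrings::getGeneticCode("11")
  codons <- substring(toupper(nt_seq), seq(1, n, 3), seq(3, n, 3))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  k <- length(aa)
  if (aa[k] == "*") aa <- aa[-k]
  if (any(aa == "*")) {
    if (internal_stop == "error")
      stop(sprintf("internal stop at codon %d", which(aa == "*")[1]))
    aa[aa == "*"] <- "X"
  }
  paste(aa, collapse = "")
}

#' Add amino-acid sequences to gene records
#'
#' Translates the `nt_seq` of every CDS record (bacterial code, table 11)
#' into an `aa_seq` column. Non-CDS records get `NA`.
#'
#' @param records gene records from [read_annotation()].
#' @param internal_stop policy passed to [translate_cds()].
#' @return `records` with an `aa_seq` column.
#' @export
translate_genes <- function(records, internal_stop = c("error", "x")) {
  internal_stop <- match.arg(internal_stop)
  aa <- rep(NA_character_, nrow(records))
  cds <- which(records$type == "CDS")
  for (i in cds) {
    aa[i] <- tryCatch(
      translate_cds(records$nt_seq[i], internal_stop),
      error = function(e) stop(sprintf("gene '%s': %s", records$gene_id[i],
                                       conditionMessage(e)), call. = FALSE))
  }
  records$aa_seq <- aa
  records
}

#' Write assembly statistics for several genomes as TSV
#'
#' @param stats data frame as returned by [assembly_stats()] (rows may be
#'   bound together).
#' @param path output file.
#' @export
write_assembly_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
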