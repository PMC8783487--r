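# End-to-end relatedness report: the per-pair summary a taxonomist reads
# off when placing an isolate against reference type strains.

#' Genome relatedness report for a query against reference assemblies
#'
#' Runs the full genome-relatedness workflow of the package for one query
#' assembly against each reference: fragment-based ANI, dDDH distance and
#' mapped percentage, and the species-boundary call (ANI >= 95 or
#' dDDH >= 70 implies "same"). This is the function behind the integration
#' driver that reproduces published pairwise values when the corresponding
#' reference assemblies are supplied.
#'
#' @param query a [genome_assembly()].
#' @param references list of [genome_assembly()] objects.
#' @param ani_cfg,ddh_cfg configurations.
#' @return data frame: `reference`, `ani_percent`, `n_reciprocal_pairs`,
#'   `d2`, `ddh_percent`, `classification`.
#' @export
taxogenomic_report <- function(query, references, ani_cfg = ani_config(),
                               ddh_cfg = ddh_config()) {
  stopifnot(inherits(query, "genome_assembly"))
  rows <- lapply(references, function(ref) {
    a <- orthoani(query, ref, ani_cfg)
    d <- ddh_distance(query, ref, ddh_cfg)
    data.frame(reference = ref$genome_id,
               ani_percent = a$ani_percent,
               n_reciprocal_pairs = a$n_reciprocal_pairs,
               d2 = d$d2, ddh_percent = d$ddh_percent,
               classification = classify_species(a$ani_percent,
                                                 d$ddh_percent),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
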