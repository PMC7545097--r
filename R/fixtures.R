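#' Paths to the shipped cross-link identification fixtures
#'
#' Six compact-notation TSV tables transcribing the published summary
#' tables of identified cross-linked peptides: the PREP1-PBX1
#' inter/intra/looped peptide sets and the MEIS1-PBX1
#' inter/intra/looped sets.
#'
#' @param name one of `"prep1_pbx1_inter"`, `"prep1_pbx1_intra"`,
#'   `"prep1_pbx1_loop"`, `"meis1_pbx1_inter"`, `"meis1_pbx1_intra"`,
#'   `"meis1_pbx1_loop"`; omit for all six.
#' @return named character vector of file paths.
#' @export
tale_fixture <- function(name = NULL) {
  all <- c("prep1_pbx1_inter", "prep1_pbx1_intra", "prep1_pbx1_loop",
           "meis1_pbx1_inter", "meis1_pbx1_intra", "meis1_pbx1_loop")
  if (is.null(name)) name <- all
  bad <- setdiff(name, all)
  if (length(bad)) stop("unknown fixture: ", paste(bad, collapse = ", "))
  paths <- vapply(name, function(n) {
    system.file("extdata", paste0(n, ".tsv"), package = "talemap",
                mustWork = TRUE)
  }, "")
  paths
}

# residues named individually in the helix descriptions, used to enrich
# the reconstructed scaffolds beyond the peptide placements
heptad_residue_constraints <- function() {
  list(
    PREP1 = c("63" = "L", "64" = "F", "66" = "L", "67" = "L", "69" = "L",
              "70" = "L", "71" = "F", "117" = "L", "122" = "I",
              "124" = "V", "125" = "L", "129" = "L", "130" = "L"),
    PBX1 = c("43" = "I", "45" = "D", "46" = "L", "47" = "L", "48" = "Q",
             "49" = "Q", "50" = "I", "52" = "T", "53" = "I", "55" = "D",
             "56" = "Q", "80" = "V", "89" = "V", "90" = "L", "105" = "L",
             "108" = "L", "112" = "L", "201" = "V", "204" = "I",
             "211" = "I"))
}

TALE_FULL_LENGTHS <- c(PBX1 = 430L, PREP1 = 436L, MEIS1 = 390L)

#' Scaffold protein records for PBX1, PREP1 and MEIS1
#'
#' Reconstructs synthetic scaffold sequences for the three proteins from
#' the peptide placements implied by the shipped fixtures (plus the
#' individually named heptad residues), padded with filler to the
#' full-length protein sizes, and annotates them with the
#' [default_domain_tables()]. These scaffolds carry every residue the
#' published tables constrain and filler (`G`) elsewhere -- sufficient
#' for residue mapping, heptad annotation over the constrained intervals
#' and diagram layout, but *not* native sequences.
#'
#' @return named list of annotated [protein_record()]s.
#' @export
tale_scaffold_proteins <- function() {
  ids <- do.call(rbind, lapply(unname(tale_fixture()), parse_compact_table))
  class(ids) <- c("xlink_ids", "data.frame")
  prots <- build_scaffold(ids, lengths = TALE_FULL_LENGTHS,
                          extra = heptad_residue_constraints())
  doms <- default_domain_tables()
  for (pn in names(prots)) {
    if (pn %in% names(doms)) prots[[pn]] <- annotate_domains(prots[[pn]],
                                                             doms[[pn]])
  }
  prots[order(names(prots))]
}

#' Run the residue-mapping pipeline over identification tables
#'
#' Convenience wrapper chaining [map_to_residues()], [classify_links()],
#' [collapse_redundant()] and [aggregate_replicates()].
#'
#' @param ids an [xlink_ids()] table (e.g. from [parse_compact_table()]
#'   or [parse_plink_table()], possibly several `rbind`-ed).
#' @param proteins named list of [protein_record()]s.
#' @return an `xlink_links` table with `both_replicates`.
#' @export
map_and_collapse <- function(ids, proteins) {
  ids <- map_to_residues(ids, proteins)
  ids <- classify_links(ids)
  aggregate_replicates(collapse_redundant(ids))
}
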