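longest_run <- function(ordinals) {
  if (!length(ordinals)) return(0L)
  v <- sort(unique(as.integer(ordinals)))
  if (length(v) == 1L) return(1L)
  runs <- rle(diff(v) == 1L)
  hits <- runs$lengths[runs$values]
  if (length(hits)) max(hits) + 1L else 1L
}

peptide_passes_ions <- function(ions_b, ions_y, min_consecutive) {
  longest_run(parse_ion_list(ions_b)) >= min_consecutive ||
    longest_run(parse_ion_list(ions_y)) >= min_consecutive
}

#' Curate peptide identifications
#'
#' Applies the manual-curation rules used on the search output: a record
#' is kept iff its E-value is strictly below `evalue_max`, each
#' cross-linked peptide shows at least `min_consecutive` consecutive
#' fragment ordinals in its b series or in its y series (the two series
#' are considered independently, not mixed), the fraction of assigned
#' spectrum peaks strictly exceeds `majority_fraction`, and every linked
#' position falls on a lysine (the N-terminal alpha-amine is accepted at
#' position 1 when `allow_nterm = TRUE`; BS3 chemistry permits it, but
#' only K-K links are reported by default). Records lacking ion
#' annotations are dropped unless `permissive = TRUE`, in which case they
#' are kept and marked `"uncurated"`.
#'
#' @param ids an [xlink_ids()] table.
#' @param evalue_max E-value threshold (strict `<`).
#' @param min_consecutive minimum consecutive b- or y-ion run per peptide.
#' @param majority_fraction assigned/total peak fraction (strict `>`).
#' @param allow_nterm accept a link at peptide position 1 on a non-K
#'   residue (protein N-terminus chemistry).
#' @param permissive keep records without ion annotations, flagged.
#' @return list with `kept` (an `xlink_ids` table, plus a `curation`
#'   column equal to `"pass"` or `"uncurated"`) and `rejected` (the
#'   discarded rows with a `reason` column; the first failed rule among
#'   evalue, consecutive-ions, majority-assigned, site-not-lysine).
#' @export
curate_identifications <- function(ids, evalue_max = 0.001,
                                   min_consecutive = 4L,
                                   majority_fraction = 0.5,
                                   allow_nterm = FALSE,
                                   permissive = FALSE) {
  validate_ids(ids)
  n <- nrow(ids)
  reason <- rep(NA_character_, n)
  curation <- rep("pass", n)
  for (i in seq_len(n)) {
    loop <- is.na(ids$peptide_b[i])
    # lysine rule first: it is a structural constraint on the record
    site_ok <- function(pep, pos) {
      aa <- substring(pep, pos, pos)
      aa == "K" || (allow_nterm && pos == 1L)
    }
    sites <- if (loop) {
      site_ok(ids$peptide_a[i], ids$pos_a[i]) &&
        site_ok(ids$peptide_a[i], ids$pos_b[i])
    } else {
      site_ok(ids$peptide_a[i], ids$pos_a[i]) &&
        site_ok(ids$peptide_b[i], ids$pos_b[i])
    }
    if (!sites) { reason[i] <- "site-not-lysine"; next }
    if (is.na(ids$evalue[i]) || ids$evalue[i] >= evalue_max) {
      reason[i] <- "evalue"; next
    }
    has_ions_a <- !is.na(ids$ions_b_a[i]) || !is.na(ids$ions_y_a[i])
    has_ions_b <- loop || !is.na(ids$ions_b_b[i]) || !is.na(ids$ions_y_b[i])
    if (!has_ions_a || !has_ions_b) {
      if (permissive) { curation[i] <- "uncurated"; next }
      reason[i] <- "no-ion-annotation"; next
    }
    ok_a <- peptide_passes_ions(ids$ions_b_a[i], ids$ions_y_a[i],
                                min_consecutive)
    ok_b <- loop || peptide_passes_ions(ids$ions_b_b[i], ids$ions_y_b[i],
                                        min_consecutive)
    if (!ok_a || !ok_b) { reason[i] <- "consecutive-ions"; next }
    if (is.na(ids$n_peaks_total[i]) || is.na(ids$n_peaks_assigned[i]) ||
        ids$n_peaks_assigned[i] / ids$n_peaks_total[i] <= majority_fraction) {
      reason[i] <- "majority-assigned"; next
    }
  }
  keep <- is.na(reason)
  kept <- ids[keep, , drop = FALSE]
  kept$curation <- curation[keep]
  rejected <- ids[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

locate_peptide <- function(peptide, protein, claimed_residue, pos) {
  hits <- gregexpr(peptide, protein$sequence, fixed = TRUE)[[1]]
  hits <- hits[hits > 0L]
  if (!length(hits)) {
    stop("peptide '", peptide, "' not found in protein '",
         protein$name, "'")
  }
  if (length(hits) == 1L) return(hits)
  if (is.na(claimed_residue)) {
    stop("peptide '", peptide, "' occurs at ", length(hits),
         " offsets in '", protein$name,
         "' and no claimed residue is available to disambiguate")
  }
  want <- claimed_residue - pos + 1L
  if (!want %in% hits) {
    stop("claimed residue ", claimed_residue, " incompatible with any ",
         "occurrence of '", peptide, "' in '", protein$name, "'")
  }
  want
}

#' Map in-peptide link positions to absolute residues
#'
#' Locates each peptide in its assigned protein sequence and converts the
#' in-peptide link position to the absolute 1-based residue
#' (`peptide_start + pos - 1`). When the table already carries a claimed
#' absolute residue the computed value must agree; when a peptide occurs
#' at several offsets the claimed residue resolves the ambiguity.
#'
#' @param ids an [xlink_ids()] table.
#' @param proteins named list of [protein_record()]s covering every
#'   protein referenced by `ids`.
#' @return `ids` with `residue_a`/`residue_b` filled and verified, plus
#'   `start_a`/`start_b` peptide offsets.
#' @export
map_to_residues <- function(ids, proteins) {
  validate_ids(ids)
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    names(proteins) <- vapply(proteins, `[[`, "", "name")
  }
  n <- nrow(ids)
  start_a <- start_b <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    loop <- is.na(ids$peptide_b[i])
    pa <- ids$protein_a[i]
    if (!pa %in% names(proteins)) stop("unknown protein '", pa, "'")
    sa <- locate_peptide(ids$peptide_a[i], proteins[[pa]],
                         ids$residue_a[i], ids$pos_a[i])
    ra <- sa + ids$pos_a[i] - 1L
    if (!is.na(ids$residue_a[i]) && ids$residue_a[i] != ra) {
      stop("row ", i, ": claimed residue_a ", ids$residue_a[i],
           " != computed ", ra)
    }
    ids$residue_a[i] <- ra
    start_a[i] <- sa
    if (loop) {
      rb <- sa + ids$pos_b[i] - 1L
      if (!is.na(ids$residue_b[i]) && ids$residue_b[i] != rb) {
        stop("row ", i, ": claimed residue_b ", ids$residue_b[i],
             " != computed ", rb)
      }
      ids$residue_b[i] <- rb
      ids$protein_b[i] <- pa
      start_b[i] <- sa
    } else {
      pb <- ids$protein_b[i]
      if (!pb %in% names(proteins)) stop("unknown protein '", pb, "'")
      sb <- locate_peptide(ids$peptide_b[i], proteins[[pb]],
                           ids$residue_b[i], ids$pos_b[i])
      rb <- sb + ids$pos_b[i] - 1L
      if (!is.na(ids$residue_b[i]) && ids$residue_b[i] != rb) {
        stop("row ", i, ": claimed residue_b ", ids$residue_b[i],
             " != computed ", rb)
      }
      ids$residue_b[i] <- rb
      start_b[i] <- sb
    }
  }
  ids$start_a <- start_a
  ids$start_b <- start_b
  ids
}

#' Audit peptide offsets implied by claimed residues
#'
#' Every record implies a peptide start (`residue - pos + 1`); all
#' records sharing a (protein, peptide) pair must imply the same start.
#' Report-only: contradictions are listed, not raised.
#'
#' @param ids an [xlink_ids()] table with claimed residues.
#' @return list with `offsets` (data.frame `protein`, `peptide`, `start`,
#'   `n_records`) and `contradictions` (data.frame of offending protein,
#'   peptide and the distinct implied starts, zero rows when consistent).
#' @export
infer_peptide_offsets <- function(ids) {
  validate_ids(ids)
  obs <- list()
  add <- function(protein, peptide, residue, pos) {
    if (is.na(residue) || is.na(pos)) return()
    obs[[length(obs) + 1L]] <<- data.frame(
      protein = protein, peptide = peptide,
      start = as.integer(residue - pos + 1L), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ids))) {
    loop <- is.na(ids$peptide_b[i])
    add(ids$protein_a[i], ids$peptide_a[i], ids$residue_a[i], ids$pos_a[i])
    if (loop) {
      add(ids$protein_a[i], ids$peptide_a[i], ids$residue_b[i], ids$pos_b[i])
    } else {
      add(ids$protein_b[i], ids$peptide_b[i], ids$residue_b[i], ids$pos_b[i])
    }
  }
  if (!length(obs)) {
    return(list(offsets = data.frame(protein = character(0),
                                     peptide = character(0),
                                     start = integer(0),
                                     n_records = integer(0)),
                contradictions = data.frame(protein = character(0),
                                            peptide = character(0),
                                            starts = character(0))))
  }
  all_obs <- do.call(rbind, obs)
  key <- paste(all_obs$protein, all_obs$peptide, sep = "\r")
  split_starts <- split(all_obs$start, key)
  uk <- strsplit(names(split_starts), "\r", fixed = TRUE)
  offsets <- data.frame(
    protein = vapply(uk, `[`, "", 1L),
    peptide = vapply(uk, `[`, "", 2L),
    start = vapply(split_starts, function(s) s[1], 0L),
    n_records = lengths(split_starts),
    stringsAsFactors = FALSE)
  bad <- vapply(split_starts, function(s) length(unique(s)) > 1L, NA)
  contradictions <- data.frame(
    protein = offsets$protein[bad],
    peptide = offsets$peptide[bad],
    starts = vapply(split_starts[bad], function(s)
      paste(sort(unique(s)), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  offsets$start[bad] <- NA_integer_
  rownames(offsets) <- rownames(contradictions) <- NULL
  list(offsets = offsets, contradictions = contradictions)
}

#' Reconstruct scaffold sequences from peptide placements
#'
#' Builds, for each protein referenced by an identification table, a
#' synthetic scaffold sequence in which every peptide is written at the
#' offset implied by its claimed residues and every unconstrained
#' position carries the filler residue. The result is *not* the native
#' sequence -- it is the minimal sequence consistent with the printed
#' peptide placements, sufficient for residue mapping and diagram layout.
#' Conflicting placements (two peptides claiming different residues at
#' one position) raise an error.
#'
#' @param ids an [xlink_ids()] table with claimed residues.
#' @param lengths optional named integer vector of full protein lengths;
#'   defaults to the largest placed peptide end per protein.
#' @param fill single filler residue (default `"G"`).
#' @param extra optional named list (per protein) of named character
#'   vectors giving additional known residues, e.g. `c("63" = "L")`.
#' @return named list of [protein_record()]s.
#' @export
build_scaffold <- function(ids, lengths = NULL, fill = "G", extra = NULL) {
  validate_ids(ids)
  place <- new.env(parent = emptyenv())
  put <- function(protein, peptide, start) {
    if (is.na(start)) return()
    cur <- if (!is.null(place[[protein]])) place[[protein]] else character(0)
    chars <- strsplit(peptide, "")[[1]]
    idx <- start + seq_along(chars) - 1L
    if (any(idx < 1L)) stop("peptide '", peptide, "' implies start < 1")
    old <- cur[as.character(idx)]
    clash <- !is.na(old) & old != chars
    if (any(clash)) {
      stop("conflicting placement in '", protein, "' at residue ",
           idx[clash][1], ": '", old[clash][1], "' vs '",
           chars[clash][1], "' (peptide ", peptide, ")")
    }
    cur[as.character(idx)] <- chars
    place[[protein]] <- cur
  }
  for (i in seq_len(nrow(ids))) {
    loop <- is.na(ids$peptide_b[i])
    if (!is.na(ids$residue_a[i])) {
      put(ids$protein_a[i], ids$peptide_a[i],
          ids$residue_a[i] - ids$pos_a[i] + 1L)
    }
    if (!loop && !is.na(ids$residue_b[i])) {
      put(ids$protein_b[i], ids$peptide_b[i],
          ids$residue_b[i] - ids$pos_b[i] + 1L)
    }
  }
  for (pn in names(extra)) {
    for (ps in names(extra[[pn]])) put(pn, extra[[pn]][[ps]], as.integer(ps))
  }
  out <- list()
  for (pn in ls(place)) {
    known <- place[[pn]]
    idx <- as.integer(names(known))
    len <- max(idx)
    if (!is.null(lengths) && pn %in% names(lengths)) {
      len <- max(len, as.integer(lengths[[pn]]))
    }
    chars <- rep(fill, len)
    chars[idx] <- known
    out[[pn]] <- protein_record(pn, paste(chars, collapse = ""))
  }
  out
}

#' Classify cross-link records
#'
#' `loop` for single-peptide records, `inter` when the two proteins
#' differ, `intra` otherwise. The classes are exhaustive and mutually
#' exclusive.
#'
#' @param ids an [xlink_ids()] table (mapped or not).
#' @return `ids` with a `link_class` column.
#' @export
classify_links <- function(ids) {
  validate_ids(ids)
  loop <- is.na(ids$peptide_b)
  cls <- ifelse(loop, "loop",
                ifelse(ids$protein_a != ids$protein_b, "inter", "intra"))
  ids$link_class <- cls
  ids
}

canonical_pair <- function(protein_a, residue_a, protein_b, residue_b) {
  swap <- protein_a > protein_b |
    (protein_a == protein_b & residue_a > residue_b)
  list(protein_a = ifelse(swap, protein_b, protein_a),
       residue_a = ifelse(swap, residue_b, residue_a),
       protein_b = ifelse(swap, protein_a, protein_b),
       residue_b = ifelse(swap, residue_a, residue_b))
}

#' Collapse redundant identifications to unique residue-pair cross-links
#'
#' Records are unique by the canonically ordered
#' `(protein_a, residue_a, protein_b, residue_b, link_class)` key -- a
#' symmetric duplicate `(B, rb, A, ra)` collapses onto `(A, ra, B, rb)`,
#' and a loop link's two in-peptide positions are unordered. Evidence is
#' retained and the best (minimum) E-value reported.
#'
#' @param ids a classified [xlink_ids()] table (see [classify_links()])
#'   with absolute residues.
#' @return data.frame of class `xlink_links` with one row per unique
#'   link: canonical proteins/residues, `link_class`, `n_evidence`,
#'   `best_evalue`, `replicates` (sorted `;`-joined distinct labels) and
#'   an `evidence` list-column of the supporting record rows.
#' @export
collapse_redundant <- function(ids) {
  validate_ids(ids)
  if (!"link_class" %in% names(ids)) ids <- classify_links(ids)
  if (any(is.na(ids$residue_a) | is.na(ids$residue_b))) {
    stop("collapse_redundant requires absolute residues; run map_to_residues")
  }
  cp <- canonical_pair(ids$protein_a, ids$residue_a,
                       ifelse(is.na(ids$protein_b), ids$protein_a,
                              ids$protein_b),
                       ids$residue_b)
  key <- paste(cp$protein_a, cp$residue_a, cp$protein_b, cp$residue_b,
               ids$link_class, sep = "\r")
  groups <- split(seq_len(nrow(ids)), key)
  # deterministic order: by protein pair, then residues
  ord <- order(vapply(groups, function(g) key[g[1]], ""))
  groups <- groups[ord]
  rows <- lapply(groups, function(g) {
    reps <- sort(unique(ids$replicate[g][!is.na(ids$replicate[g])]))
    data.frame(protein_a = cp$protein_a[g[1]], residue_a = cp$residue_a[g[1]],
               protein_b = cp$protein_b[g[1]], residue_b = cp$residue_b[g[1]],
               link_class = ids$link_class[g[1]],
               n_evidence = length(g),
               best_evalue = if (all(is.na(ids$evalue[g]))) NA_real_
                             else min(ids$evalue[g], na.rm = TRUE),
               replicates = paste(reps, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (length(rows)) {
    links <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    links$evidence <- lapply(groups, function(g) ids[g, , drop = FALSE])
  } else {
    links <- data.frame(protein_a = character(0), residue_a = integer(0),
                        protein_b = character(0), residue_b = integer(0),
                        link_class = character(0), n_evidence = integer(0),
                        best_evalue = numeric(0), replicates = character(0),
                        stringsAsFactors = FALSE)
    links$evidence <- list()
  }
  class(links) <- c("xlink_links", "data.frame")
  links
}

#' Flag links supported by both biological replicates
#'
#' Adds `both_replicates = TRUE` when a link's evidence spans at least
#' two distinct replicate labels (drawn in bold on the linear maps).
#' Monotone: adding evidence can only set the flag, never unset it.
#'
#' @param links an `xlink_links` table from [collapse_redundant()].
#' @return `links` with a logical `both_replicates` column.
#' @export
aggregate_replicates <- function(links) {
  stopifnot(inherits(links, "xlink_links"))
  n_reps <- vapply(strsplit(links$replicates, ";", fixed = TRUE),
                   function(r) length(r[nzchar(r)]), 0L)
  links$both_replicates <- n_reps >= 2L
  links
}
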