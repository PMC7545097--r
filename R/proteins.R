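AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Protein record with 1-based residue numbering
#'
#' A `protein_record` holds a named amino-acid sequence, its lysine
#' inventory and (optionally) a table of domain annotations. All residue
#' coordinates throughout the package are 1-based and intervals are
#' inclusive, matching the K87/K153-style numbering used for cross-link
#' sites.
#'
#' @param name protein identifier (non-empty string).
#' @param sequence amino-acid sequence using the 20 standard one-letter
#'   codes. With `permissive = TRUE`, `X` is additionally tolerated.
#' @param domains optional data.frame of domain annotations as produced by
#'   [domain_table()].
#' @param permissive allow `X` in the sequence.
#' @return an object of class `protein_record` with elements `name`,
#'   `sequence`, `length`, `lysines` (1-based positions of K) and
#'   `domains`.
#' @examples
#' p <- protein_record("P", "MKAE")
#' p$lysines  # 2
#' @export
protein_record <- function(name, sequence, domains = NULL, permissive = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("protein '", name, "': empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  allowed <- if (permissive) c(AA_STANDARD, "X") else AA_STANDARD
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    stop("protein '", name, "': non-standard residue '", chars[bad[1]],
         "' at position ", bad[1])
  }
  rec <- structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         lysines = which(chars == "K"), domains = NULL),
    class = "protein_record")
  if (!is.null(domains)) rec <- annotate_domains(rec, domains)
  rec
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$name, ": ", x$length, " aa, ",
      length(x$lysines), " lysines", sep = "")
  if (!is.null(x$domains)) cat(", ", nrow(x$domains), " domains", sep = "")
  cat("\n")
  invisible(x)
}

residue_at <- function(protein, pos) {
  stopifnot(inherits(protein, "protein_record"))
  if (any(pos < 1L | pos > protein$length)) {
    stop("residue position out of range for '", protein$name, "'")
  }
  substring(protein$sequence, pos, pos)
}

#' Read protein records from a FASTA file
#'
#' @param path FASTA file.
#' @param permissive tolerate `X` residues.
#' @return named list of [protein_record()] objects, one per entry, in
#'   file order. Duplicate names are rejected.
#' @export
load_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) return(list())
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA entry name: ", nm[duplicated(nm)][1])
  }
  recs <- lapply(seq_along(set), function(i) {
    protein_record(nm[i], as.character(set[[i]]), permissive = permissive)
  })
  names(recs) <- nm
  recs
}

#' Domain annotation tables
#'
#' Builds the data.frame used to annotate [protein_record()] objects with
#' named regions (HR1/HR2/HR3 for the PREP/MEIS side, PBC-A/PBC-B and the
#' homeodomain for PBX1, or any custom label).
#'
#' @param label character vector of domain labels (unique per protein).
#' @param start,end 1-based inclusive residue bounds, `start <= end`.
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
domain_table <- function(label, start, end) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("domain with start > end")
  if (any(start < 1L)) stop("domain start below 1")
  if (anyDuplicated(label)) stop("duplicate domain label: ",
                                 label[duplicated(label)][1])
  data.frame(label = as.character(label), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Attach domain annotations to a protein
#'
#' @param protein a [protein_record()].
#' @param table a [domain_table()] (or equivalent data.frame).
#' @return the protein with `$domains` set; use [domain_lookup()] to map
#'   residues to domain labels.
#' @export
annotate_domains <- function(protein, table) {
  stopifnot(inherits(protein, "protein_record"))
  table <- domain_table(table$label, table$start, table$end)
  if (any(table$end > protein$length)) {
    bad <- table$label[table$end > protein$length][1]
    stop("domain '", bad, "' extends beyond '", protein$name,
         "' (length ", protein$length, ")")
  }
  protein$domains <- table
  protein
}

#' Map residues to domain labels
#'
#' Residues outside every annotated domain map to `"linker"`. When
#' domains overlap, the first matching row of the annotation table wins.
#'
#' @param protein an annotated [protein_record()].
#' @param pos vector of 1-based residue positions.
#' @return character vector of domain labels.
#' @export
domain_lookup <- function(protein, pos) {
  stopifnot(inherits(protein, "protein_record"))
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > protein$length)) {
    stop("residue position out of range (1-based) for '", protein$name, "'")
  }
  out <- rep("linker", length(pos))
  dom <- protein$domains
  if (is.null(dom) || nrow(dom) == 0L) return(out)
  for (i in rev(seq_len(nrow(dom)))) {
    hit <- pos >= dom$start[i] & pos <= dom$end[i]
    out[hit] <- dom$label[i]
  }
  out
}

#' Default domain annotations for PBX1, PREP1 and MEIS1
#'
#' Approximate boundaries assembled from the regions discussed with the
#' cross-link maps: the PREP1/MEIS1 homology regions HR1 and HR2 (plus the
#' leucine-rich "HR3" stretch specific to the PREP subfamily), the PBX1
#' PBC-A/PBC-B hydrophobic stretches and the homeodomains. Boundaries of
#' the helical stretches are taken from the heptad intervals
#' (PREP1 HR1 63-73, HR2 117-132, HR3 242-252; PBX1 stretches 43-55,
#' 77-90, 105-113, 197-211); the enclosing PBC-A/PBC-B/homeodomain blocks
#' are conventional and flagged approximate.
#'
#' @return named list of [domain_table()] data.frames for `PBX1`, `PREP1`
#'   and `MEIS1`, each carrying an `approximate` attribute set to `TRUE`.
#' @export
default_domain_tables <- function() {
  out <- list(
    PBX1 = domain_table(
      c("PBC-A", "PBC-B", "homeodomain"),
      c(38, 137, 233),
      c(127, 232, 292)),
    PREP1 = domain_table(
      c("HR1", "HR2", "HR3", "homeodomain"),
      c(63, 117, 242, 258),
      c(73, 132, 252, 320)),
    MEIS1 = domain_table(
      c("HR1", "HR2", "homeodomain"),
      c(87, 159, 272),
      c(97, 195, 334)))
  for (i in seq_along(out)) attr(out[[i]], "approximate") <- TRUE
  out
}

HEPTAD_LETTERS <- letters[1:7]

#' Assign a heptad-repeat register to a helical interval
#'
#' Coiled-coil style heptad positions a..g cycle with period 7 starting
#' from a residue of known phase; hydrophobic residues at positions a and
#' d form the interaction face of an amphipathic helix.
#'
#' @param protein a [protein_record()].
#' @param start first residue of the interval (1-based).
#' @param phase heptad letter (`"a"`..`"g"`) assigned to `start`.
#' @param end last residue of the interval, `>= start`.
#' @return object of class `heptad_assignment`: list with `start`, `end`,
#'   `phase` and `registers`, a named character vector mapping each
#'   residue (names) of `[start, end]` to its heptad letter.
#' @examples
#' p <- protein_record("H", strrep("A", 80))
#' h <- assign_heptad(p, 63, "a", 73)
#' h$registers[c("63", "66", "70", "73")]  # a d a d
#' @export
assign_heptad <- function(protein, start, phase = "a", end) {
  stopifnot(inherits(protein, "protein_record"))
  start <- as.integer(start); end <- as.integer(end)
  if (!phase %in% HEPTAD_LETTERS) stop("phase must be one of a..g")
  if (start > end) stop("start must be <= end")
  if (start < 1L || end > protein$length) {
    stop("heptad interval [", start, ", ", end, "] outside '",
         protein$name, "' (length ", protein$length, ")")
  }
  pos <- start:end
  idx <- (match(phase, HEPTAD_LETTERS) - 1L + (pos - start)) %% 7L
  registers <- HEPTAD_LETTERS[idx + 1L]
  names(registers) <- pos
  structure(list(protein = protein$name, start = start, end = end,
                 phase = phase, registers = registers),
            class = "heptad_assignment")
}

#' @export
print.heptad_assignment <- function(x, ...) {
  cat("<heptad_assignment> ", x$protein, " ", x$start, "-", x$end,
      " (", x$phase, " at ", x$start, ")\n", sep = "")
  invisible(x)
}

#' Residues occupying selected heptad positions
#'
#' Reports, in ascending residue order, the residues of a heptad interval
#' that sit on the requested register letters -- by default the a/d
#' hydrophobic face.
#'
#' @param assignment a [assign_heptad()] result.
#' @param protein the [protein_record()] the assignment refers to.
#' @param letters subset of `"a"`..`"g"` to report.
#' @return data.frame with columns `residue`, `aa`, `letter`.
#' @export
hydrophobic_face <- function(assignment, protein, letters = c("a", "d")) {
  stopifnot(inherits(assignment, "heptad_assignment"),
            inherits(protein, "protein_record"))
  if (!all(letters %in% HEPTAD_LETTERS)) stop("letters must be within a..g")
  if (assignment$end > protein$length) {
    stop("assignment does not fit protein '", protein$name, "'")
  }
  keep <- assignment$registers %in% letters
  pos <- as.integer(names(assignment$registers))[keep]
  data.frame(residue = pos,
             aa = if (length(pos)) residue_at(protein, pos) else character(0),
             letter = unname(assignment$registers[keep]),
             stringsAsFactors = FALSE)
}
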