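ID_COLUMNS <- c("peptide_a", "pos_a", "peptide_b", "pos_b",
                "protein_a", "protein_b", "residue_a", "residue_b",
                "evalue", "replicate",
                "ions_b_a", "ions_y_a", "ions_b_b", "ions_y_b",
                "n_peaks_total", "n_peaks_assigned")

empty_ids <- function() {
  df <- data.frame(peptide_a = character(0), pos_a = integer(0),
                   peptide_b = character(0), pos_b = integer(0),
                   protein_a = character(0), protein_b = character(0),
                   residue_a = integer(0), residue_b = integer(0),
                   evalue = numeric(0), replicate = character(0),
                   ions_b_a = character(0), ions_y_a = character(0),
                   ions_b_b = character(0), ions_y_b = character(0),
                   n_peaks_total = integer(0), n_peaks_assigned = integer(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("xlink_ids", "data.frame")
  df
}

#' Assemble a peptide-identification table
#'
#' One row per search-engine record. A cross-linked peptide pair carries
#' two peptides with one in-peptide link position each; a looped peptide
#' (both cross-linked residues within a single peptide) is encoded with
#' `peptide_b = NA` and the two in-peptide positions in `pos_a`/`pos_b`.
#' `residue_a`/`residue_b` are the claimed absolute 1-based residues as
#' reported by the search output (may be `NA` until mapped). Fragment-ion
#' annotations (`ions_b_*`, `ions_y_*`) are comma-separated ordinal lists;
#' `n_peaks_total`/`n_peaks_assigned` summarise spectrum peak assignment.
#'
#' @param ... vectors for any subset of the schema columns; missing
#'   columns are filled with `NA`.
#' @return data.frame of class `xlink_ids`.
#' @export
xlink_ids <- function(...) {
  args <- list(...)
  unknown <- setdiff(names(args), ID_COLUMNS)
  if (length(unknown)) stop("unknown column(s): ",
                            paste(unknown, collapse = ", "))
  n <- if (length(args)) max(lengths(args)) else 0L
  tmpl <- empty_ids()
  out <- lapply(ID_COLUMNS, function(cn) {
    v <- if (cn %in% names(args)) args[[cn]] else rep(NA, n)
    v <- rep_len(v, n)
    mode_fun <- switch(class(tmpl[[cn]])[1],
                       character = as.character,
                       integer = as.integer,
                       numeric = as.numeric)
    v <- mode_fun(v)
    if (is.character(v)) v[!is.na(v) & !nzchar(v)] <- NA_character_
    v
  })
  names(out) <- ID_COLUMNS
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  class(df) <- c("xlink_ids", "data.frame")
  validate_ids(df)
  df
}

is_loop_record <- function(ids) is.na(ids$peptide_b)

validate_ids <- function(ids) {
  stopifnot(is.data.frame(ids), all(ID_COLUMNS %in% names(ids)))
  bad <- !is.na(ids$evalue) & ids$evalue <= 0
  if (any(bad)) stop("E-values must be positive (row ",
                     which(bad)[1], ")")
  len_a <- nchar(ids$peptide_a)
  if (any(!is.na(ids$pos_a) & (ids$pos_a < 1L | ids$pos_a > len_a))) {
    stop("pos_a outside peptide_a")
  }
  loop <- is_loop_record(ids)
  lim_b <- ifelse(loop, len_a, nchar(ids$peptide_b))
  if (any(!is.na(ids$pos_b) & (ids$pos_b < 1L | ids$pos_b > lim_b))) {
    stop("pos_b outside its peptide")
  }
  if (any(loop & !is.na(ids$pos_a) & !is.na(ids$pos_b) &
          ids$pos_a == ids$pos_b)) {
    stop("loop record with identical positions")
  }
  invisible(ids)
}

parse_ion_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  sort(unique(as.integer(strsplit(x, ",", fixed = TRUE)[[1]])))
}

format_ion_list <- function(v) {
  if (!length(v)) return(NA_character_)
  paste(sort(unique(as.integer(v))), collapse = ",")
}

# "ANIYAAK(7)" -> list(peptide, pos); "IKEKTVLSIR(2)(4)" -> two positions
parse_compact_peptide <- function(txt) {
  m <- regmatches(txt, regexec("^\\s*([A-Z]+)\\s*\\((\\d+)\\)(?:\\((\\d+)\\))?\\s*$",
                               txt))[[1]]
  if (!length(m)) stop("unparsable compact peptide: '", txt, "'")
  list(peptide = m[2], pos1 = as.integer(m[3]),
       pos2 = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_)
}

# "PBX1(87)-PREP1(55)" or "PREP1 (260)(262)"
parse_compact_link <- function(txt) {
  pair <- regmatches(txt, regexec(
    "^\\s*([A-Za-z0-9_.-]+)\\s*\\((\\d+)\\)\\s*-\\s*([A-Za-z0-9_.-]+)\\s*\\((\\d+)\\)\\s*$",
    txt))[[1]]
  if (length(pair)) {
    return(list(protein_a = pair[2], residue_a = as.integer(pair[3]),
                protein_b = pair[4], residue_b = as.integer(pair[5]),
                loop = FALSE))
  }
  lp <- regmatches(txt, regexec(
    "^\\s*([A-Za-z0-9_.-]+)\\s*\\((\\d+)\\)\\s*\\((\\d+)\\)\\s*$", txt))[[1]]
  if (length(lp)) {
    return(list(protein_a = lp[2], residue_a = as.integer(lp[3]),
                protein_b = lp[2], residue_b = as.integer(lp[4]),
                loop = TRUE))
  }
  stop("unparsable cross-link descriptor: '", txt, "'")
}

#' Read a compact-notation cross-link table
#'
#' Reads the two-column dialect used by the in-package fixtures: a `link`
#' column with the residue-level descriptor (`PBX1(87)-PREP1(55)` or, for
#' looped peptides, `PREP1(260)(262)`) and a `peptides` column with the
#' peptide pair and in-peptide link positions
#' (`KTVLSIR(1)-SQTPMDVDKQAIYR(9)` or `IKEKTVLSIR(2)(4)`). An optional
#' `replicate` column carries a replicate label (rows observed in several
#' replicates may be listed with semicolon-separated labels, which are
#' expanded to one record each).
#'
#' @param path TSV file.
#' @return an [xlink_ids()] table.
#' @export
parse_compact_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) return(empty_ids())
  need <- c("link", "peptides")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s) in '", path, "': ",
                         paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    lk <- tryCatch(parse_compact_link(raw$link[i]),
                   error = function(e) stop(conditionMessage(e),
                                            " (line ", i + 1L, ")"))
    reps <- if ("replicate" %in% names(raw) && nzchar(raw$replicate[i])) {
      strsplit(raw$replicate[i], ";", fixed = TRUE)[[1]]
    } else NA_character_
    if (lk$loop) {
      pep <- tryCatch(parse_compact_peptide(raw$peptides[i]),
                      error = function(e) stop(conditionMessage(e),
                                               " (line ", i + 1L, ")"))
      if (is.na(pep$pos2)) stop("loop record without second position (line ",
                                i + 1L, ")")
      xlink_ids(peptide_a = pep$peptide, pos_a = pep$pos1, pos_b = pep$pos2,
                protein_a = lk$protein_a, protein_b = lk$protein_b,
                residue_a = lk$residue_a, residue_b = lk$residue_b,
                replicate = reps)
    } else {
      parts <- strsplit(raw$peptides[i], ")-", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("expected a peptide pair (line ",
                                    i + 1L, "): '", raw$peptides[i], "'")
      pa <- parse_compact_peptide(paste0(parts[1], ")"))
      pb <- parse_compact_peptide(parts[2])
      xlink_ids(peptide_a = pa$peptide, pos_a = pa$pos1,
                peptide_b = pb$peptide, pos_b = pb$pos1,
                protein_a = lk$protein_a, protein_b = lk$protein_b,
                residue_a = lk$residue_a, residue_b = lk$residue_b,
                replicate = reps)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("xlink_ids", "data.frame")
  rownames(out) <- NULL
  out
}

#' Default column map for delimited identification exports
#'
#' @param ... overrides, e.g. `evalue = "E.value"`; names are schema
#'   columns, values the file's column names.
#' @param sep field separator of the file.
#' @return list with elements `columns` and `sep`.
#' @export
plink_dialect <- function(..., sep = "\t") {
  columns <- as.list(ID_COLUMNS)
  names(columns) <- ID_COLUMNS
  over <- list(...)
  unknown <- setdiff(names(over), ID_COLUMNS)
  if (length(unknown)) stop("unknown schema column(s): ",
                            paste(unknown, collapse = ", "))
  columns[names(over)] <- over
  list(columns = columns, sep = sep)
}

#' Read a delimited identification table
#'
#' Reads pLink-2-style delimited exports into the [xlink_ids()] schema.
#' Column names are resolved through a configurable dialect so that any
#' export whose columns can be mapped one-to-one onto the schema is
#' accepted; columns absent from the file are filled with `NA`
#' (`peptide_a`, `pos_a`, `protein_a` and `evalue` are required).
#'
#' @param path delimited text file.
#' @param dialect a [plink_dialect()].
#' @return an [xlink_ids()] table.
#' @export
parse_plink_table <- function(path, dialect = plink_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = dialect$sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) return(empty_ids())
  required <- c("peptide_a", "pos_a", "protein_a", "evalue")
  args <- list()
  for (cn in ID_COLUMNS) {
    file_col <- dialect$columns[[cn]]
    if (file_col %in% names(raw)) {
      args[[cn]] <- raw[[file_col]]
    } else if (cn %in% required) {
      stop("missing required column '", file_col, "' in '", path, "'")
    }
  }
  ids <- tryCatch(do.call(xlink_ids, args), error = function(e) {
    stop("while parsing '", path, "': ", conditionMessage(e))
  })
  ids
}

#' Write an identification table
#'
#' @param ids an [xlink_ids()] table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ids_table <- function(ids, path) {
  validate_ids(ids)
  write.table(ids, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
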