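#' In-silico digestion specification
#'
#' Describes a (double) enzymatic digest: trypsin cleaves C-terminally to
#' K/R, Glu-C C-terminally to E (optionally also D, a buffer-dependent
#' specificity). Cleavage is suppressed before a proline when
#' `proline_block` is set, and never occurs after a residue listed in
#' `blocked_sites` -- the mechanism by which a cross-linker-modified
#' lysine escapes cleavage and ends up inside (or at the N-terminus of) a
#' hybrid peptide such as KTVLSIR.
#'
#' @param enzymes subset of `c("trypsin", "gluc")`.
#' @param max_missed maximum number of missed cleavages, 0..5 (the search
#'   setting mirrored by the identification tables).
#' @param gluc_cleaves_d also cleave after D.
#' @param proline_block suppress cleavage when the next residue is P.
#' @param blocked_sites integer vector of 1-based residue positions after
#'   which cleavage is forbidden (cross-linked lysines).
#' @return object of class `digest_spec`.
#' @export
digest_spec <- function(enzymes = c("trypsin", "gluc"), max_missed = 0L,
                        gluc_cleaves_d = FALSE, proline_block = TRUE,
                        blocked_sites = integer(0)) {
  enzymes <- match.arg(enzymes, c("trypsin", "gluc"), several.ok = TRUE)
  max_missed <- as.integer(max_missed)
  if (max_missed < 0L || max_missed > 5L) {
    stop("max_missed must be between 0 and 5")
  }
  structure(list(enzymes = enzymes, max_missed = max_missed,
                 gluc_cleaves_d = isTRUE(gluc_cleaves_d),
                 proline_block = isTRUE(proline_block),
                 blocked_sites = as.integer(blocked_sites)),
            class = "digest_spec")
}

# 1-based positions i such that cleavage occurs between i and i+1
cleavage_sites <- function(sequence, spec) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  targets <- character(0)
  if ("trypsin" %in% spec$enzymes) targets <- c(targets, "K", "R")
  if ("gluc" %in% spec$enzymes) {
    targets <- c(targets, "E")
    if (spec$gluc_cleaves_d) targets <- c(targets, "D")
  }
  sites <- which(chars[-n] %in% targets)
  if (spec$proline_block && length(sites)) {
    sites <- sites[chars[sites + 1L] != "P"]
  }
  setdiff(sites, spec$blocked_sites)
}

#' In-silico (double) digestion of a protein
#'
#' Enumerates all peptides with up to `spec$max_missed` missed cleavages.
#' With `max_missed = 0` the peptides tile the sequence exactly; a
#' peptide with `k` missed cleavages is the merge of `k + 1` adjacent
#' fully-cleaved peptides.
#'
#' @param protein a [protein_record()] or a plain sequence string.
#' @param spec a [digest_spec()].
#' @return data.frame with columns `sequence`, `start`, `end`, `missed`,
#'   ordered by `start` then `missed`.
#' @examples
#' digest_in_silico("AKRLE", digest_spec())$sequence  # "AK" "R" "LE"
#' @export
digest_in_silico <- function(protein, spec = digest_spec()) {
  stopifnot(inherits(spec, "digest_spec"))
  seqstr <- if (inherits(protein, "protein_record")) protein$sequence
            else protein
  n <- nchar(seqstr)
  sites <- cleavage_sites(seqstr, spec)
  bounds <- c(0L, sites, n)            # peptide i spans bounds[i]+1 .. bounds[i+1]
  np <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(np)) {
    for (k in 0:min(spec$max_missed, np - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + k]
      out[[length(out) + 1L]] <- list(
        sequence = substring(seqstr, s, e), start = s, end = e, missed = k)
    }
  }
  df <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  df <- df[order(df$start, df$missed), , drop = FALSE]
  rownames(df) <- NULL
  df
}
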