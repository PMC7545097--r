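#' Summarise unique cross-links by class and protein pair
#'
#' @param links an `xlink_links` table from [collapse_redundant()].
#' @param proteins optional named list of annotated [protein_record()]s;
#'   when given, a domain-pair contact matrix is computed via
#'   [domain_lookup()].
#' @return object of class `link_summary`: list with
#'   `total` (number of unique links), `by_class` (named counts for
#'   inter/intra/loop), `intra_by_protein` and `loop_by_protein` (named
#'   counts), `by_pair` (data.frame protein_a, protein_b, link_class, n),
#'   `both_replicates` (data.frame of bold links, when flagged) and
#'   `domain_matrix` (or `NULL`).
#' @export
summarize_counts <- function(links, proteins = NULL) {
  stopifnot(inherits(links, "xlink_links"))
  by_class <- c(inter = sum(links$link_class == "inter"),
                intra = sum(links$link_class == "intra"),
                loop = sum(links$link_class == "loop"))
  tab_by <- function(cls) {
    sel <- links$link_class == cls
    if (!any(sel)) return(integer(0))
    tapply(rep(1L, sum(sel)), links$protein_a[sel], sum)
  }
  pair_key <- paste(links$protein_a, links$protein_b, links$link_class,
                    sep = "\r")
  pairs <- do.call(rbind, lapply(split(seq_len(nrow(links)), pair_key),
    function(g) data.frame(protein_a = links$protein_a[g[1]],
                           protein_b = links$protein_b[g[1]],
                           link_class = links$link_class[g[1]],
                           n = length(g), stringsAsFactors = FALSE)))
  if (is.null(pairs)) {
    pairs <- data.frame(protein_a = character(0), protein_b = character(0),
                        link_class = character(0), n = integer(0))
  }
  rownames(pairs) <- NULL
  domain_matrix <- NULL
  if (!is.null(proteins) && nrow(links)) {
    dom_a <- mapply(function(p, r) domain_lookup(proteins[[p]], r),
                    links$protein_a, links$residue_a)
    dom_b <- mapply(function(p, r) domain_lookup(proteins[[p]], r),
                    links$protein_b, links$residue_b)
    lab_a <- paste(links$protein_a, dom_a, sep = ":")
    lab_b <- paste(links$protein_b, dom_b, sep = ":")
    all_lab <- sort(unique(c(lab_a, lab_b)))
    domain_matrix <- matrix(0L, length(all_lab), length(all_lab),
                            dimnames = list(all_lab, all_lab))
    for (i in seq_along(lab_a)) {
      domain_matrix[lab_a[i], lab_b[i]] <- domain_matrix[lab_a[i], lab_b[i]] + 1L
      if (lab_a[i] != lab_b[i]) {
        domain_matrix[lab_b[i], lab_a[i]] <- domain_matrix[lab_b[i], lab_a[i]] + 1L
      }
    }
  }
  bold <- NULL
  if ("both_replicates" %in% names(links)) {
    bold <- links[links$both_replicates,
                  c("protein_a", "residue_a", "protein_b", "residue_b",
                    "link_class"), drop = FALSE]
    rownames(bold) <- NULL
  }
  structure(list(total = nrow(links), by_class = by_class,
                 intra_by_protein = tab_by("intra"),
                 loop_by_protein = tab_by("loop"),
                 by_pair = pairs, both_replicates = bold,
                 domain_matrix = domain_matrix),
            class = "link_summary")
}

#' @export
print.link_summary <- function(x, ...) {
  cat("<link_summary> ", x$total, " unique links (inter ",
      x$by_class[["inter"]], ", intra ", x$by_class[["intra"]],
      ", loop ", x$by_class[["loop"]], ")\n", sep = "")
  if (length(x$intra_by_protein)) {
    cat("  intra:", paste(names(x$intra_by_protein), x$intra_by_protein,
                          sep = "=", collapse = ", "), "\n")
  }
  if (length(x$loop_by_protein)) {
    cat("  loop:", paste(names(x$loop_by_protein), x$loop_by_protein,
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

default_map_style <- function() {
  list(width = 900, margin = 60, bar_height = 14, bar_gap = 140,
       scale = NULL, arc_scale = 0.35, stroke = "#444444",
       bold_width = 2.5, thin_width = 1,
       class_colors = c(inter = "#b2182b", intra = "#2166ac",
                        loop = "#4dac26"),
       domain_colors = c("#fdd49e", "#a6bddb", "#c2e699", "#f1b6da",
                         "#cccccc"))
}

#' Render a linear cross-link map as SVG
#'
#' Draws each protein as a horizontal bar (domain annotations as coloured
#' blocks) and each unique cross-link as an arc whose height is
#' proportional to the sequence separation. Links supported by both
#' replicates are drawn with a heavier stroke. The layout is
#' deterministic for a fixed input order.
#'
#' @param links an `xlink_links` table (optionally with
#'   `both_replicates`).
#' @param proteins named list of [protein_record()]s covering all linked
#'   proteins, drawn top to bottom in list order.
#' @param style named list overriding entries of the default style
#'   (colours, bar geometry, arc height factor).
#' @return single SVG string of class `svg_document`. Use
#'   [write_svg()] to save it.
#' @export
render_linear_map <- function(links, proteins, style = list()) {
  stopifnot(inherits(links, "xlink_links"))
  st <- utils::modifyList(default_map_style(), style)
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    names(proteins) <- vapply(proteins, `[[`, "", "name")
  }
  miss <- setdiff(unique(c(links$protein_a, links$protein_b)),
                  names(proteins))
  if (length(miss)) stop("unknown protein in links: ",
                         paste(miss, collapse = ", "))
  max_len <- max(vapply(proteins, `[[`, 0L, "length"))
  scale <- if (is.null(st$scale)) (st$width - 2 * st$margin) / max_len
           else st$scale
  ys <- st$margin + (seq_along(proteins) - 1L) * st$bar_gap
  names(ys) <- names(proteins)
  xpos <- function(protein, residue) st$margin + (residue - 0.5) * scale
  height <- st$margin + (length(proteins) - 1L) * st$bar_gap +
    st$bar_height + st$margin
  out <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            st$width, round(height), st$width, round(height)),
    "<metadata>linear cross-link map; domain blocks use the package's approximate default boundaries unless a custom table was supplied</metadata>")
  # protein bars + domains
  for (pn in names(proteins)) {
    p <- proteins[[pn]]
    y <- ys[[pn]]
    out <- c(out, sprintf(
      '<rect class="protein-bar" x="%.1f" y="%.1f" width="%.1f" height="%d" fill="#e8e8e8" stroke="#555"/>',
      st$margin, y, p$length * scale, st$bar_height))
    if (!is.null(p$domains) && nrow(p$domains)) {
      for (j in seq_len(nrow(p$domains))) {
        col <- st$domain_colors[(j - 1L) %% length(st$domain_colors) + 1L]
        out <- c(out, sprintf(
          '<rect class="domain-block" data-label="%s" x="%.1f" y="%.1f" width="%.1f" height="%d" fill="%s" stroke="#555"/>',
          svg_escape(p$domains$label[j]),
          st$margin + (p$domains$start[j] - 1) * scale, y,
          (p$domains$end[j] - p$domains$start[j] + 1) * scale,
          st$bar_height, col))
        out <- c(out, sprintf(
          '<text class="domain-label" x="%.1f" y="%.1f" font-size="9" text-anchor="middle">%s</text>',
          st$margin + (p$domains$start[j] + p$domains$end[j]) / 2 * scale,
          y + st$bar_height - 3, svg_escape(p$domains$label[j])))
      }
    }
    out <- c(out, sprintf(
      '<text class="protein-label" x="%.1f" y="%.1f" font-size="12">%s</text>',
      st$margin, y - 6, svg_escape(pn)))
  }
  # arcs
  bold <- if ("both_replicates" %in% names(links)) links$both_replicates
          else rep(FALSE, nrow(links))
  for (i in seq_len(nrow(links))) {
    pa <- links$protein_a[i]; pb <- links$protein_b[i]
    x1 <- xpos(pa, links$residue_a[i]); x2 <- xpos(pb, links$residue_b[i])
    cls <- links$link_class[i]
    col <- st$class_colors[[cls]]
    sw <- if (isTRUE(bold[i])) st$bold_width else st$thin_width
    if (pa == pb) {
      y <- ys[[pa]]
      h <- max(8, abs(x2 - x1) * st$arc_scale)
      d <- sprintf("M %.1f %.1f C %.1f %.1f, %.1f %.1f, %.1f %.1f",
                   x1, y, x1, y - h, x2, y - h, x2, y)
    } else {
      y1 <- ys[[pa]] + if (ys[[pa]] < ys[[pb]]) st$bar_height else 0
      y2 <- ys[[pb]] + if (ys[[pb]] < ys[[pa]]) st$bar_height else 0
      d <- sprintf("M %.1f %.1f L %.1f %.1f", x1, y1, x2, y2)
    }
    out <- c(out, sprintf(
      '<path class="xlink-arc" data-class="%s" data-link="%s(%d)-%s(%d)" d="%s" fill="none" stroke="%s" stroke-width="%.1f"/>',
      cls, svg_escape(pa), links$residue_a[i], svg_escape(pb),
      links$residue_b[i], d, col, sw))
  }
  out <- c(out, "</svg>")
  structure(paste(out, collapse = "\n"), class = "svg_document")
}

#' @export
print.svg_document <- function(x, ...) {
  cat("<svg_document> ", nchar(x), " characters\n", sep = "")
  invisible(x)
}

#' Write an SVG document
#'
#' @param svg an `svg_document` from [render_linear_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  stopifnot(inherits(svg, "svg_document"))
  writeLines(unclass(svg), path)
  invisible(path)
}

LINK_TSV_COLUMNS <- c("protein_a", "residue_a", "protein_b", "residue_b",
                      "link_class", "n_evidence", "best_evalue",
                      "replicates", "both_replicates")

#' Export unique cross-links as TSV
#'
#' Stable column order; round-trips through [read_link_table()].
#'
#' @param links an `xlink_links` table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_link_table <- function(links, path) {
  stopifnot(inherits(links, "xlink_links"))
  if (!"both_replicates" %in% names(links)) {
    links <- aggregate_replicates(links)
  }
  write.table(links[, LINK_TSV_COLUMNS, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a unique cross-link TSV
#'
#' @param path TSV written by [export_link_table()].
#' @return an `xlink_links` table (without the `evidence` list-column).
#' @export
read_link_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(LINK_TSV_COLUMNS, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, LINK_TSV_COLUMNS, drop = FALSE]
  df$replicates <- ifelse(is.na(df$replicates), "", df$replicates)
  df$residue_a <- as.integer(df$residue_a)
  df$residue_b <- as.integer(df$residue_b)
  df$n_evidence <- as.integer(df$n_evidence)
  df$best_evalue <- as.numeric(df$best_evalue)
  df$both_replicates <- as.logical(df$both_replicates)
  class(df) <- c("xlink_links", "data.frame")
  df
}
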