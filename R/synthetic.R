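# run expr under a local RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a reproducible pair of synthetic proteins
#'
#' Random sequences with a controlled lysine inventory, constrained so
#' that every fully-cleaved trypsin/Glu-C peptide of length >= 5 occurs
#' at a unique offset within its protein (regenerated on collision, up to
#' `max_retries`); unique peptide placement is what makes downstream
#' residue mapping unambiguous.
#'
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param length_a,length_b sequence lengths (>= 50).
#' @param n_lysines lysines per protein.
#' @param names protein names.
#' @param max_retries regeneration attempts before failing.
#' @return named list of two [protein_record()]s.
#' @export
synth_protein_pair <- function(seed, length_a = 300L, length_b = 300L,
                               n_lysines = 20L,
                               names = c("SYNA", "SYNB"),
                               max_retries = 50L) {
  stopifnot(length_a >= 50L, length_b >= 50L)
  with_seed(seed, {
    gen_one <- function(nm, len, nk) {
      if (nk > len) stop("more lysines than residues")
      alphabet <- setdiff(AA_STANDARD, "K")
      for (try in seq_len(max_retries)) {
        chars <- sample(alphabet, len, replace = TRUE)
        if (nk > 0L) chars[sample.int(len, nk)] <- "K"
        seqstr <- paste(chars, collapse = "")
        peps <- digest_in_silico(seqstr, digest_spec(max_missed = 0L))
        long <- unique(peps$sequence[nchar(peps$sequence) >= 5L])
        ok <- all(vapply(long, function(p) {
          length(gregexpr(p, seqstr, fixed = TRUE)[[1]]) == 1L
        }, NA))
        if (ok) return(protein_record(nm, seqstr))
      }
      stop("could not satisfy peptide uniqueness after ", max_retries,
           " attempts")
    }
    out <- list(gen_one(names[1], length_a, n_lysines),
                gen_one(names[2], length_b, n_lysines))
    names(out) <- names
    out
  })
}

# shortest digest peptide (allowing missed cleavages) containing residue,
# with the cross-linked site blocked, of length >= min_len
peptide_for_site <- function(protein, residues, spec_template, min_len = 5L) {
  spec <- digest_spec(enzymes = spec_template$enzymes,
                      max_missed = max(spec_template$max_missed, 2L),
                      gluc_cleaves_d = spec_template$gluc_cleaves_d,
                      proline_block = spec_template$proline_block,
                      blocked_sites = as.integer(residues))
  peps <- digest_in_silico(protein, spec)
  hit <- peps[peps$start <= min(residues) & peps$end >= max(residues) &
                nchar(peps$sequence) >= min_len, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  hit[order(nchar(hit$sequence), hit$start), ][1, , drop = FALSE]
}

#' Plant a cross-link truth set on a protein pair
#'
#' Chooses residue-level true links (inter, intra and loop) on lysines of
#' the given proteins, plus decoys each of which violates exactly one
#' curation rule by construction (`evalue`, `ions`, `majority` or
#' `nonlysine`).
#'
#' @param proteins named list of two [protein_record()]s.
#' @param n_inter,n_intra,n_loop numbers of true links by class (intra
#'   links are split between the two proteins).
#' @param n_decoys number of decoy records.
#' @param replicate_labels labels of the biological replicates.
#' @param evalue_true,evalue_decoy log-uniform E-value ranges for true
#'   links and E-value decoys.
#' @param seed integer seed.
#' @param digest a [digest_spec()] describing the digestion regime.
#' @return object of class `xlink_truth`: list with `proteins`,
#'   `true_links` (data.frame protein_a, residue_a, protein_b, residue_b,
#'   link_class), `decoys` (data.frame with `violation`), `digest`,
#'   `replicate_labels`, `evalue_true`, `evalue_decoy`, `seed`.
#' @export
synth_xlink_truth <- function(proteins, n_inter = 4L, n_intra = 4L,
                              n_loop = 2L, n_decoys = 10L,
                              replicate_labels = c("R1", "R2"),
                              evalue_true = c(1e-8, 1e-4),
                              evalue_decoy = c(1e-3, 1),
                              seed = 1L,
                              digest = digest_spec(max_missed = 5L)) {
  stopifnot(length(proteins) == 2L)
  if (is.null(names(proteins))) {
    names(proteins) <- vapply(proteins, `[[`, "", "name")
  }
  pa <- proteins[[1]]; pb <- proteins[[2]]
  if ((n_inter + n_intra + n_loop) > 0L &&
      (length(pa$lysines) == 0L || length(pb$lysines) == 0L)) {
    stop("cannot plant links: a protein has no lysines")
  }
  with_seed(seed, {
    usable <- function(p, residues) {
      vapply(residues, function(r)
        !is.null(peptide_for_site(p, r, digest)), NA)
    }
    ka <- pa$lysines[usable(pa, pa$lysines)]
    kb <- pb$lysines[usable(pb, pb$lysines)]
    links <- list()
    add_link <- function(p1, r1, p2, r2, cls) {
      links[[length(links) + 1L]] <<- data.frame(
        protein_a = p1, residue_a = r1, protein_b = p2, residue_b = r2,
        link_class = cls, stringsAsFactors = FALSE)
    }
    pick_pair <- function(pool1, pool2, same, used) {
      for (i in seq_len(500L)) {
        r1 <- sample(pool1, 1L); r2 <- sample(pool2, 1L)
        if (same && r1 == r2) next
        key <- paste(sort(c(r1, r2)), collapse = "-")
        if (!key %in% used) return(c(r1, r2))
      }
      stop("could not sample enough distinct link pairs")
    }
    used_inter <- character(0)
    for (i in seq_len(n_inter)) {
      pr <- pick_pair(ka, kb, FALSE, used_inter)
      used_inter <- c(used_inter, paste(sort(pr), collapse = "-"))
      add_link(pa$name, pr[1], pb$name, pr[2], "inter")
    }
    used_intra <- list(a = character(0), b = character(0))
    for (i in seq_len(n_intra)) {
      side <- if (i %% 2L == 1L) "a" else "b"
      p <- if (side == "a") pa else pb
      pool <- if (side == "a") ka else kb
      pr <- pick_pair(pool, pool, TRUE, used_intra[[side]])
      used_intra[[side]] <- c(used_intra[[side]],
                              paste(sort(pr), collapse = "-"))
      add_link(p$name, min(pr), p$name, max(pr), "intra")
    }
    loops_added <- 0L
    loop_used <- character(0)
    pools <- list(a = ka, b = kb)
    tries <- 0L
    while (loops_added < n_loop && tries < 1000L) {
      tries <- tries + 1L
      which_p <- if (tries %% 2L == 1L) "a" else "b"
      p <- if (which_p == "a") pa else pb
      pool <- pools[[which_p]]
      close <- which(outer(pool, pool, function(x, y) {
        d <- y - x; d > 0 & d <= 25
      }), arr.ind = TRUE)
      if (!nrow(close)) next
      pick <- close[sample.int(nrow(close), 1L), ]
      r1 <- pool[pick[1]]; r2 <- pool[pick[2]]
      key <- paste(p$name, r1, r2)
      if (key %in% loop_used) next
      if (is.null(peptide_for_site(p, c(r1, r2), digest))) next
      loop_used <- c(loop_used, key)
      add_link(p$name, r1, p$name, r2, "loop")
      loops_added <- loops_added + 1L
    }
    if (loops_added < n_loop) {
      stop("could not place ", n_loop, " loop links (lysines too sparse)")
    }
    true_links <- if (length(links)) do.call(rbind, links) else
      data.frame(protein_a = character(0), residue_a = integer(0),
                 protein_b = character(0), residue_b = integer(0),
                 link_class = character(0))
    # decoys: rotate through the violation types
    types <- c("evalue", "ions", "majority", "nonlysine")
    decoys <- list()
    used_d <- character(0)
    for (i in seq_len(n_decoys)) {
      vt <- types[(i - 1L) %% length(types) + 1L]
      if (vt == "nonlysine") {
        # a position that is not K: take a non-K residue inside a peptide
        for (j in seq_len(500L)) {
          r1 <- sample.int(pa$length, 1L)
          if (residue_at(pa, r1) == "K") next
          if (is.null(peptide_for_site(pa, r1, digest))) next
          r2 <- sample(kb, 1L)
          key <- paste("nl", r1, r2)
          if (key %in% used_d) next
          used_d <- c(used_d, key)
          decoys[[length(decoys) + 1L]] <- data.frame(
            protein_a = pa$name, residue_a = r1, protein_b = pb$name,
            residue_b = r2, link_class = "inter", violation = vt,
            stringsAsFactors = FALSE)
          break
        }
      } else {
        pr <- pick_pair(ka, kb, FALSE, c(used_inter, used_d))
        used_d <- c(used_d, paste(sort(pr), collapse = "-"))
        decoys[[length(decoys) + 1L]] <- data.frame(
          protein_a = pa$name, residue_a = pr[1], protein_b = pb$name,
          residue_b = pr[2], link_class = "inter", violation = vt,
          stringsAsFactors = FALSE)
      }
    }
    decoys <- if (length(decoys)) do.call(rbind, decoys) else
      data.frame(protein_a = character(0), residue_a = integer(0),
                 protein_b = character(0), residue_b = integer(0),
                 link_class = character(0), violation = character(0))
    structure(list(proteins = proteins, true_links = true_links,
                   decoys = decoys, digest = digest,
                   replicate_labels = replicate_labels,
                   evalue_true = evalue_true, evalue_decoy = evalue_decoy,
                   seed = seed),
              class = "xlink_truth")
  })
}

rlog_uniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

ion_series_passing <- function(pep_len) {
  # full y series: longest consecutive run = pep_len - 1 >= 4
  format_ion_list(seq_len(max(pep_len - 1L, 1L)))
}

ion_series_failing <- function(pep_len) {
  # max run of 3, never 4, regardless of length
  ords <- seq_len(max(pep_len - 1L, 1L))
  format_ion_list(ords[(ords - 1L) %% 4L != 3L][seq_len(min(3L, length(ords)))])
}

#' Emit a synthetic identification table from a planted truth
#'
#' Each true link is emitted as 1--3 records distributed over the
#' replicate labels, with passing E-values, full consecutive ion series
#' and a majority of assigned peaks; the cross-linked lysine is treated
#' as a blocked cleavage site when selecting the supporting peptide.
#' Each decoy record fails exactly its designated rule. The result is an
#' [xlink_ids()] table (claimed residues filled), parseable and mappable
#' by the analysis pipeline.
#'
#' @param truth an [synth_xlink_truth()] object.
#' @param seed integer seed (defaults to the truth's).
#' @return an `xlink_ids` table with attribute `truth`.
#' @export
synth_xlink_dataset <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "xlink_truth"))
  proteins <- truth$proteins
  with_seed(seed + 1000L, {
    rows <- list()
    emit <- function(link, evalue, reps, pass_ions = TRUE,
                     majority = 0.7, shift_pos = 0L) {
      p1 <- proteins[[link$protein_a]]; p2 <- proteins[[link$protein_b]]
      if (link$link_class == "loop") {
        pep <- peptide_for_site(p1, c(link$residue_a, link$residue_b),
                                truth$digest)
        if (is.null(pep)) stop("no peptide covers loop site")
        for (rep in reps) {
          rows[[length(rows) + 1L]] <<- xlink_ids(
            peptide_a = pep$sequence,
            pos_a = link$residue_a - pep$start + 1L,
            pos_b = link$residue_b - pep$start + 1L,
            protein_a = link$protein_a, protein_b = link$protein_b,
            residue_a = link$residue_a, residue_b = link$residue_b,
            evalue = evalue, replicate = rep,
            ions_y_a = if (pass_ions) ion_series_passing(nchar(pep$sequence))
                       else ion_series_failing(nchar(pep$sequence)),
            n_peaks_total = 40L,
            n_peaks_assigned = as.integer(round(40 * majority)))
        }
      } else {
        pep_a <- peptide_for_site(p1, link$residue_a, truth$digest)
        pep_b <- peptide_for_site(p2, link$residue_b, truth$digest)
        if (is.null(pep_a) || is.null(pep_b)) stop("no peptide covers site")
        for (rep in reps) {
          rows[[length(rows) + 1L]] <<- xlink_ids(
            peptide_a = pep_a$sequence,
            pos_a = link$residue_a - pep_a$start + 1L,
            peptide_b = pep_b$sequence,
            pos_b = link$residue_b - pep_b$start + 1L,
            protein_a = link$protein_a, protein_b = link$protein_b,
            residue_a = link$residue_a, residue_b = link$residue_b,
            evalue = evalue, replicate = rep,
            ions_y_a = if (pass_ions) ion_series_passing(nchar(pep_a$sequence))
                       else ion_series_failing(nchar(pep_a$sequence)),
            ions_y_b = if (pass_ions) ion_series_passing(nchar(pep_b$sequence))
                       else ion_series_failing(nchar(pep_b$sequence)),
            n_peaks_total = 40L,
            n_peaks_assigned = as.integer(round(40 * majority)))
        }
      }
    }
    tl <- truth$true_links
    for (i in seq_len(nrow(tl))) {
      n_rep <- sample(c(1L, 2L), 1L)
      reps <- sample(truth$replicate_labels, n_rep)
      n_extra <- sample(0:1, 1L)
      reps <- c(reps, if (n_extra) sample(reps, 1L))
      emit(tl[i, ], rlog_uniform(1L, truth$evalue_true), reps)
    }
    dc <- truth$decoys
    for (i in seq_len(nrow(dc))) {
      vt <- dc$violation[i]
      link <- dc[i, ]
      rep <- sample(truth$replicate_labels, 1L)
      switch(vt,
        evalue = emit(link, rlog_uniform(1L, truth$evalue_decoy), rep),
        ions = emit(link, rlog_uniform(1L, truth$evalue_true), rep,
                    pass_ions = FALSE),
        majority = emit(link, rlog_uniform(1L, truth$evalue_true), rep,
                        majority = 0.4),
        nonlysine = emit(link, rlog_uniform(1L, truth$evalue_true), rep))
    }
    out <- if (length(rows)) do.call(rbind, rows) else empty_ids()
    class(out) <- c("xlink_ids", "data.frame")
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Standard ELISA dose ladder
#'
#' Eight 3-fold dilutions from 500 nM down to 0.23 nM, the span used for
#' the saturation assays this package models.
#'
#' @return numeric vector of doses in nM, ascending.
#' @export
elisa_doses <- function() 500 / 3^(7:0)

#' Simulate one-site binding curves with multiplicative noise
#'
#' Signal `baseline + bmax * x / (kd + x)` multiplied by unit-mean
#' log-normal noise of coefficient of variation `noise_cv`
#' (immunoassay-like multiplicative error).
#'
#' @param kd dissociation constant (nM, > 0).
#' @param bmax saturation signal.
#' @param baseline signal at zero dose.
#' @param doses concentrations (nM).
#' @param noise_cv coefficient of variation of the noise (>= 0).
#' @param n_replicates replicates per dose.
#' @param seed integer seed.
#' @return a [binding_curve()].
#' @export
synth_binding_curves <- function(kd, bmax = 1, baseline = 0,
                                 doses = elisa_doses(), noise_cv = 0.05,
                                 n_replicates = 3L, seed = 1L) {
  stopifnot(kd > 0, noise_cv >= 0)
  with_seed(seed, {
    dose <- rep(doses, times = n_replicates)
    repl <- rep(paste0("R", seq_len(n_replicates)), each = length(doses))
    mu <- one_site(dose, kd, bmax, baseline)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      mu <- mu * exp(rnorm(length(mu), -sdlog^2 / 2, sdlog))
    }
    binding_curve(dose, mu, repl)
  })
}

# ---- microscopy field generators ----

inside_ellipse <- function(r, c, ell, scale = 1) {
  th <- ell$theta
  dr <- r - ell$row; dc <- c - ell$col
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  (u / (ell$a * scale))^2 + (v / (ell$b * scale))^2 <= 1
}

#' Sample a ground-truth layout for a synthetic PLA field
#'
#' Elliptical nuclei plus point foci flagged nuclear or cytoplasmic, with
#' minimum pairwise separation and margins that keep the classification
#' unambiguous, over a linear background gradient with Gaussian noise.
#'
#' @param shape image dimensions (rows, cols).
#' @param n_nuclei number of nuclei.
#' @param n_nuclear_foci,n_cyto_foci planted focus counts.
#' @param amplitude focus peak amplitude above background.
#' @param noise_sd Gaussian noise standard deviation.
#' @param spot_sigma Gaussian focus width (px).
#' @param min_separation minimum distance between foci (px).
#' @param seed integer seed.
#' @return object of class `image_truth` (list of geometry, intensities
#'   and the seed).
#' @export
synth_image_truth <- function(shape = c(160L, 160L), n_nuclei = 3L,
                              n_nuclear_foci = 12L, n_cyto_foci = 5L,
                              amplitude = 100, noise_sd = 4,
                              spot_sigma = 1.5, min_separation = 10,
                              seed = 1L) {
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    margin <- 14
    nuclei <- list()
    tries <- 0L
    while (length(nuclei) < n_nuclei && tries < 5000L) {
      tries <- tries + 1L
      cand <- list(row = runif(1, margin + 20, nr - margin - 20),
                   col = runif(1, margin + 20, nc - margin - 20),
                   a = runif(1, 15, 19), b = runif(1, 13, 17),
                   theta = runif(1, 0, pi))
      ok <- all(vapply(nuclei, function(e) {
        sqrt((e$row - cand$row)^2 + (e$col - cand$col)^2) >
          (max(e$a, e$b) + max(cand$a, cand$b) + 5)
      }, NA) | !length(nuclei))
      if (ok) nuclei[[length(nuclei) + 1L]] <- cand
    }
    if (length(nuclei) < n_nuclei) stop("could not place nuclei")
    foci <- data.frame(row = numeric(0), col = numeric(0), nuclear = logical(0))
    place_focus <- function(nuclear) {
      for (j in seq_len(20000L)) {
        r <- runif(1, 8, nr - 8); c <- runif(1, 8, nc - 8)
        in_core <- any(vapply(nuclei, function(e)
          inside_ellipse(r, c, e, scale = 0.75), NA))
        near <- any(vapply(nuclei, function(e)
          inside_ellipse(r, c, e, scale = 1.25), NA))
        ok_zone <- if (nuclear) in_core else !near
        if (!ok_zone) next
        if (nrow(foci) &&
            min(sqrt((foci$row - r)^2 + (foci$col - c)^2)) < min_separation) {
          next
        }
        foci[nrow(foci) + 1L, ] <<- list(round(r), round(c), nuclear)
        return(invisible())
      }
      stop("could not place focus (field too crowded)")
    }
    for (i in seq_len(n_nuclear_foci)) place_focus(TRUE)
    for (i in seq_len(n_cyto_foci)) place_focus(FALSE)
    structure(list(shape = as.integer(shape), nuclei = nuclei, foci = foci,
                   amplitude = amplitude, noise_sd = noise_sd,
                   spot_sigma = spot_sigma,
                   nucleus_intensity = 120, background_base = 10,
                   background_slope = c(row = 0.08, col = 0.05),
                   seed = as.integer(seed)),
              class = "image_truth")
  })
}

render_spots <- function(shape, foci, amplitude, sigma) {
  img <- matrix(0, shape[1], shape[2])
  if (!nrow(foci)) return(img)
  half <- ceiling(4 * sigma)
  for (i in seq_len(nrow(foci))) {
    r0 <- foci$row[i]; c0 <- foci$col[i]
    rs <- max(1, r0 - half):min(shape[1], r0 + half)
    cs <- max(1, c0 - half):min(shape[2], c0 + half)
    g <- outer(rs - r0, cs - c0, function(dr, dc)
      exp(-(dr^2 + dc^2) / (2 * sigma^2)))
    img[rs, cs] <- img[rs, cs] + amplitude * g
  }
  img
}

#' Render a synthetic PLA field from a ground truth
#'
#' DAPI channel: filled nucleus ellipses (softened by a light blur) plus
#' noise; red channel: Gaussian spots at the planted foci over a linear
#' background gradient plus noise. Bitwise reproducible from the truth's
#' seed.
#'
#' @param truth an [synth_image_truth()] object.
#' @return list with `field` (an [image_field()] with `dapi` and `red`)
#'   and `truth`.
#' @export
synth_pla_image <- function(truth) {
  stopifnot(inherits(truth, "image_truth"))
  with_seed(truth$seed + 7L, {
    nr <- truth$shape[1]; nc <- truth$shape[2]
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    nuc <- matrix(FALSE, nr, nc)
    for (e in truth$nuclei) nuc <- nuc | inside_ellipse(rr, cc, e)
    dapi <- truth$background_base + truth$nucleus_intensity * nuc
    dapi <- gaussian_blur(dapi, 1)
    dapi <- dapi + rnorm(nr * nc, 0, truth$noise_sd)
    bg <- truth$background_base +
      truth$background_slope[["row"]] * rr +
      truth$background_slope[["col"]] * cc
    red <- bg + render_spots(truth$shape, truth$foci, truth$amplitude,
                             truth$spot_sigma)
    red <- red + rnorm(nr * nc, 0, truth$noise_sd)
    field <- image_field(list(dapi = pmax(dapi, 0), red = pmax(red, 0)))
    list(field = field, truth = truth)
  })
}

#' Synthetic nuclear/cytoplasmic localisation field
#'
#' Cells are concentric ellipse pairs: the nucleus carries
#' `nuclear_mean` GFP intensity, the surrounding cytoplasmic annulus
#' `cyto_mean`, plus optional Gaussian noise; the DAPI channel marks the
#' nuclei. The planted ratio `nuclear_mean / cyto_mean` is recorded, and
#' the per-cell nucleus and cytoplasm masks are returned so that
#' quantification can be run against exact regions.
#'
#' @param nuclear_mean,cyto_mean per-compartment mean intensities (>= 0).
#' @param n_cells number of cells.
#' @param shape image dimensions.
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `field` (channels `dapi`, `gfp`), `nucleus_labels`
#'   (matrix), `cytoplasm_labels` (matrix), `true_ratio`.
#' @export
synth_nc_image <- function(nuclear_mean = 100, cyto_mean = 25,
                           n_cells = 3L, shape = c(128L, 128L),
                           noise_sd = 0, seed = 1L) {
  stopifnot(nuclear_mean >= 0, cyto_mean >= 0)
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    cells <- list()
    tries <- 0L
    while (length(cells) < n_cells && tries < 5000L) {
      tries <- tries + 1L
      cand <- list(row = runif(1, 26, nr - 26), col = runif(1, 26, nc - 26),
                   a = runif(1, 10, 13), b = runif(1, 9, 12),
                   theta = runif(1, 0, pi))
      ok <- !length(cells) || all(vapply(cells, function(e)
        sqrt((e$row - cand$row)^2 + (e$col - cand$col)^2) > 46, NA))
      if (ok) cells[[length(cells) + 1L]] <- cand
    }
    if (length(cells) < n_cells) stop("could not place cells")
    nucleus_labels <- matrix(0L, nr, nc)
    cytoplasm_labels <- matrix(0L, nr, nc)
    gfp <- matrix(0, nr, nc)
    for (k in seq_along(cells)) {
      e <- cells[[k]]
      nucp <- inside_ellipse(rr, cc, e)
      cytp <- inside_ellipse(rr, cc, e, scale = 1.9) & !nucp
      nucleus_labels[nucp] <- k
      cytoplasm_labels[cytp] <- k
      gfp[nucp] <- nuclear_mean
      gfp[cytp] <- cyto_mean
    }
    dapi <- 10 + 120 * (nucleus_labels > 0L)
    if (noise_sd > 0) {
      gfp <- pmax(gfp + rnorm(nr * nc, 0, noise_sd), 0)
      dapi <- pmax(dapi + rnorm(nr * nc, 0, noise_sd), 0)
    }
    list(field = image_field(list(dapi = dapi, gfp = gfp)),
         nucleus_labels = nucleus_labels,
         cytoplasm_labels = cytoplasm_labels,
         true_ratio = if (cyto_mean > 0) nuclear_mean / cyto_mean else Inf)
  })
}
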