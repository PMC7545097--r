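#' Multichannel image field
#'
#' @param channels named list of equal-shaped numeric matrices (e.g.
#'   `dapi`, `red`, `gfp`), intensities finite and non-negative.
#' @param pixel_size optional physical pixel size.
#' @return object of class `image_field`.
#' @export
image_field <- function(channels, pixel_size = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), NA))) {
    stop("channel shapes differ")
  }
  for (ch in names(channels)) {
    m <- channels[[ch]]
    if (!is.matrix(m) || !is.numeric(m)) stop("channel '", ch,
                                              "' is not a numeric matrix")
    if (any(!is.finite(m))) stop("non-finite intensities in '", ch, "'")
    if (any(m < 0)) stop("negative intensities in '", ch, "'")
  }
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<image_field> ", d[1], "x", d[2], " px, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# affine rescale to [0,1] for EBImage morphology (which clamps), undo after
with_unit_scale <- function(image, f) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)            # constant: morphology is identity
  out <- f((image - lo) / (hi - lo))
  out * (hi - lo) + lo
}

#' Rolling-ball style background estimation
#'
#' Estimates a smooth background as the grayscale opening of the image by
#' a disc-shaped structuring element of the given radius (the flat-disc
#' approximation of the rolling-ball algorithm) and subtracts it. The
#' background never exceeds the image, so the corrected image is
#' non-negative, and a constant image corrects to all zeros.
#'
#' @param image numeric matrix.
#' @param radius ball radius in pixels (>= 1).
#' @return list with `background` and `corrected` matrices.
#' @export
rolling_ball_background <- function(image, radius = 50) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (radius < 1) stop("radius must be >= 1")
  d <- dim(image)
  if (2 * radius + 1 > max(d)) {
    warning("radius exceeds image extent; using global minimum background")
    bg <- matrix(min(image), d[1], d[2])
    return(list(background = bg, corrected = image - bg))
  }
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- with_unit_scale(image, function(u) {
    as.matrix(EBImage::opening(u, brush))
  })
  bg <- pmin(bg, image)   # guard against rounding above the image
  list(background = bg, corrected = image - bg)
}

#' Gaussian blur
#'
#' Separable Gaussian smoothing; `sigma = 0` is the identity. Borders are
#' handled by replication, so total intensity is conserved up to boundary
#' effects.
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels (>= 0).
#' @return blurred matrix.
#' @export
gaussian_blur <- function(image, sigma) {
  stopifnot(is.matrix(image), is.numeric(image), sigma >= 0)
  if (sigma == 0) return(image)
  as.matrix(EBImage::gblur(image, sigma = sigma, boundary = "replicate"))
}

# shared histogram over `levels` integer bins; integer-valued images keep
# their own levels so that thresholds are on the native intensity scale
histogram_levels <- function(image, levels = 256L) {
  v <- as.vector(image)
  if (all(v == round(v)) && diff(range(v)) <= levels - 1L) {
    g <- sort(unique(as.integer(v)))
    lev <- seq(min(g), max(g))
  } else {
    lo <- min(v); hi <- max(v)
    lev <- lo + (seq_len(levels) - 1L) * (hi - lo) / (levels - 1L)
    v <- lev[pmin(levels, pmax(1L, 1L + round((v - lo) / (hi - lo) *
                                                (levels - 1L))))]
  }
  counts <- tabulate(match(v, lev), nbins = length(lev))
  list(levels = lev, counts = counts)
}

#' Otsu threshold
#'
#' Returns the intensity `t` maximising the between-class variance of the
#' histogram split into `value <= t` and `value > t`. Integer images use
#' their native levels; continuous images are binned into `levels` bins.
#' Ties are broken toward the lowest threshold.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param levels number of histogram bins for continuous images.
#' @return threshold value; foreground is `image > t`.
#' @export
threshold_otsu <- function(image, levels = 256L) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (length(unique(as.vector(image))) < 2L) {
    stop("degenerate input: constant image has no threshold")
  }
  h <- histogram_levels(image, levels)
  n <- sum(h$counts)
  w0 <- cumsum(h$counts) / n
  mu <- cumsum(h$counts * h$levels) / n
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(h$levels))
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  separating_threshold(h, which.max(bcv))
}

# report the threshold as the midpoint between the last background level
# and the first foreground level actually present, so it separates the
# two classes strictly
separating_threshold <- function(h, ti) {
  above <- which(h$counts > 0 & seq_along(h$levels) > ti)
  if (!length(above)) return(h$levels[ti])
  (h$levels[ti] + h$levels[above[1]]) / 2
}

huang_cost_from_hist <- function(levels, counts, C) {
  n <- sum(counts)
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * levels)
  costs <- rep(Inf, length(levels))
  for (ti in seq_along(levels)) {
    n0 <- cum_n[ti]; n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- cum_s[ti] / n0
    mu1 <- (cum_s[length(levels)] - cum_s[ti]) / n1
    mu <- ifelse(seq_along(levels) <= ti, mu0, mu1)
    u <- 1 / (1 + abs(levels - mu) / C)
    s <- ifelse(u <= 0 | u >= 1, 0,
                -u * log(u) - (1 - u) * log(1 - u))
    costs[ti] <- sum(counts * s)
  }
  costs
}

#' Huang fuzzy-entropy threshold
#'
#' Minimises the Huang--Wang fuzzy entropy: for a candidate threshold the
#' two class means define a membership
#' `u(g) = 1 / (1 + |g - mu_class(g)| / C)` with `C = g_max - g_min`, and
#' the cost is the Shannon entropy `S(u) = -u log u - (1-u) log(1-u)`
#' accumulated over the histogram. The threshold with minimal cost is
#' returned (lowest such threshold on ties).
#'
#' @inheritParams threshold_otsu
#' @return threshold value; foreground is `image > t`.
#' @export
threshold_huang <- function(image, levels = 256L) {
  stopifnot(is.matrix(image), is.numeric(image))
  v <- as.vector(image)
  if (length(unique(v)) < 2L) {
    stop("degenerate input: constant image has no threshold")
  }
  h <- histogram_levels(image, levels)
  C <- max(v) - min(v)
  costs <- huang_cost_from_hist(h$levels, h$counts, C)
  separating_threshold(h, which.min(costs))
}

# ---- Find Maxima (prominence / noise-tolerance semantics) ----

neighbor_offsets8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Detect intensity maxima with a noise tolerance
#'
#' Reimplementation of the Find Maxima behaviour: a regional maximum `m`
#' is accepted iff no path starting at `m` can reach a strictly higher
#' pixel without first descending below `value(m) - noise_tolerance`
#' (prominence semantics). The global maximum, which has no higher
#' ground, follows the topographic convention: its prominence is the
#' height above the image minimum and must likewise exceed the
#' tolerance. Equal-valued plateau maxima are merged to a
#' single point at the plateau's centre of mass (rounded to the nearest
#' plateau pixel; ties broken toward the smallest row, then column).
#' Output is deterministic and ordered by decreasing value, then row/col.
#'
#' @param image numeric matrix.
#' @param noise_tolerance positive prominence threshold.
#' @return data.frame with columns `row`, `col`, `value`; zero rows for a
#'   flat image.
#' @export
find_maxima <- function(image, noise_tolerance) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!(noise_tolerance > 0)) stop("noise_tolerance must be > 0")
  nr <- nrow(image); nc <- ncol(image); n <- nr * nc
  empty <- data.frame(row = integer(0), col = integer(0),
                      value = numeric(0))
  if (length(unique(as.vector(image))) < 2L) return(empty)
  v <- as.vector(image)                 # column-major: idx = (c-1)*nr + r
  ord <- order(v, decreasing = TRUE)
  parent <- integer(n)                  # 0 = not yet activated
  peak_val <- numeric(n)                # component peak value (at root)
  alive <- vector("list", n)            # plateau indices of alive maxima
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  accepted <- list()
  finish_maxima <- function(plateaus, vmax, level) {
    # maxima of value vmax whose component gained a higher pixel at `level`
    for (pl in plateaus) {
      if (level < vmax - noise_tolerance) accepted[[length(accepted) + 1L]] <<-
          list(idx = pl, value = vmax)
    }
  }
  pos <- 1L
  while (pos <= n) {
    val <- v[ord[pos]]
    end <- pos
    while (end < n && v[ord[end + 1L]] == val) end <- end + 1L
    batch <- ord[pos:end]
    # activate batch pixels as singleton components
    parent[batch] <- batch
    peak_val[batch] <- val
    for (i in batch) alive[[i]] <- list()   # placeholder; plateaus set below
    # union within batch and with active higher neighbours
    for (i in batch) {
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (k in 1:8) {
        r2 <- r + neighbor_offsets8[k, 1L]
        c2 <- cc + neighbor_offsets8[k, 2L]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- (c2 - 1L) * nr + r2
        if (parent[j] == 0L) next         # not yet activated (lower value)
        ri <- find_root(i); rj <- find_root(j)
        if (ri == rj) next
        pi <- peak_val[ri]; pj <- peak_val[rj]
        if (pi == pj) {                   # same peak height: merge alive sets
          parent[rj] <- ri
          alive[[ri]] <- c(alive[[ri]], alive[[rj]])
          alive[[rj]] <- list()
        } else {
          lo <- if (pi < pj) ri else rj
          hi <- if (pi < pj) rj else ri
          finish_maxima(alive[[lo]], peak_val[lo], val)
          alive[[lo]] <- list()
          parent[lo] <- hi
        }
      }
    }
    # new components made entirely of batch pixels are regional-max plateaus
    rb <- vapply(batch, find_root, 0L)
    for (rt in unique(rb)) {
      if (peak_val[rt] == val && length(alive[[rt]]) == 0L) {
        alive[[rt]] <- list(batch[rb == rt])
      }
    }
    pos <- end + 1L
  }
  # components never merged into anything higher hold the global maxima;
  # their prominence is the height above the image minimum (topographic
  # convention), which must also clear the tolerance
  vmin <- min(v)
  for (i in seq_len(n)) {
    if (parent[i] == i && length(alive[[i]]) &&
        peak_val[i] - vmin > noise_tolerance) {
      for (pl in alive[[i]]) accepted[[length(accepted) + 1L]] <-
          list(idx = pl, value = peak_val[i])
    }
  }
  if (!length(accepted)) return(empty)
  pts <- do.call(rbind, lapply(accepted, function(a) {
    rr <- ((a$idx - 1L) %% nr) + 1L
    cc <- ((a$idx - 1L) %/% nr) + 1L
    cm_r <- mean(rr); cm_c <- mean(cc)
    d2 <- (rr - cm_r)^2 + (cc - cm_c)^2
    sel <- order(d2, rr, cc)[1L]
    data.frame(row = rr[sel], col = cc[sel], value = a$value)
  }))
  pts <- pts[order(-pts$value, pts$row, pts$col), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

# 8-connected components of a logical mask (union-find)
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  parent <- seq_along(idx)
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  find_root <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (t in seq_along(idx)) {
    i <- idx[t]
    r <- ((i - 1L) %% nr) + 1L
    cc <- ((i - 1L) %/% nr) + 1L
    for (k in c(1L, 2L, 3L, 4L)) {       # upper-left half of 8-neighbourhood
      r2 <- r + neighbor_offsets8[k, 1L]
      c2 <- cc + neighbor_offsets8[k, 2L]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      j <- (c2 - 1L) * nr + r2
      if (pos[j] == 0L) next
      ra <- find_root(t); rb <- find_root(pos[j])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find_root, 0L)
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Nucleus segmentation configuration
#'
#' @param rolling_radius rolling-ball radius for background removal (px).
#' @param sigma Gaussian blur sigma (px).
#' @param method threshold method, `"huang"` or `"otsu"`.
#' @param min_area minimum nucleus area (px^2).
#' @param fill_holes fill holes inside nuclei.
#' @param min_contrast minimum dynamic range of the processed DAPI image
#'   for thresholding to be attempted (guards blank fields, in which a
#'   histogram threshold would otherwise split noise).
#' @return list of class `nuclei_config`.
#' @export
nuclei_config <- function(rolling_radius = 50, sigma = 2,
                          method = c("huang", "otsu"), min_area = 200,
                          fill_holes = TRUE, min_contrast = 5) {
  method <- match.arg(method)
  structure(list(rolling_radius = rolling_radius, sigma = sigma,
                 method = method, min_area = min_area,
                 fill_holes = isTRUE(fill_holes),
                 min_contrast = min_contrast),
            class = "nuclei_config")
}

#' Segment nuclei from a DAPI channel
#'
#' Pipeline: rolling-ball background removal, Gaussian blur, global
#' threshold (Huang by default, Otsu optionally), 8-connected component
#' labelling, hole filling and minimum-area filtering. Labels are
#' contiguous positive integers, stable for a fixed input.
#'
#' @param dapi numeric matrix (DAPI channel).
#' @param cfg a [nuclei_config()].
#' @return object of class `nucleus_mask`: list with `labels` (integer
#'   matrix, 0 = background), `n` and `table` (per-nucleus `label`,
#'   `area`, `centroid_row`, `centroid_col`).
#' @export
segment_nuclei <- function(dapi, cfg = nuclei_config()) {
  stopifnot(is.matrix(dapi), inherits(cfg, "nuclei_config"))
  img <- if (cfg$rolling_radius > 0) {
    rolling_ball_background(dapi, cfg$rolling_radius)$corrected
  } else dapi
  img <- gaussian_blur(img, cfg$sigma)
  if (diff(range(img)) < cfg$min_contrast) {
    warning("no nucleus found (image contrast below min_contrast)")
    return(empty_mask(dim(dapi)))
  }
  thr <- tryCatch(
    switch(cfg$method, huang = threshold_huang(img),
           otsu = threshold_otsu(img)),
    error = function(e) NA_real_)
  if (is.na(thr)) {
    warning("no nucleus found (degenerate image)")
    return(empty_mask(dim(dapi)))
  }
  mask <- img > thr
  lab <- label_components8(mask)
  if (cfg$fill_holes && max(lab) > 0L) {
    lab <- as.matrix(EBImage::fillHull(lab))
    storage.mode(lab) <- "integer"
  }
  if (max(lab) == 0L) {
    warning("no nucleus found")
    return(empty_mask(dim(dapi)))
  }
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= cfg$min_area)
  if (!length(keep)) {
    warning("no nucleus passed the area filter")
    return(empty_mask(dim(dapi)))
  }
  relab <- integer(max(lab)); relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  tab <- do.call(rbind, lapply(seq_along(keep), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    data.frame(label = k, area = nrow(px),
               centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
  }))
  structure(list(labels = lab, n = length(keep), table = tab),
            class = "nucleus_mask")
}

empty_mask <- function(d) {
  structure(list(labels = matrix(0L, d[1], d[2]), n = 0L,
                 table = data.frame(label = integer(0), area = integer(0),
                                    centroid_row = numeric(0),
                                    centroid_col = numeric(0))),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat("<nucleus_mask> ", x$n, " nuclei\n", sep = "")
  invisible(x)
}

#' Partition foci into nuclear and cytoplasmic
#'
#' A focus is nuclear iff the nucleus-mask label at its pixel is
#' positive. The two totals always partition the focus list.
#'
#' @param foci data.frame from [find_maxima()].
#' @param mask a `nucleus_mask` from [segment_nuclei()].
#' @return list with `n_nuclear`, `n_cytoplasmic`, `per_nucleus` (named
#'   integer vector over nucleus labels) and `foci` (input plus an
#'   `inside_nucleus` label column, 0 = cytoplasmic).
#' @export
count_foci <- function(foci, mask) {
  stopifnot(inherits(mask, "nucleus_mask"))
  lab <- if (nrow(foci)) mask$labels[cbind(foci$row, foci$col)]
         else integer(0)
  foci$inside_nucleus <- lab
  per <- if (mask$n > 0L) {
    v <- tabulate(lab[lab > 0L], nbins = mask$n)
    names(v) <- seq_len(mask$n)
    v
  } else integer(0)
  list(n_nuclear = sum(lab > 0L), n_cytoplasmic = sum(lab == 0L),
       per_nucleus = per, foci = foci)
}

#' Count PLA foci inside and outside nuclei
#'
#' The full foci-counting procedure: nuclei are segmented on the DAPI
#' channel (blur + Huang threshold after background removal), foci are
#' detected on the red channel with [find_maxima()] after rolling-ball
#' background removal (optionally lightly smoothed first), and the
#' detected foci are partitioned by [count_foci()].
#'
#' @param field an [image_field()] with `dapi` and `red` channels.
#' @param noise_tolerance prominence threshold for focus detection.
#' @param rolling_radius background-removal radius for the red channel.
#' @param smooth_sigma optional Gaussian sigma applied to the red channel
#'   before maximum detection (0 disables).
#' @param nuclei_cfg a [nuclei_config()] for the DAPI channel.
#' @return list with `counts` (from [count_foci()]), `foci`, `mask`.
#' @export
quantify_pla <- function(field, noise_tolerance = 20, rolling_radius = 50,
                         smooth_sigma = 1, nuclei_cfg = nuclei_config()) {
  stopifnot(inherits(field, "image_field"),
            all(c("dapi", "red") %in% names(field$channels)))
  mask <- segment_nuclei(field$channels$dapi, nuclei_cfg)
  red <- rolling_ball_background(field$channels$red,
                                 rolling_radius)$corrected
  if (smooth_sigma > 0) red <- gaussian_blur(red, smooth_sigma)
  foci <- find_maxima(red, noise_tolerance)
  counts <- count_foci(foci, mask)
  list(counts = counts, foci = counts$foci, mask = mask)
}

#' Nuclear / cytoplasmic mean-intensity ratio per cell
#'
#' For each nucleus, the ratio of the mean (optionally
#' background-removed) signal over the nucleus to the mean over the
#' matching cytoplasmic region. Cytoplasm regions may be supplied
#' explicitly (the hand-drawn-region analogue): a list of logical
#' matrices or a single label matrix matched to nucleus labels.
#' Alternatively they are derived automatically as a dilation ring around
#' each nucleus minus all nuclei.
#'
#' @param field an [image_field()] with a `gfp` channel (or
#'   `channel` naming another one).
#' @param mask a `nucleus_mask`.
#' @param cytoplasm `NULL` (derive rings), a label matrix, or a list of
#'   logical matrices, one per nucleus label.
#' @param channel channel name to quantify.
#' @param rolling_radius background-removal radius (0 disables).
#' @param ring_width dilation ring width in pixels for derived regions.
#' @return data.frame with `cell`, `nuclear_mean`, `cytoplasmic_mean`,
#'   `ratio`.
#' @export
nc_ratio <- function(field, mask, cytoplasm = NULL, channel = "gfp",
                     rolling_radius = 0, ring_width = 6) {
  stopifnot(inherits(field, "image_field"), inherits(mask, "nucleus_mask"))
  if (!channel %in% names(field$channels)) {
    stop("channel '", channel, "' not present")
  }
  img <- field$channels[[channel]]
  if (rolling_radius > 0) {
    img <- rolling_ball_background(img, rolling_radius)$corrected
  }
  if (mask$n == 0L) {
    return(data.frame(cell = integer(0), nuclear_mean = numeric(0),
                      cytoplasmic_mean = numeric(0), ratio = numeric(0)))
  }
  cyto_masks <- vector("list", mask$n)
  if (is.null(cytoplasm)) {
    brush <- EBImage::makeBrush(2L * as.integer(ring_width) + 1L, "disc")
    any_nucleus <- mask$labels > 0L
    for (k in seq_len(mask$n)) {
      nuc <- mask$labels == k
      dil <- as.matrix(EBImage::dilate(nuc * 1, brush)) > 0.5
      cyto_masks[[k]] <- dil & !any_nucleus
    }
  } else if (is.list(cytoplasm)) {
    if (length(cytoplasm) != mask$n) stop("need one cytoplasm mask per cell")
    cyto_masks <- lapply(cytoplasm, function(m) m > 0)
  } else if (is.matrix(cytoplasm)) {
    for (k in seq_len(mask$n)) cyto_masks[[k]] <- cytoplasm == k
  } else stop("unsupported cytoplasm specification")
  rows <- lapply(seq_len(mask$n), function(k) {
    cy <- cyto_masks[[k]]
    if (!any(cy)) stop("empty cytoplasm region for cell ", k)
    cm <- mean(img[cy])
    if (cm == 0) stop("zero cytoplasmic mean for cell ", k)
    nm <- mean(img[mask$labels == k])
    data.frame(cell = k, nuclear_mean = nm, cytoplasmic_mean = cm,
               ratio = nm / cm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalise per-cell N/C ratios to a reference condition
#'
#' Divides every ratio by the median ratio of the reference condition
#' (wild type), the convention used for reporting localisation shifts.
#'
#' @param ratios numeric vector of per-cell ratios.
#' @param reference numeric vector of reference-condition ratios.
#' @param center `"median"` (default) or `"mean"` of the reference.
#' @return normalised ratios.
#' @export
normalize_nc_ratios <- function(ratios, reference,
                                center = c("median", "mean")) {
  center <- match.arg(center)
  ref <- if (center == "median") stats::median(reference) else mean(reference)
  if (!length(reference) || ref == 0) stop("invalid reference condition")
  ratios / ref
}
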