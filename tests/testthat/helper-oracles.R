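# Independent brute-force oracles used to validate the analysis
# implementations. These deliberately recompute everything from the
# definitions, avoiding the code paths they check.

# both oracles report the midpoint between the optimal split's classes,
# matching the implementations' separating-threshold convention
midpoint_of <- function(v, t) {
  hi <- v[v > t]
  if (!length(hi)) t else (t + min(hi)) / 2
}

brute_otsu <- function(v) {
  cand <- sort(unique(v))
  best <- -Inf; bt <- NA_real_
  for (t in cand) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    b <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (b > best) { best <- b; bt <- t }
  }
  midpoint_of(v, bt)
}

brute_huang <- function(v) {
  cand <- sort(unique(v))
  C <- max(v) - min(v)
  best <- Inf; bt <- NA_real_
  for (t in cand) {
    lo <- v <= t
    if (all(lo) || !any(lo)) next
    mu <- ifelse(lo, mean(v[lo]), mean(v[!lo]))
    u <- 1 / (1 + abs(v - mu) / C)
    s <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
    cost <- sum(s)
    if (cost < best) { best <- cost; bt <- t }
  }
  midpoint_of(v, bt)
}

# grayscale opening by a disc, clipped windows at the borders
brute_opening <- function(img, radius) {
  brush <- EBImage::makeBrush(2L * radius + 1L, "disc")
  off <- which(brush == 1, arr.ind = TRUE) - (radius + 1L)
  nr <- nrow(img); nc <- ncol(img)
  pass <- function(m, f) {
    out <- matrix(NA_real_, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      rr <- r + off[, 1]; cc <- c + off[, 2]
      k <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      out[r, c] <- f(m[cbind(rr[k], cc[k])])
    }
    out
  }
  pass(pass(img, min), max)
}

# prominence-definition maxima: a strict local maximum m is accepted iff
# the connected region reachable from m through pixels with value
# >= value(m) - tol contains no strictly higher pixel; the global
# maximum must additionally rise more than tol above the image minimum
brute_prominence_maxima <- function(img, tol) {
  nr <- nrow(img); nc <- ncol(img)
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs, cs] <- img[rs - dr, cs - dc]
    is_max <- is_max & img > shifted
  }
  cand <- which(is_max, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    v <- img[cand[i, 1], cand[i, 2]]
    lo <- v - tol
    seen <- matrix(FALSE, nr, nc)
    queue <- list(cand[i, ])
    seen[cand[i, 1], cand[i, 2]] <- TRUE
    ok <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (seen[r2, c2] || img[r2, c2] < lo) next
        if (img[r2, c2] > v) { ok <- FALSE; break }
        seen[r2, c2] <- TRUE
        queue[[length(queue) + 1L]] <- c(r2, c2)
      }
      if (!ok) break
    }
    if (ok && v == max(img)) ok <- v - min(img) > tol
    keep[i] <- ok
  }
  cand[keep, , drop = FALSE]
}

# smooth continuous test raster (no plateaus) on a 0..255-like scale
random_raster <- function(nr, nc, sigma = 1.5) {
  gaussian_blur(matrix(runif(nr * nc), nr, nc), sigma) * 255
}

match_foci <- function(detected, truth, max_dist = 3) {
  used <- rep(FALSE, nrow(truth)); tp <- 0L
  for (i in seq_len(nrow(detected))) {
    d <- sqrt((truth$row - detected$row[i])^2 +
                (truth$col - detected$col[i])^2)
    d[used] <- Inf
    if (length(d) && min(d) <= max_dist) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = nrow(detected) - tp, fn = nrow(truth) - tp)
}

read_all_fixtures <- function(names = NULL) {
  paths <- tale_fixture(names)
  ids <- do.call(rbind, lapply(unname(paths), parse_compact_table))
  class(ids) <- c("xlink_ids", "data.frame")
  ids
}

link_keys <- function(df) {
  swap <- df$protein_a > df$protein_b |
    (df$protein_a == df$protein_b & df$residue_a > df$residue_b)
  pa <- ifelse(swap, df$protein_b, df$protein_a)
  ra <- ifelse(swap, df$residue_b, df$residue_a)
  pb <- ifelse(swap, df$protein_a, df$protein_b)
  rb <- ifelse(swap, df$residue_a, df$residue_b)
  sort(paste(pa, ra, pb, rb, df$link_class))
}
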