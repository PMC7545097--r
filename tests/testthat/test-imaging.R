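test_that("rolling-ball background equals brute-force opening", {
  const <- matrix(50, 40, 40)
  rb <- rolling_ball_background(const, 10)
  expect_equal(rb$corrected, matrix(0, 40, 40))

  spike <- matrix(50, 64, 64); spike[20, 20] <- 250
  rb2 <- rolling_ball_background(spike, 15)
  expect_lt(max(abs(rb2$corrected - (spike - 50))), 1)

  set.seed(31)
  img <- matrix(runif(64 * 64, 0, 200), 64, 64)
  rb3 <- rolling_ball_background(img, 5)
  expect_lt(max(abs(rb3$background - brute_opening(img, 5L))), 1)
  expect_true(all(rb3$corrected >= 0))
  expect_true(all(rb3$background <= img + 1e-9))

  expect_warning(rolling_ball_background(matrix(1:9, 3, 3), 10),
                 "global minimum")
})

test_that("gaussian blur is identity at sigma 0 and conserves mass", {
  img <- matrix(runif(33 * 33), 33, 33)
  expect_identical(gaussian_blur(img, 0), img)

  delta <- matrix(0, 33, 33); delta[17, 17] <- 1
  g <- gaussian_blur(delta, 2)
  expect_lt(abs(sum(g) - 1), 1e-6)
  expect_identical(which(g == max(g)), which(delta == 1))
  # linearity
  expect_equal(gaussian_blur(3.7 * img, 2), 3.7 * gaussian_blur(img, 2))
})

test_that("Otsu threshold maximises between-class variance", {
  v <- c(rep(10, 900), rep(200, 100))
  img <- matrix(v, 25, 40)
  t1 <- threshold_otsu(img)
  expect_gt(t1, 10); expect_lt(t1, 200)

  set.seed(5)
  for (i in 1:5) {
    m <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    expect_identical(threshold_otsu(m), brute_otsu(as.vector(m)))
  }
  # shifting all intensities shifts the threshold by the same constant
  m <- matrix(sample(0:200, 32 * 32, TRUE), 32, 32)
  expect_equal(threshold_otsu(m + 17), threshold_otsu(m) + 17)
  expect_error(threshold_otsu(matrix(3, 4, 4)), "degenerate")
})

test_that("Otsu agrees with an established implementation on 8-bit data", {
  set.seed(6)
  m <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  ours <- threshold_otsu(m)
  eb <- EBImage::otsu(EBImage::Image(m / 255), range = c(0, 1),
                      levels = 256) * 255
  expect_lt(abs(ours - eb), 2)
})

test_that("Huang threshold minimises fuzzy entropy", {
  bim <- matrix(c(rep(10, 600), rep(200, 424)), 32, 32)
  th <- threshold_huang(bim)
  expect_gt(th, 10); expect_lt(th, 200)

  set.seed(8)
  for (i in 1:5) {
    m <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    expect_identical(threshold_huang(m), brute_huang(as.vector(m)))
  }
  # symmetric histogram: threshold lands at the centre bin +/- 1
  sym <- matrix(rep(c(0:10, 10:0), length.out = 900), 30, 30)
  centre <- 5
  expect_lte(abs(threshold_huang(sym) - centre), 1)
  expect_error(threshold_huang(matrix(1, 3, 3)), "degenerate")
})

test_that("find_maxima implements prominence semantics", {
  expect_identical(nrow(find_maxima(matrix(0, 64, 64), 10)), 0L)

  z <- matrix(0, 64, 64); z[32, 32] <- 1
  spot <- gaussian_blur(z, 2) * 2500   # single smooth peak, amp ~100
  fm <- find_maxima(spot, 20)
  expect_identical(nrow(fm), 1L)
  expect_identical(c(fm$row, fm$col), c(32L, 32L))

  # 7 planted spots, pairwise separation >= 15 px, low noise
  set.seed(12)
  centers <- cbind(row = c(10, 10, 32, 32, 54, 54, 32),
                   col = c(10, 54, 10, 54, 22, 54, 32))
  img <- matrix(0, 64, 64)
  img[centers] <- 1
  img <- gaussian_blur(img, 2) * 2000 +
    matrix(rnorm(64 * 64, 0, 2), 64, 64)
  fm7 <- find_maxima(img, 20)
  expect_identical(nrow(fm7), 7L)
  m <- match_foci(fm7, as.data.frame(centers), max_dist = 1)
  expect_identical(unname(m["tp"]), 7L)

  # equal-valued plateau collapses to its centre of mass
  plat <- matrix(0, 21, 21); plat[10:12, 10:12] <- 5
  fp <- find_maxima(plat, 1)
  expect_identical(nrow(fp), 1L)
  expect_identical(c(fp$row, fp$col), c(11L, 11L))
  expect_error(find_maxima(plat, 0), "noise_tolerance")
})

test_that("find_maxima equals the brute-force prominence oracle", {
  set.seed(19)
  for (i in 1:5) {
    img <- random_raster(40, 40)
    fm <- find_maxima(img, 8)
    oracle <- brute_prominence_maxima(img, 8)
    expect_identical(nrow(fm), nrow(oracle))
    got <- paste(fm$row, fm$col)
    want <- paste(oracle[, 1], oracle[, 2])
    expect_setequal(got, want)
  }
})

test_that("nucleus segmentation recovers disks with areas and labels", {
  rr <- matrix(seq_len(120), 120, 120)
  cc <- t(rr)
  disk <- function(r0, c0, rad) (rr - r0)^2 + (cc - c0)^2 <= rad^2
  dapi <- 10 + 150 * disk(60, 60, 20) +
    matrix(rnorm(120 * 120, 0, 2), 120, 120)
  # otsu splits the sharp disk edge at half height, preserving the area;
  # a light blur keeps the edge position unbiased
  mask <- segment_nuclei(pmax(dapi, 0),
                         nuclei_config(rolling_radius = 30, sigma = 1,
                                       method = "otsu"))
  expect_identical(mask$n, 1L)
  expect_lt(abs(mask$table$area - pi * 400) / (pi * 400), 0.05)

  two <- 10 + 150 * (disk(35, 35, 16) | disk(85, 85, 16))
  mask2 <- segment_nuclei(two, nuclei_config(rolling_radius = 30))
  expect_identical(mask2$n, 2L)

  blank <- matrix(5, 80, 80) + matrix(rnorm(6400, 0, 0.5), 80, 80)
  expect_warning(mask0 <- segment_nuclei(pmax(blank, 0),
                                         nuclei_config(rolling_radius = 30)),
                 "no nucleus")
  expect_identical(mask0$n, 0L)
})

test_that("foci counting partitions into nuclear and cytoplasmic", {
  lab <- matrix(0L, 50, 50); lab[20:30, 20:30] <- 1L
  mask <- structure(list(labels = lab, n = 1L, table = NULL),
                    class = "nucleus_mask")
  foci <- data.frame(row = c(22, 25, 28, 21, 29, 5, 10, 45),
                     col = c(22, 25, 28, 26, 24, 5, 40, 45),
                     value = 1)
  ct <- count_foci(foci, mask)
  expect_identical(ct$n_nuclear, 5L)
  expect_identical(ct$n_cytoplasmic, 3L)
  expect_identical(ct$n_nuclear + ct$n_cytoplasmic, nrow(foci))

  empty <- structure(list(labels = matrix(0L, 50, 50), n = 0L,
                          table = NULL), class = "nucleus_mask")
  ct0 <- count_foci(foci, empty)
  expect_identical(ct0$n_nuclear, 0L)
  expect_identical(ct0$n_cytoplasmic, nrow(foci))

  shuf <- foci[sample.int(nrow(foci)), ]
  ct2 <- count_foci(shuf, mask)
  expect_identical(ct2$n_nuclear, ct$n_nuclear)
})

test_that("N/C ratio is exact on uniform and two-level fields", {
  lab <- matrix(0L, 60, 60); lab[20:30, 20:30] <- 1L
  cyto <- matrix(0L, 60, 60); cyto[35:45, 20:30] <- 1L
  mask <- structure(list(labels = lab, n = 1L, table = NULL),
                    class = "nucleus_mask")
  uni <- image_field(list(gfp = matrix(7, 60, 60)))
  expect_equal(nc_ratio(uni, mask, cytoplasm = cyto)$ratio, 1)

  two <- matrix(25, 60, 60); two[lab == 1L] <- 100
  fld <- image_field(list(gfp = two))
  expect_equal(nc_ratio(fld, mask, cytoplasm = cyto)$ratio, 4)

  bad <- matrix(0L, 60, 60)
  expect_error(nc_ratio(fld, mask, cytoplasm = bad), "empty cytoplasm")
})

test_that("wild-type-like fields show higher median N/C ratio than
           mutant-like fields", {
  rats <- function(nm, cm, seeds) {
    unlist(lapply(seeds, function(s) {
      g <- synth_nc_image(nm, cm, noise_sd = 3, seed = s)
      mask <- structure(list(labels = g$nucleus_labels,
                             n = max(g$nucleus_labels), table = NULL),
                        class = "nucleus_mask")
      nc_ratio(g$field, mask, cytoplasm = g$cytoplasm_labels)$ratio
    }))
  }
  wt <- rats(100, 25, 1:4)     # nuclear-enriched
  mut <- rats(30, 60, 1:4)     # cytoplasm-enriched
  expect_gt(median(wt), median(mut))
  norm <- normalize_nc_ratios(mut, wt)
  expect_equal(median(normalize_nc_ratios(wt, wt)), 1)
  expect_lt(median(norm), 1)
})
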