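test_that("protein generation is reproducible with unique peptides", {
  p1 <- synth_protein_pair(seed = 3)
  p2 <- synth_protein_pair(seed = 3)
  expect_identical(p1[[1]]$sequence, p2[[1]]$sequence)
  expect_identical(p1[[2]]$sequence, p2[[2]]$sequence)
  expect_false(identical(p1[[1]]$sequence,
                         synth_protein_pair(seed = 4)[[1]]$sequence))

  # uniqueness property by exhaustive substring scan
  for (p in p1) {
    peps <- digest_in_silico(p, digest_spec(max_missed = 0L))
    long <- unique(peps$sequence[nchar(peps$sequence) >= 5L])
    hits <- vapply(long, function(s) {
      length(gregexpr(s, p$sequence, fixed = TRUE)[[1]])
    }, 0L)
    expect_true(all(hits == 1L))
  }

  nolys <- synth_protein_pair(seed = 5, n_lysines = 0)
  expect_identical(nolys[[1]]$lysines, integer(0))
  expect_error(synth_xlink_truth(nolys, n_inter = 1, n_intra = 0,
                                 n_loop = 0, n_decoys = 0),
               "no lysines")
})

test_that("planted links sit on lysines and decoys each break one rule", {
  pp <- synth_protein_pair(seed = 13)
  tr <- synth_xlink_truth(pp, n_inter = 5, n_intra = 3, n_loop = 2,
                          n_decoys = 8, seed = 13)
  for (i in seq_len(nrow(tr$true_links))) {
    l <- tr$true_links[i, ]
    expect_identical(residue_at(pp[[l$protein_a]], l$residue_a), "K")
    expect_identical(residue_at(pp[[l$protein_b]], l$residue_b), "K")
  }
  expect_identical(nrow(tr$decoys), 8L)
  expect_setequal(unique(tr$decoys$violation),
                  c("evalue", "ions", "majority", "nonlysine"))
})

test_that("curation recovers exactly the planted links (round trip)", {
  pp <- synth_protein_pair(seed = 17)
  tr <- synth_xlink_truth(pp, n_inter = 4, n_intra = 4, n_loop = 2,
                          n_decoys = 8, seed = 17)
  ds <- synth_xlink_dataset(tr)
  cur <- curate_identifications(ds)
  links <- map_and_collapse(cur$kept, pp)
  expect_identical(link_keys(links), link_keys(tr$true_links))
  # every decoy record was rejected
  expect_identical(nrow(cur$rejected), nrow(tr$decoys))

  # zero links yield an empty curated output
  tr0 <- synth_xlink_truth(pp, n_inter = 0, n_intra = 0, n_loop = 0,
                           n_decoys = 3, seed = 18)
  ds0 <- synth_xlink_dataset(tr0)
  expect_identical(nrow(curate_identifications(ds0)$kept), 0L)
})

test_that("replicate support of planted links is propagated", {
  pp <- synth_protein_pair(seed = 23)
  tr <- synth_xlink_truth(pp, n_inter = 6, n_intra = 0, n_loop = 0,
                          n_decoys = 0, seed = 23)
  ds <- synth_xlink_dataset(tr)
  links <- map_and_collapse(curate_identifications(ds)$kept, pp)
  for (i in seq_len(nrow(links))) {
    reps <- unique(links$evidence[[i]]$replicate)
    expect_identical(links$both_replicates[i], length(reps) >= 2L)
  }
})

test_that("binding-curve noise model has the requested moments", {
  clean <- synth_binding_curves(kd = 18, bmax = 2, baseline = 0.1,
                                noise_cv = 0, seed = 1)
  expect_equal(clean$signal,
               0.1 + 2 * clean$dose / (18 + clean$dose))
  # half-saturation identity at x = kd
  at_kd <- synth_binding_curves(kd = 50, bmax = 1, doses = 50,
                                noise_cv = 0, n_replicates = 1, seed = 1)
  expect_equal(at_kd$signal, 0.5)

  noisy <- synth_binding_curves(kd = 18, doses = rep(100, 1000),
                                noise_cv = 0.1, n_replicates = 1, seed = 2)
  emp_cv <- sd(noisy$signal) / mean(noisy$signal)
  expect_lt(abs(emp_cv - 0.1) / 0.1, 0.1)
  # the dose ladder spans the published range
  expect_equal(min(elisa_doses()), 500 / 3^7, tolerance = 1e-12)
  expect_equal(max(elisa_doses()), 500)
})

test_that("synthetic PLA fields are reproducible with planted truth", {
  tr <- synth_image_truth(seed = 41)
  f1 <- synth_pla_image(tr)
  f2 <- synth_pla_image(tr)
  expect_identical(f1$field$channels$red, f2$field$channels$red)
  expect_identical(f1$field$channels$dapi, f2$field$channels$dapi)
  # nuclear-flagged foci lie inside an ellipse
  for (i in which(tr$foci$nuclear)) {
    inside <- any(vapply(tr$nuclei, function(e) {
      talemap:::inside_ellipse(tr$foci$row[i], tr$foci$col[i], e)
    }, NA))
    expect_true(inside)
  }

  q <- quantify_pla(f1$field, noise_tolerance = 30)
  expect_identical(q$counts$n_nuclear, sum(tr$foci$nuclear))
  expect_identical(q$counts$n_cytoplasmic, sum(!tr$foci$nuclear))

  tr0 <- synth_image_truth(n_nuclear_foci = 0, n_cyto_foci = 0, seed = 42)
  q0 <- quantify_pla(synth_pla_image(tr0)$field, noise_tolerance = 30)
  expect_identical(q0$counts$n_nuclear, 0L)
  expect_identical(q0$counts$n_cytoplasmic, 0L)
})

test_that("synthetic N/C fields carry their planted ratio", {
  g <- synth_nc_image(100, 25, noise_sd = 0, seed = 2)
  mask <- structure(list(labels = g$nucleus_labels,
                         n = max(g$nucleus_labels), table = NULL),
                    class = "nucleus_mask")
  r <- nc_ratio(g$field, mask, cytoplasm = g$cytoplasm_labels)
  expect_equal(r$ratio, rep(4, nrow(r)))
  expect_equal(g$true_ratio, 4)

  eq <- synth_nc_image(50, 50, noise_sd = 0, seed = 3)
  mask_eq <- structure(list(labels = eq$nucleus_labels,
                            n = max(eq$nucleus_labels), table = NULL),
                       class = "nucleus_mask")
  expect_equal(nc_ratio(eq$field, mask_eq,
                        cytoplasm = eq$cytoplasm_labels)$ratio,
               rep(1, 3))

  # with noise the measured ratio stays within 5 % over repeated fields
  meas <- vapply(1:20, function(s) {
    g <- synth_nc_image(100, 25, noise_sd = 5, seed = s)
    m <- structure(list(labels = g$nucleus_labels,
                        n = max(g$nucleus_labels), table = NULL),
                   class = "nucleus_mask")
    mean(nc_ratio(g$field, m, cytoplasm = g$cytoplasm_labels)$ratio)
  }, 0)
  expect_lt(abs(mean(meas) - 4) / 4, 0.05)
})
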