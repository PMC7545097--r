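test_that("compact notation parses peptide pairs and looped peptides", {
  ids <- parse_compact_table(tale_fixture("prep1_pbx1_inter"))
  # first row: KTVLSIR(1)-SQTPMDVDKQAIYR(9), claimed residues 87/55,
  # observed in both replicates (expanded to one record each)
  first <- ids[ids$peptide_a == "KTVLSIR" &
                 ids$peptide_b == "SQTPMDVDKQAIYR", ]
  expect_identical(nrow(first), 2L)
  expect_identical(first$pos_a[1], 1L)
  expect_identical(first$pos_b[1], 9L)
  expect_identical(first$residue_a[1], 87L)
  expect_identical(first$residue_b[1], 55L)
  expect_setequal(first$replicate, c("R1", "R2"))

  loops <- parse_compact_table(tale_fixture("prep1_pbx1_loop"))
  lp <- loops[loops$peptide_a == "IKEKTVLSIR", ]
  expect_true(is.na(lp$peptide_b))
  expect_identical(c(lp$pos_a, lp$pos_b), c(2L, 4L))
  expect_identical(c(lp$residue_a, lp$residue_b), c(85L, 87L))

  hdr_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("link\tpeptides", hdr_only)
  expect_identical(nrow(parse_compact_table(hdr_only)), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("link\tpeptides", "PBX1(87)-PREP1(55)\tKTVLSIR1-LEKVNE(3)"),
             bad)
  expect_error(parse_compact_table(bad), "line 2")
})

test_that("delimited exports are read through a configurable dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Peptide1,LinkPos1,Peptide2,LinkPos2,Prot1,Prot2,Evalue",
               "KTVLSIR,1,LEKVNE,3,PBX1,PREP1,2e-05"), f)
  dia <- plink_dialect(peptide_a = "Peptide1", pos_a = "LinkPos1",
                       peptide_b = "Peptide2", pos_b = "LinkPos2",
                       protein_a = "Prot1", protein_b = "Prot2",
                       evalue = "Evalue", sep = ",")
  ids <- parse_plink_table(f, dia)
  expect_identical(ids$peptide_b, "LEKVNE")
  expect_identical(ids$evalue, 2e-05)
  expect_error(parse_plink_table(f, plink_dialect(sep = ",")),
               "missing required column")
})

test_that("curation applies the E-value, ion-run, majority and lysine rules", {
  base <- list(peptide_a = "KTVLSIR", pos_a = 1L, peptide_b = "LEKVNE",
               pos_b = 3L, protein_a = "PBX1", protein_b = "PREP1",
               n_peaks_total = 40L)
  mk <- function(...) do.call(xlink_ids, utils::modifyList(base, list(...)))

  good <- mk(evalue = 5e-4, ions_y_a = "2,3,4,5", ions_y_b = "1,2,3,4",
             n_peaks_assigned = 24L)  # 60 % assigned
  res <- curate_identifications(good)
  expect_identical(nrow(res$kept), 1L)
  expect_identical(res$kept$curation, "pass")

  high_e <- mk(evalue = 0.002, ions_y_a = "1,2,3,4,5,6",
               ions_y_b = "1,2,3,4,5", n_peaks_assigned = 35L)
  expect_identical(curate_identifications(high_e)$rejected$reason, "evalue")
  # the threshold is strict
  at_e <- mk(evalue = 0.001, ions_y_a = "1,2,3,4", ions_y_b = "1,2,3,4",
             n_peaks_assigned = 35L)
  expect_identical(curate_identifications(at_e)$rejected$reason, "evalue")

  broken_run <- mk(evalue = 5e-4, ions_y_a = "1,2,4,5",
                   ions_y_b = "1,2,3,4", n_peaks_assigned = 30L)
  expect_identical(curate_identifications(broken_run)$rejected$reason,
                   "consecutive-ions")
  # b and y series are considered independently; a 4-run in b rescues
  b_run <- mk(evalue = 5e-4, ions_y_a = "1,2,4,5", ions_b_a = "3,4,5,6",
              ions_y_b = "1,2,3,4", n_peaks_assigned = 30L)
  expect_identical(nrow(curate_identifications(b_run)$kept), 1L)

  half <- mk(evalue = 5e-4, ions_y_a = "1,2,3,4", ions_y_b = "1,2,3,4",
             n_peaks_assigned = 20L)  # exactly 0.5: strict majority fails
  expect_identical(curate_identifications(half)$rejected$reason,
                   "majority-assigned")

  non_k <- mk(pos_a = 2L, evalue = 5e-4, ions_y_a = "1,2,3,4",
              ions_y_b = "1,2,3,4", n_peaks_assigned = 30L)
  expect_identical(curate_identifications(non_k)$rejected$reason,
                   "site-not-lysine")
  # N-terminal alpha-amine link at position 1 behind the flag
  nterm <- mk(peptide_a = "TVLSIR", pos_a = 1L, evalue = 5e-4,
              ions_y_a = "1,2,3,4", ions_y_b = "1,2,3,4",
              n_peaks_assigned = 30L)
  expect_identical(curate_identifications(nterm)$rejected$reason,
                   "site-not-lysine")
  expect_identical(
    nrow(curate_identifications(nterm, allow_nterm = TRUE)$kept), 1L)

  bare <- mk(evalue = 5e-4)
  expect_identical(curate_identifications(bare)$rejected$reason,
                   "no-ion-annotation")
  perm <- curate_identifications(bare, permissive = TRUE)
  expect_identical(perm$kept$curation, "uncurated")
})

test_that("longest consecutive ion run matches an exhaustive scan", {
  set.seed(42)
  scan_run <- function(v) {
    v <- sort(unique(v))
    best <- 0L
    for (i in seq_along(v)) {
      j <- i
      while (j < length(v) && v[j + 1L] == v[j] + 1L) j <- j + 1L
      best <- max(best, j - i + 1L)
    }
    best
  }
  for (rep in 1:50) {
    v <- sample.int(20, sample.int(12, 1))
    ids <- xlink_ids(peptide_a = strrep("K", 25), pos_a = 1L,
                     peptide_b = "KAAAA", pos_b = 1L,
                     protein_a = "A", protein_b = "B", evalue = 1e-5,
                     ions_y_a = paste(v, collapse = ","),
                     ions_y_b = "1,2,3,4",
                     n_peaks_total = 10L, n_peaks_assigned = 9L)
    kept <- nrow(curate_identifications(ids)$kept) == 1L
    expect_identical(kept, scan_run(v) >= 4L)
  }
})

test_that("mapping converts in-peptide positions to absolute residues", {
  prots <- tale_scaffold_proteins()
  ids <- parse_compact_table(tale_fixture("prep1_pbx1_inter"))
  mapped <- map_to_residues(ids, prots)
  expect_identical(mapped$start_a[mapped$peptide_a == "KTVLSIR"][1], 87L)
  expect_identical(mapped$residue_a[mapped$peptide_a == "KTVLSIR"][1], 87L)

  loops <- map_to_residues(parse_compact_table(tale_fixture("prep1_pbx1_loop")),
                           prots)
  lp <- loops[loops$peptide_a == "IKEKTVLSIR", ]
  expect_identical(lp$start_a, 84L)
  expect_identical(c(lp$residue_a, lp$residue_b), c(85L, 87L))

  # position 1 of a peptide at protein start maps to residue 1
  p <- protein_record("P", "KVLSAAAR")
  one <- map_to_residues(xlink_ids(peptide_a = "KVLSAAAR", pos_a = 1L,
                                   peptide_b = "KAAA", pos_b = 1L,
                                   protein_a = "P", protein_b = "Q"),
                         list(P = p, Q = protein_record("Q", "KAAAR")))
  expect_identical(one$residue_a, 1L)

  # claimed/computed mismatch and missing peptide are errors
  wrong <- xlink_ids(peptide_a = "KTVLSIR", pos_a = 1L, peptide_b = "LEKVNE",
                     pos_b = 3L, protein_a = "PBX1", protein_b = "PREP1",
                     residue_a = 90L)
  expect_error(map_to_residues(wrong, prots), "incompatible|!= computed")
  absent <- xlink_ids(peptide_a = "WWWWW", pos_a = 1L, peptide_b = "LEKVNE",
                      pos_b = 3L, protein_a = "PBX1", protein_b = "PREP1")
  expect_error(map_to_residues(absent, prots), "not found")
})

test_that("ambiguous peptide occurrences need a claimed residue", {
  p <- protein_record("R", "AAKRGGAAKR")   # AAKR occurs at 1 and 7
  amb <- xlink_ids(peptide_a = "AAKR", pos_a = 3L, peptide_b = "KAA",
                   pos_b = 1L, protein_a = "R", protein_b = "S")
  prots <- list(R = p, S = protein_record("S", "KAAG"))
  expect_error(map_to_residues(amb, prots), "offsets")
  amb$residue_a <- 9L   # second occurrence
  got <- map_to_residues(amb, prots)
  expect_identical(got$start_a, 7L)
})

test_that("offset audit is consistent on fixtures and flags fabrications", {
  ids <- read_all_fixtures()
  audit <- infer_peptide_offsets(ids)
  expect_identical(nrow(audit$contradictions), 0L)
  off <- audit$offsets
  expect_identical(off$start[off$peptide == "KTVLSIR" &
                               off$protein == "PBX1"], 87L)
  expect_identical(off$start[off$peptide == "IKEKTVLSIR" &
                               off$protein == "PBX1"], 84L)

  fab <- xlink_ids(peptide_a = "KTVLSIR", pos_a = 1L, peptide_b = "LEKVNE",
                   pos_b = 3L, protein_a = "PBX1", protein_b = "PREP1",
                   residue_a = 90L, residue_b = 134L)
  audit2 <- infer_peptide_offsets(rbind(ids, fab))
  expect_identical(audit2$contradictions$peptide, "KTVLSIR")
  expect_identical(audit2$contradictions$starts, "87;90")
})

test_that("classification is exhaustive and collapse canonicalises", {
  two <- xlink_ids(peptide_a = c("AKLSQIR", "AKLSQIR"), pos_a = 2L,
                   peptide_b = "GVLPKHATNVMR", pos_b = 5L,
                   protein_a = "PBX1", protein_b = "PREP1",
                   residue_a = 153L, residue_b = 268L,
                   evalue = c(1e-5, 5e-6), replicate = c("R1", "R2"))
  two <- classify_links(two)
  expect_identical(two$link_class, c("inter", "inter"))
  links <- collapse_redundant(two)
  expect_identical(nrow(links), 1L)
  expect_identical(links$n_evidence, 2L)
  expect_identical(links$best_evalue, 5e-6)

  # symmetric duplicate collapses onto one canonical link
  sym <- xlink_ids(peptide_a = c("KTVLSIR", "SQTPMDVDKQAIYR"),
                   pos_a = c(1L, 9L),
                   peptide_b = c("SQTPMDVDKQAIYR", "KTVLSIR"),
                   pos_b = c(9L, 1L),
                   protein_a = c("PBX1", "PREP1"),
                   protein_b = c("PREP1", "PBX1"),
                   residue_a = c(87L, 55L), residue_b = c(55L, 87L))
  expect_identical(nrow(collapse_redundant(classify_links(sym))), 1L)

  # classes partition the non-redundant links
  ids <- classify_links(map_to_residues(read_all_fixtures(),
                                        tale_scaffold_proteins()))
  links_all <- collapse_redundant(ids)
  expect_identical(sum(links_all$link_class == "inter") +
                     sum(links_all$link_class == "intra") +
                     sum(links_all$link_class == "loop"),
                   nrow(links_all))
  # permutation invariance of the collapsed set
  shuf <- ids[sample.int(nrow(ids)), ]
  expect_identical(link_keys(collapse_redundant(shuf)),
                   link_keys(links_all))
})

test_that("replicate aggregation is a monotone set union", {
  mk <- function(reps) {
    ids <- xlink_ids(peptide_a = rep("AKLSQIR", length(reps)), pos_a = 2L,
                     peptide_b = "GVLPKHATNVMR", pos_b = 5L,
                     protein_a = "PBX1", protein_b = "PREP1",
                     residue_a = 153L, residue_b = 268L, replicate = reps)
    aggregate_replicates(collapse_redundant(classify_links(ids)))
  }
  expect_true(mk(c("R1", "R2"))$both_replicates)
  expect_false(mk("R1")$both_replicates)
  expect_false(mk(c("R1", "R1"))$both_replicates)
  # merging two single-replicate evidence sets turns the flag on
  expect_true(mk(c("R1", "R1", "R2"))$both_replicates)
})
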