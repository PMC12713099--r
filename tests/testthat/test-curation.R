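toy_table <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      `Compound ID` = c("CPD1", "CPD2", "CPD3"),
      Smiles = c("CCO", "c1ccccc1", "CCN"),
      Uniprot = c("P1", "P2", "P1"),
      `E3 ligase Uniprot` = c("E1", "E1", "E2"),
      `DC50 (nM)` = c(10, NA, 1000),
      `Dmax (%)` = c(90, NA, 20),
      `Assay (DC50/Dmax)` = c("", "DC50 = 50 nM; Dmax of 85%", ""),
      check.names = FALSE)
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

test_that("table parsing keeps duplicates and validates columns", {
  path <- toy_table(withr::local_tempfile(fileext = ".csv"))
  rec <- parse_protac_table(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$dc50_nM, c(10, NA, 1000))
  expect_match(rec$assay_text[2], "DC50 = 50 nM")

  # duplicate compound under two assays stays two records
  dup <- data.frame(Smiles = c("CCO", "CCO"), Uniprot = "P1",
                    `E3 ligase Uniprot` = "E1",
                    `Compound ID` = "CPD1", check.names = FALSE)
  rec2 <- parse_protac_table(toy_table(withr::local_tempfile(fileext = ".csv"),
                                       dup))
  expect_equal(nrow(rec2), 2L)
  expect_equal(rec2$compound_id, c("CPD1", "CPD1"))

  # missing mandatory column
  bad <- data.frame(Uniprot = "P1", `E3 ligase Uniprot` = "E1",
                    check.names = FALSE)
  expect_error(
    parse_protac_table(toy_table(withr::local_tempfile(fileext = ".csv"),
                                 bad)),
    "smiles")

  # row lacking SMILES is rejected with its row number
  holey <- data.frame(Smiles = c("CCO", ""), Uniprot = "P1",
                      `E3 ligase Uniprot` = "E1", check.names = FALSE)
  expect_error(
    parse_protac_table(toy_table(withr::local_tempfile(fileext = ".csv"),
                                 holey)),
    "2")
})

test_that("implicit extraction handles units, order and qualitative phrases", {
  expect_equal(extract_implicit_values("DC50 = 50 nM")$dc50_nM, 50)
  both <- extract_implicit_values("0.1 uM DC50; Dmax of 85%")
  expect_equal(both$dc50_nM, 100)         # 0.1 uM -> 100 nM
  expect_equal(both$dmax_pct, 85)
  micro <- extract_implicit_values("DC50 of 2.5 µM")
  expect_equal(micro$dc50_nM, 2500)
  plain_m <- extract_implicit_values("DC50 of 0.000001 M")
  expect_equal(plain_m$dc50_nM, 1000)
  pico <- extract_implicit_values("DC50 = 500 pM")
  expect_equal(pico$dc50_nM, 0.5)
  pct <- extract_implicit_values("about 85% degradation at 1 uM")
  expect_equal(pct$dmax_pct, 85)

  none <- extract_implicit_values("no degradation observed")
  expect_true(is.na(none$dc50_nM))
  expect_true(none$low_activity)

  silent <- extract_implicit_values("cells were treated for 24 h")
  expect_true(is.na(silent$dc50_nM) && is.na(silent$dmax_pct) &&
                !silent$low_activity)
})

test_that("tiered labeling follows the thresholds and evidence precedence", {
  lab <- function(dc50 = NA, dmax = NA, text = "") {
    assign_label(list(dc50_nM = dc50, dmax_pct = dmax, assay_text = text))
  }
  expect_equal(as.integer(lab(10, 90)), 1L)
  expect_equal(as.integer(lab(1000, 20)), 0L)
  expect_identical(lab(), "excluded")
  expect_identical(lab(50, 65), "excluded")        # gray zone
  expect_equal(as.integer(lab(10)), 1L)            # missing dmax non-blocking
  expect_equal(as.integer(lab(NA, 90)), 1L)
  expect_equal(as.integer(lab(200, 90)), 0L)       # dc50 over cutoff wins
  # implicit evidence applies the same cutoffs
  expect_equal(as.integer(lab(text = "DC50 = 5 nM, Dmax = 95%")), 1L)
  expect_equal(as.integer(lab(text = "no degradation observed")), 0L)
  # explicit values shadow contradictory text
  expect_equal(as.integer(lab(10, 90, "no degradation observed")), 1L)
})

test_that("labeling is total and partitions labeled records", {
  ds <- generate_dataset(80, seed = 3)
  lab <- curate_records(ds$records)
  expect_true(all(lab$label %in% c(0L, 1L)))
  expect_equal(sum(lab$label == 1L) + sum(lab$label == 0L), nrow(lab))
  # deterministic
  expect_identical(lab, curate_records(ds$records))
})

test_that("tanimoto similarity matches set arithmetic and endpoints", {
  expect_equal(tanimoto_bits(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto_bits(c(1, 2), c(5, 6)), 0)
  expect_equal(tanimoto_bits(integer(0), integer(0)), 1)
  expect_equal(tanimoto_similarity("CCO", "CCO"), 1)
  expect_gt(tanimoto_similarity("CCOCC", "CCOCCC"), 0.3)
  expect_lt(tanimoto_similarity("CCCCC", "c1ccncc1"), 0.5)
})

test_that("alignment similarity matches dynamic-programming expectations", {
  expect_equal(nw_similarity("MKVLAW", "MKVLAW"), 1)
  expect_equal(nw_similarity("AAAA", "TTTT"), 0)
  expect_equal(nw_similarity("ACGT", "ACTT"), 0.75)
  expect_error(nw_similarity("", "AAAA"), "non-empty")
})

test_that("SMILES-based split never shares a canonical molecule", {
  ds <- generate_dataset(60, seed = 5)
  lab <- curate_records(ds$records)
  sp <- split_smiles_based(lab, seed = 4)
  expect_length(intersect(sp$train$canonical_smiles,
                          sp$test$canonical_smiles), 0L)
  # deterministic under the same seed
  sp2 <- split_smiles_based(lab, seed = 4)
  expect_identical(sp$train$compound_id, sp2$train$compound_id)
  expect_identical(sp$test$compound_id, sp2$test$compound_id)
  # every record lands in exactly one split (dropped leaks excluded)
  expect_lte(nrow(sp$train) + nrow(sp$test), nrow(lab))
  expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0L)

  # toy set with a molecule repeated 4 times never straddles the splits
  toy <- lab[1:10, ]
  toy$smiles[1:4] <- toy$smiles[1]
  toy$compound_id <- sprintf("T%02d", 1:10)
  for (seed in 1:5) {
    sp3 <- split_smiles_based(toy, seed = seed)
    shared <- intersect(sp3$train$canonical_smiles,
                        sp3$test$canonical_smiles)
    expect_length(shared, 0L)
  }
})

test_that("similarity-based split removes near-duplicate evaluation records", {
  ds <- generate_dataset(40, seed = 8)
  lab <- curate_records(ds$records)
  sp <- split_similarity_based(lab, ds$sequences, seed = 2)
  expect_lte(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(lab))
  # exact duplicates across splits are always removed (similarity 1 >= 0.9)
  for (part in c("val", "test")) {
    dup <- sp[[part]]$canonical_smiles %in% sp$train$canonical_smiles
    same_poi <- sp[[part]]$poi_uniprot[dup] %in% sp$train$poi_uniprot
    # any record left in val/test with a train-duplicate molecule must
    # differ in at least one protein beyond the threshold
    if (any(dup)) {
      for (i in which(dup)) {
        match_rows <- which(sp$train$canonical_smiles ==
                              sp[[part]]$canonical_smiles[i])
        for (j in match_rows) {
          same_triplet <- sp$train$poi_uniprot[j] ==
            sp[[part]]$poi_uniprot[i] &&
            sp$train$e3_uniprot[j] == sp[[part]]$e3_uniprot[i]
          expect_false(same_triplet)
        }
      }
    }
  }
})

test_that("threshold 1 reduces the similarity split to exact-triplet dedup", {
  ds <- generate_dataset(30, seed = 12)
  lab <- curate_records(ds$records)
  sp <- split_similarity_based(lab, ds$sequences, threshold = 1, seed = 3)
  key <- function(df) paste(df$canonical_smiles, df$poi_uniprot,
                            df$e3_uniprot)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_length(intersect(key(sp$train), key(sp$val)), 0L)
})
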