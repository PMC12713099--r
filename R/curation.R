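# PROTAC-DB-style table curation: parsing, rule-based extraction of DC50 /
# Dmax from free-text assay descriptions, tiered activity labeling, and
# leakage-safe train/test splitting by molecular fingerprint and protein
# sequence similarity.

.norm_colname <- function(x) {
  gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
}

# Accepted column-name spellings (normalized) for each record field
.COLUMN_ALIASES <- list(
  compound_id = c("compound_id", "compound", "id"),
  smiles = c("smiles"),
  poi_uniprot = c("poi_uniprot", "uniprot", "target_uniprot", "poi"),
  e3_uniprot = c("e3_uniprot", "e3_ligase_uniprot", "e3_ligase", "e3"),
  dc50_nM = c("dc50_nm", "dc50_nm_", "dc50"),
  dmax_pct = c("dmax_pct", "dmax_", "dmax")
)

.find_column <- function(norm_names, aliases) {
  hit <- which(norm_names %in% aliases)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Parse a PROTAC table into degradation records
#'
#' The PROTAC table must carry a SMILES column and POI / E3 UniProt columns
#' (several PROTAC-DB column spellings are accepted; see README). Optional
#' DC50 (nM) and Dmax (%) columns are read when present; every column whose
#' name contains "assay" or "degradation" is collected as free assay text.
#' Rows lacking a SMILES are rejected with their row number. Duplicate
#' compounds (same molecule under different assays) stay distinct records.
#'
#' @param protac_csv path to the PROTAC CSV/TSV table.
#' @param warhead_csv,linker_csv,e3ligand_csv optional companion tables,
#'   currently carried through as attributes only.
#' @param sep field separator (default auto: "," for .csv, tab otherwise).
#' @return data.frame of class `degradation_records` with columns
#'   compound_id, smiles, poi_uniprot, e3_uniprot, dc50_nM, dmax_pct,
#'   assay_text, label (NA), label_source ("unlabeled").
#' @export
parse_protac_table <- function(protac_csv, warhead_csv = NULL,
                               linker_csv = NULL, e3ligand_csv = NULL,
                               sep = NULL) {
  if (!file.exists(protac_csv)) {
    stop("PROTAC table not found: ", protac_csv, call. = FALSE)
  }
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", protac_csv)) "\t" else ","
  df <- utils::read.table(protac_csv, sep = sep, header = TRUE,
                          check.names = FALSE, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  norm <- .norm_colname(names(df))
  cols <- lapply(.COLUMN_ALIASES, .find_column, norm_names = norm)
  for (mandatory in c("smiles", "poi_uniprot", "e3_uniprot")) {
    if (is.na(cols[[mandatory]])) {
      stop("mandatory column missing from ", protac_csv, ": ", mandatory,
           call. = FALSE)
    }
  }
  smiles <- trimws(as.character(df[[cols$smiles]]))
  bad <- which(is.na(smiles) | !nzchar(smiles))
  if (length(bad) > 0L) {
    stop("row(s) lacking SMILES: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  assay_cols <- which(grepl("assay|degradation", norm) &
                        !(seq_along(norm) %in% unlist(cols)))
  assay_text <- if (length(assay_cols) > 0L) {
    apply(df[, assay_cols, drop = FALSE], 1L, function(r) {
      r <- r[!is.na(r) & nzchar(trimws(r))]
      paste(r, collapse = " ; ")
    })
  } else rep("", nrow(df))
  num_or_na <- function(col) {
    if (is.na(col)) rep(NA_real_, nrow(df))
    else suppressWarnings(as.numeric(df[[col]]))
  }
  out <- data.frame(
    compound_id = if (is.na(cols$compound_id)) {
      sprintf("row%04d", seq_len(nrow(df)))
    } else as.character(df[[cols$compound_id]]),
    smiles = smiles,
    poi_uniprot = as.character(df[[cols$poi_uniprot]]),
    e3_uniprot = as.character(df[[cols$e3_uniprot]]),
    dc50_nM = num_or_na(cols$dc50_nM),
    dmax_pct = num_or_na(cols$dmax_pct),
    assay_text = assay_text,
    label = NA_integer_,
    label_source = "unlabeled",
    stringsAsFactors = FALSE)
  class(out) <- c("degradation_records", "data.frame")
  out
}

.UNIT_TO_NM <- c(pm = 1e-3, nm = 1, um = 1e3, mm = 1e6, m = 1e9)

.norm_unit <- function(u) {
  u <- gsub("µ|μ", "u", u)   # micro signs -> u
  tolower(u)
}

#' Extract implicit DC50 / Dmax values from assay text
#'
#' Rule-based extraction: numeric DC50 values with a concentration unit
#' (pM/nM/uM/mM/M, converted to nM) in either "DC50 = 50 nM" or
#' "0.1 uM DC50" order, and Dmax or "X% degradation" percentages. Phrases
#' like "no degradation" count as low-activity evidence without a numeric
#' value. Explicit table values always take precedence upstream. Total on all
#' strings; returns missing values on no match.
#'
#' @param assay_texts character vector of free-text descriptions for one
#'   record (concatenated before matching).
#' @return list(dc50_nM, dmax_pct, low_activity).
#' @export
extract_implicit_values <- function(assay_texts) {
  text <- paste(assay_texts[!is.na(assay_texts)], collapse = " ; ")
  num <- "([0-9]+\\.?[0-9]*)"
  unit <- "(p[Mm]|n[Mm]|[uµμ][Mm]|m[Mm]|[Mm])"
  dc50 <- NA_real_
  m <- regmatches(text, regexec(
    paste0("DC50[^0-9<>=~]*[=:~<of ismeasured]*\\s*", num, "\\s*", unit,
           "\\b"), text, ignore.case = TRUE))[[1]]
  if (length(m) == 3L) {
    dc50 <- as.numeric(m[2]) * .UNIT_TO_NM[[.norm_unit(m[3])]]
  } else {
    m <- regmatches(text, regexec(
      paste0(num, "\\s*", unit, "\\s*DC50"), text,
      ignore.case = TRUE))[[1]]
    if (length(m) == 3L) {
      dc50 <- as.numeric(m[2]) * .UNIT_TO_NM[[.norm_unit(m[3])]]
    }
  }
  dmax <- NA_real_
  m <- regmatches(text, regexec(
    paste0("Dmax[^0-9]*", num, "\\s*%?"), text, ignore.case = TRUE))[[1]]
  if (length(m) == 2L) {
    dmax <- as.numeric(m[2])
  } else {
    m <- regmatches(text, regexec(
      paste0(num, "\\s*%\\s*(of\\s+)?(protein\\s+)?degradation"), text,
      ignore.case = TRUE))[[1]]
    if (length(m) >= 2L) dmax <- as.numeric(m[2])
  }
  low <- grepl("no\\s+(significant\\s+)?degradation|not\\s+degraded|inactive",
               text, ignore.case = TRUE)
  list(dc50_nM = dc50, dmax_pct = dmax, low_activity = low)
}

#' Default labeling thresholds
#'
#' DC50 at most 100 nM together with Dmax at least 80% marks high activity;
#' DC50 above 100 nM or Dmax below 50% marks low activity; the gray zone in
#' between is excluded. Fully configurable.
#'
#' @export
ptan_label_thresholds <- function() {
  list(dc50_max_nM = 100, dmax_min_pct = 80, dmax_low_pct = 50)
}

#' Assign a degradation label to one record
#'
#' Tiered rule: explicit DC50/Dmax values are consulted first; when both are
#' absent, values extracted from the assay text (and qualitative low-activity
#' statements) are applied with the same cutoffs. A missing value never
#' blocks the other criterion. Returns "excluded" when no decision is
#' possible.
#'
#' @param record one-row data.frame (or list) with dc50_nM, dmax_pct,
#'   assay_text.
#' @param thresholds see [ptan_label_thresholds()].
#' @return 1, 0, or the string "excluded".
#' @export
assign_label <- function(record, thresholds = ptan_label_thresholds()) {
  dc50 <- record$dc50_nM
  dmax <- record$dmax_pct
  low_evidence <- FALSE
  source <- "explicit"
  if ((is.null(dc50) || is.na(dc50)) && (is.null(dmax) || is.na(dmax))) {
    imp <- extract_implicit_values(record$assay_text)
    dc50 <- imp$dc50_nM
    dmax <- imp$dmax_pct
    low_evidence <- imp$low_activity
    source <- "implicit"
  }
  have_dc50 <- !is.null(dc50) && !is.na(dc50)
  have_dmax <- !is.null(dmax) && !is.na(dmax)
  if (!have_dc50 && !have_dmax) {
    return(if (low_evidence) structure(0L, source = source) else "excluded")
  }
  if ((have_dc50 && dc50 > thresholds$dc50_max_nM) ||
      (have_dmax && dmax < thresholds$dmax_low_pct) || low_evidence) {
    return(structure(0L, source = source))
  }
  if ((!have_dc50 || dc50 <= thresholds$dc50_max_nM) &&
      (!have_dmax || dmax >= thresholds$dmax_min_pct)) {
    return(structure(1L, source = source))
  }
  "excluded"
}

#' Label every record of a parsed table
#'
#' @param records a `degradation_records` data.frame.
#' @param thresholds see [ptan_label_thresholds()].
#' @param drop_excluded drop records with no usable evidence (default TRUE).
#' @return the records with label and label_source filled in.
#' @export
curate_records <- function(records, thresholds = ptan_label_thresholds(),
                           drop_excluded = TRUE) {
  labels <- integer(nrow(records))
  sources <- character(nrow(records))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    res <- assign_label(records[i, , drop = FALSE], thresholds)
    if (identical(res, "excluded")) {
      keep[i] <- FALSE
      labels[i] <- NA_integer_
      sources[i] <- "unlabeled"
    } else {
      keep[i] <- TRUE
      labels[i] <- as.integer(res)
      sources[i] <- attr(res, "source")
    }
  }
  records$label <- labels
  records$label_source <- sources
  if (drop_excluded) records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  records
}

# ---- similarities ----------------------------------------------------------

.fingerprint_bits <- function(smiles, fp_type = "FP2") {
  key <- paste0("fp::", fp_type, "::", smiles)
  cached <- .ptan_env[[key]]
  if (!is.null(cached)) return(cached)
  .parse_smiles(smiles)   # syntax validation + cache warm-up
  fp <- ChemmineOB::forEachMol("SMILES", smiles, function(m) {
    ChemmineOB::fingerprint_OB(list(m), fp_type)
  })
  bits <- which(as.numeric(unlist(fp)) != 0)
  .ptan_env[[key]] <- bits
  bits
}

#' Tanimoto similarity of two molecules
#'
#' |A&B| / |A|B| on binary fingerprints (OpenBabel FP2 path fingerprints,
#' 1024 bits, by default). Two empty fingerprints count as similarity 1.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @param fp_type OpenBabel fingerprint name (default "FP2").
#' @return similarity in [0, 1].
#' @export
tanimoto_similarity <- function(smiles_a, smiles_b, fp_type = "FP2") {
  a <- .fingerprint_bits(smiles_a, fp_type)
  b <- .fingerprint_bits(smiles_b, fp_type)
  tanimoto_bits(a, b)
}

#' Tanimoto coefficient of two bit sets
#'
#' @param a,b integer vectors of on-bit indices.
#' @return |intersection| / |union|; 1 when both are empty.
#' @export
tanimoto_bits <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Global-alignment sequence similarity (Needleman-Wunsch)
#'
#' Global alignment under an identity substitution matrix (+1 match,
#' 0 mismatch) with gap penalty 1 by default (BLOSUM62 selectable);
#' similarity is identical aligned positions divided by alignment length.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param substitution "identity" (default) or a Biostrings matrix name such
#'   as "BLOSUM62".
#' @param gap linear gap penalty (default 1).
#' @return similarity in [0, 1].
#' @export
nw_similarity <- function(seq_a, seq_b, substitution = "identity", gap = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  sub <- if (identical(substitution, "identity")) {
    letters_all <- c(LETTERS, "*")
    m <- diag(1, length(letters_all))
    dimnames(m) <- list(letters_all, letters_all)
    m
  } else substitution
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = sub,
    gapOpening = gap, gapExtension = gap)
  as.numeric(Biostrings::nmatch(pa)) /
    nchar(as.character(Biostrings::alignedPattern(pa)))
}

# ---- splits ----------------------------------------------------------------

#' SMILES-based leakage-safe train/test split
#'
#' Random split at the given ratio, after which every test record whose
#' canonical PROTAC SMILES also occurs in the training split is moved out of
#' the test set (dropped), so no molecule straddles the two splits.
#'
#' @param records labeled `degradation_records`.
#' @param ratio training fraction (default 0.8).
#' @param seed integer seed.
#' @return list(train, test) of data.frames; canonical SMILES in column
#'   `canonical_smiles`.
#' @export
split_smiles_based <- function(records, ratio = 0.8, seed = 1L) {
  n <- nrow(records)
  records$canonical_smiles <- canonical_smiles(records$smiles)
  .with_local_rng(seed, {
    idx <- sample.int(n)
    n_train <- round(ratio * n)
    train <- records[sort(idx[seq_len(n_train)]), , drop = FALSE]
    test <- records[sort(idx[-seq_len(n_train)]), , drop = FALSE]
    test <- test[!(test$canonical_smiles %in% train$canonical_smiles), ,
                 drop = FALSE]
    rownames(train) <- rownames(test) <- NULL
    list(train = train, test = test)
  })
}

#' Similarity-based leakage-safe train/val/test split
#'
#' Random split at the given ratios, after which any validation/test record
#' similar to some training record — PROTAC Tanimoto similarity, POI
#' sequence similarity AND E3 sequence similarity all at or above the
#' threshold — is removed from its evaluation split.
#'
#' @param records labeled `degradation_records`.
#' @param sequences named character vector / AAStringSet covering every
#'   accession.
#' @param ratios train/val/test fractions summing to 1 (default .8/.1/.1).
#' @param threshold similarity threshold (default 0.9).
#' @param seed integer seed.
#' @param fp_type fingerprint for the Tanimoto term (default "FP2").
#' @return list(train, val, test).
#' @export
split_similarity_based <- function(records, sequences,
                                   ratios = c(0.8, 0.1, 0.1),
                                   threshold = 0.9, seed = 1L,
                                   fp_type = "FP2") {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, threshold > 0, threshold <= 1)
  seq_map <- .as_record_list(sequences)
  n <- nrow(records)
  records$canonical_smiles <- canonical_smiles(records$smiles)
  parts <- .with_local_rng(seed, {
    idx <- sample.int(n)
    n_train <- round(ratios[1L] * n)
    n_val <- round(ratios[2L] * n)
    test_idx <- if (n_train + n_val < n) idx[seq.int(n_train + n_val + 1L, n)]
                else integer(0)
    list(train = records[sort(idx[seq_len(n_train)]), , drop = FALSE],
         val = records[sort(idx[n_train + seq_len(n_val)]), , drop = FALSE],
         test = records[sort(test_idx), , drop = FALSE])
  })
  seq_of <- function(id) seq_map[[id]]$sequence
  prot_cache <- new.env(parent = emptyenv())
  prot_sim <- function(a, b) {
    if (a == b) return(1)
    key <- paste(sort(c(a, b)), collapse = "|")
    v <- prot_cache[[key]]
    if (is.null(v)) {
      v <- nw_similarity(seq_of(a), seq_of(b))
      prot_cache[[key]] <- v
    }
    v
  }
  train <- parts$train
  leaks <- function(part) {
    if (nrow(part) == 0L) return(logical(0))
    vapply(seq_len(nrow(part)), function(i) {
      for (j in seq_len(nrow(train))) {
        if (tanimoto_similarity(part$smiles[i], train$smiles[j],
                                fp_type) < threshold) next
        if (prot_sim(part$poi_uniprot[i], train$poi_uniprot[j]) <
            threshold) next
        if (prot_sim(part$e3_uniprot[i], train$e3_uniprot[j]) >=
            threshold) return(TRUE)
      }
      FALSE
    }, logical(1))
  }
  parts$val <- parts$val[!leaks(parts$val), , drop = FALSE]
  parts$test <- parts$test[!leaks(parts$test), , drop = FALSE]
  for (nm in names(parts)) rownames(parts[[nm]]) <- NULL
  parts
}

#' Write a labeled dataset and split manifest
#'
#' @param splits named list of data.frames (e.g. from [split_smiles_based()]).
#' @param csv_path output CSV for all records (with a `split` column).
#' @param manifest_path optional JSON manifest of compound ids per split.
#' @return `csv_path`, invisibly.
#' @export
write_labeled_dataset <- function(splits, csv_path, manifest_path = NULL) {
  all <- do.call(rbind, lapply(names(splits), function(nm) {
    df <- splits[[nm]]
    if (nrow(df) == 0L) return(NULL)
    df$split <- nm
    df
  }))
  utils::write.csv(all, csv_path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(lapply(splits, function(df) df$compound_id),
                         manifest_path, auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(csv_path)
}
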