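# Offline synthetic fixtures: PROTAC-like molecules assembled from a small
# warhead/linker/E3-ligand fragment library, random protein sequences with
# an optional planted motif, assay-text rendering of DC50/Dmax values, and a
# planted joint decision rule so end-to-end learnability is testable without
# any real data. Chemical realism is not a goal; parseability and a
# controllable signal are.

.WARHEAD_FRAGMENTS <- c(
  "c1ccccc1", "c1ccncc1", "Cc1ccccc1", "c1ccc2ccccc2c1", "c1ccsc1",
  "c1ccoc1", "Fc1ccccc1", "Clc1ccccc1", "N#Cc1ccccc1", "COc1ccccc1")

.LINKER_FRAGMENTS <- c(
  "CCOCCOCC", "CCCCCC", "CCOCC", "CCNCC", "CC(=O)NCC",
  "CCOCCOCCOCC", "CCSCC", "CCC(C)CC", "CCOC(=O)CC", "CCCC")

.E3LIGAND_FRAGMENTS <- c(
  "C1CCNCC1", "C1CCOC1", "c1ccc(O)cc1", "C1CCC(=O)NC1", "c1cnc[nH]1")

#' Default planted-signal specification
#'
#' The label is 1 when the PROTAC carries one of the designated "active"
#' warheads AND the POI carries the planted motif (rule "joint"); rule
#' "molecule_only" ties the label to the warhead alone for encoder unit
#' tests. Neither entity alone resolves the joint rule, so reaching high
#' AUROC requires combining molecule and protein information. `bayes_error`
#' is the probability of flipping the planted label; the rendered DC50/Dmax
#' evidence follows the flipped label, emulating assay noise.
#'
#' @param bayes_error label-flip probability (default 0.05).
#' @param rule "joint" (default) or "molecule_only".
#' @param active_warheads indices into the warhead library (default 1:5).
#' @param motif amino-acid motif planted into half of the POI pool.
#' @param implicit_fraction fraction of records whose DC50/Dmax appear only
#'   in free assay text (default 0.3).
#' @return list of class `SignalSpec`.
#' @export
signal_spec <- function(bayes_error = 0.05, rule = c("joint", "molecule_only"),
                        active_warheads = 1:5, motif = "WYWYWYWYWY",
                        implicit_fraction = 0.3) {
  rule <- match.arg(rule)
  structure(list(bayes_error = bayes_error, rule = rule,
                 active_warheads = active_warheads, motif = motif,
                 implicit_fraction = implicit_fraction),
            class = "SignalSpec")
}

.random_protein <- function(len, motif = NULL) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")
  seq <- paste(sample(aas, len, replace = TRUE), collapse = "")
  if (!is.null(motif)) {
    pos <- sample.int(max(1L, len - nchar(motif)), 1L)
    seq <- paste0(substr(seq, 1L, pos - 1L), motif,
                  substr(seq, pos + nchar(motif), len))
  }
  seq
}

#' Generate a synthetic PROTAC degradation dataset
#'
#' Builds n records of PROTAC-like SMILES (warhead + linker + E3 ligand by
#' concatenation from the packaged fragment library), a protein pool of 12
#' POIs (6 carrying the planted motif) and 4 E3 ligases with lengths 50-300,
#' labels from the planted rule with the configured Bayes error, and
#' DC50/Dmax values consistent with each final label. Classes are balanced
#' by construction (planted label drawn fair-coin). A configurable fraction
#' of records carries its values only as rendered assay text, exercising the
#' curation extractor.
#'
#' @param n number of records (at least 20).
#' @param seed integer seed; identical (n, seed, signal) reproduce the
#'   dataset exactly.
#' @param signal a `SignalSpec`.
#' @return list(records = data.frame(compound_id, smiles, poi_uniprot,
#'   e3_uniprot, dc50_nM, dmax_pct, assay_text, label, hidden_dc50_nM,
#'   hidden_dmax_pct, warhead, linker, e3ligand), sequences = named
#'   character vector, signal).
#' @export
generate_dataset <- function(n, seed = 1L, signal = signal_spec()) {
  stopifnot(n >= 20L)
  .with_local_rng(seed, {
    n_poi <- 12L; n_motif <- 6L; n_e3 <- 4L
    poi_ids <- sprintf("POI%02d", seq_len(n_poi))
    e3_ids <- sprintf("E3L%02d", seq_len(n_e3))
    sequences <- c(
      stats::setNames(vapply(seq_len(n_poi), function(i) {
        .random_protein(sample(50:300, 1L),
                        motif = if (i <= n_motif) signal$motif else NULL)
      }, character(1)), poi_ids),
      stats::setNames(vapply(seq_len(n_e3), function(i) {
        .random_protein(sample(50:300, 1L))
      }, character(1)), e3_ids))
    motif_pois <- poi_ids[seq_len(n_motif)]

    active <- signal$active_warheads
    inactive <- setdiff(seq_along(.WARHEAD_FRAGMENTS), active)
    motifless <- setdiff(poi_ids, motif_pois)

    planted <- stats::rbinom(n, 1L, 0.5)
    warhead_idx <- integer(n); poi <- character(n)
    for (i in seq_len(n)) {
      if (signal$rule == "molecule_only") {
        warhead_idx[i] <- if (planted[i] == 1L) sample(active, 1L)
                          else sample(inactive, 1L)
        poi[i] <- sample(poi_ids, 1L)
      } else if (planted[i] == 1L) {
        warhead_idx[i] <- sample(active, 1L)
        poi[i] <- sample(motif_pois, 1L)
      } else {
        combo <- sample(3L, 1L)
        warhead_idx[i] <- if (combo == 1L) sample(active, 1L)
                          else sample(inactive, 1L)
        poi[i] <- if (combo == 2L) sample(motif_pois, 1L)
                  else sample(motifless, 1L)
      }
    }
    linker_idx <- sample(seq_along(.LINKER_FRAGMENTS), n, replace = TRUE)
    e3lig_idx <- sample(seq_along(.E3LIGAND_FRAGMENTS), n, replace = TRUE)
    e3 <- sample(e3_ids, n, replace = TRUE)
    smiles <- paste0(.WARHEAD_FRAGMENTS[warhead_idx],
                     .LINKER_FRAGMENTS[linker_idx],
                     .E3LIGAND_FRAGMENTS[e3lig_idx])

    label <- ifelse(stats::runif(n) < signal$bayes_error,
                    1L - planted, planted)

    dc50 <- ifelse(label == 1L,
                   round(10^stats::runif(n, 0, 2), 3L),
                   round(10^stats::runif(n, 2.5, 4), 3L))
    dmax <- ifelse(label == 1L,
                   round(stats::runif(n, 85, 100), 1L),
                   round(stats::runif(n, 5, 45), 1L))

    records <- data.frame(
      compound_id = sprintf("CPD%04d", seq_len(n)),
      smiles = smiles,
      poi_uniprot = poi,
      e3_uniprot = e3,
      dc50_nM = dc50,
      dmax_pct = dmax,
      assay_text = "",
      label = label,
      hidden_dc50_nM = dc50,
      hidden_dmax_pct = dmax,
      warhead = warhead_idx,
      linker = linker_idx,
      e3ligand = e3lig_idx,
      stringsAsFactors = FALSE)

    implicit <- stats::runif(n) < signal$implicit_fraction
    records <- generate_assay_texts(records, which(implicit),
                                    seed = seed + 104729L)
    list(records = records, sequences = sequences, signal = signal)
  })
}

#' Render DC50/Dmax values into free assay text
#'
#' For the given record rows, moves the numeric values out of the explicit
#' columns into varied text templates (nM and uM unit variants, percent
#' degradation phrasing, and a qualitative "no degradation observed"
#' template for a subset of negatives), so rule-based extraction can be
#' scored against the hidden truth columns.
#'
#' @param records data.frame from [generate_dataset()] (hidden_* columns
#'   required).
#' @param rows integer row indices to convert to implicit evidence.
#' @param seed integer seed for template choice.
#' @return the records with assay_text filled and explicit values blanked on
#'   the chosen rows.
#' @export
generate_assay_texts <- function(records, rows = seq_len(nrow(records)),
                                 seed = 1L) {
  .with_local_rng(seed, {
    for (i in rows) {
      v <- records$hidden_dc50_nM[i]
      p <- records$hidden_dmax_pct[i]
      tmpl <- sample.int(4L, 1L)
      text <- switch(tmpl,
        sprintf("DC50 = %.10g nM; Dmax of %.10g%%", v, p),
        sprintf("%.10g uM DC50; %.10g%% degradation observed at 24 h",
                v / 1000, p),
        sprintf("Degradation assay: DC50 of %.10g nM with Dmax = %.10g%%", v, p),
        if (records$label[i] == 0L) "no degradation observed"
        else sprintf("DC50 of %.10g nM, Dmax = %.10g%%", v, p))
      records$assay_text[i] <- text
      records$dc50_nM[i] <- NA_real_
      records$dmax_pct[i] <- NA_real_
      if (identical(text, "no degradation observed")) {
        records$hidden_dc50_nM[i] <- NA_real_
        records$hidden_dmax_pct[i] <- NA_real_
      }
    }
    records
  })
}

#' Write a synthetic dataset in the PROTAC-DB table dialect
#'
#' @param dataset list from [generate_dataset()].
#' @param csv_path output CSV (columns: Compound ID, Smiles, Uniprot,
#'   E3 ligase Uniprot, DC50 (nM), Dmax (%), Assay (DC50/Dmax)).
#' @param fasta_path output FASTA of all protein sequences.
#' @param keep_labels also write the generator's label column (default
#'   FALSE: labels are re-derived by curation).
#' @return invisible list of the two paths.
#' @export
ptan_write_dataset <- function(dataset, csv_path, fasta_path,
                               keep_labels = FALSE) {
  r <- dataset$records
  out <- data.frame(
    `Compound ID` = r$compound_id,
    Smiles = r$smiles,
    Uniprot = r$poi_uniprot,
    `E3 ligase Uniprot` = r$e3_uniprot,
    `DC50 (nM)` = r$dc50_nM,
    `Dmax (%)` = r$dmax_pct,
    `Assay (DC50/Dmax)` = r$assay_text,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (keep_labels) out$Label <- r$label
  utils::write.csv(out, csv_path, row.names = FALSE, na = "")
  aa <- Biostrings::AAStringSet(dataset$sequences)
  Biostrings::writeXStringSet(aa, fasta_path)
  invisible(list(csv = csv_path, fasta = fasta_path))
}
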