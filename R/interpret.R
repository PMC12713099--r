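# Attention-map interpretability: mean-projected pairwise maps, per-atom
# weights with top-fraction selection, and top-k residue attribution, plus
# plain-file exports. Atom indices are 0-based (canonical atom order of the
# parsed SMILES); residue indices are 1-based (UniProt/PDB convention).

.map_tensor <- function(A) {
  if (inherits(A, "AttentionMap")) A$tensor else A
}

# Combine a list of per-head maps into one tensor
.combine_heads <- function(maps, heads_mode = c("mean", "sum")) {
  heads_mode <- match.arg(heads_mode)
  tensors <- lapply(maps, .map_tensor)
  out <- Reduce(`+`, tensors)
  if (heads_mode == "mean") out <- out / length(tensors)
  out
}

#' Project the 3D attention map to a 2D pairwise map
#'
#' Mean over the dropped axis: dropping the E3 axis yields the POI-PROTAC
#' map, dropping the POI axis the PROTAC-E3 map, and dropping the PROTAC
#' axis the POI-E3 map. Remaining axes keep their original order.
#'
#' @param A an `AttentionMap` or a 3D array (POI x PROTAC x E3).
#' @param drop_axis one of "poi", "protac", "e3".
#' @return 2D matrix of means.
#' @export
pairwise_projection <- function(A, drop_axis = c("poi", "protac", "e3")) {
  drop_axis <- match.arg(drop_axis)
  tensor <- .map_tensor(A)
  stopifnot(length(dim(tensor)) == 3L)
  keep <- switch(drop_axis, poi = c(2L, 3L), protac = c(1L, 3L),
                 e3 = c(1L, 2L))
  apply(tensor, keep, mean)
}

#' Per-atom attention weights with top-fraction selection
#'
#' The weight of an atom is the mean of the attention map over the POI and
#' E3 axes (heads combined by `heads_mode`); the selection takes the
#' ceiling(fraction * n_atoms) highest-weighted atoms, ties broken by stable
#' (ascending) atom index. Default fraction 0.6 mirrors coloring the top 60%
#' of atoms in a depiction.
#'
#' @param A an `AttentionMap`, a 3D array, or a list of per-head maps.
#' @param n_atoms expected PROTAC axis length (atom count); checked.
#' @param fraction selected fraction of atoms (default 0.6).
#' @param heads_mode "mean" (default) or "sum" when `A` is a per-head list.
#' @return list(weights = named numeric vector (atom_0, ...),
#'   selected_atoms = 0-based indices, fraction).
#' @export
atom_weights <- function(A, n_atoms = NULL, fraction = 0.6,
                         heads_mode = c("mean", "sum")) {
  heads_mode <- match.arg(heads_mode)
  tensor <- if (is.list(A) && !inherits(A, "AttentionMap")) {
    .combine_heads(A, heads_mode)
  } else .map_tensor(A)
  stopifnot(length(dim(tensor)) == 3L)
  beta <- dim(tensor)[2L]
  if (!is.null(n_atoms) && n_atoms != beta) {
    stop("attention map PROTAC axis (", beta,
         ") does not match atom count (", n_atoms, ")", call. = FALSE)
  }
  w <- apply(tensor, 2L, mean)
  names(w) <- paste0("atom_", seq_len(beta) - 1L)
  k <- ceiling(fraction * beta)
  ord <- order(-w, seq_len(beta))
  list(weights = w, selected_atoms = sort(ord[seq_len(k)] - 1L),
       fraction = fraction)
}

#' Top-k attended residues of the POI or E3 ligase
#'
#' The weight of a residue is the mean of the attention map over the other
#' two axes; the top k residues are returned in non-increasing weight order,
#' ties broken by ascending residue index. Indices are 1-based residue
#' numbers. Requires token-mode protein embeddings (a residue axis of length
#' 1 indicates pooled mode and is rejected).
#'
#' @param A an `AttentionMap`, 3D array, or per-head list.
#' @param entity "poi" or "e3".
#' @param k number of residues (default 5, clamped to the axis length).
#' @param heads_mode "mean" (default) or "sum".
#' @return data.frame(residue_index, weight), k rows.
#' @export
residue_topk <- function(A, entity = c("poi", "e3"), k = 5L,
                         heads_mode = c("mean", "sum")) {
  entity <- match.arg(entity)
  heads_mode <- match.arg(heads_mode)
  tensor <- if (is.list(A) && !inherits(A, "AttentionMap")) {
    .combine_heads(A, heads_mode)
  } else .map_tensor(A)
  stopifnot(length(dim(tensor)) == 3L)
  axis <- if (entity == "poi") 1L else 3L
  n <- dim(tensor)[axis]
  if (n == 1L) {
    stop("residue attribution requires token-mode protein embeddings; ",
         "this map has a pooled (length-1) ", entity, " axis", call. = FALSE)
  }
  w <- apply(tensor, axis, mean)
  k <- min(k, n)
  ord <- order(-w, seq_len(n))[seq_len(k)]
  data.frame(residue_index = ord, weight = w[ord])
}

#' Export attribution artifacts for one sample
#'
#' Writes atom_weights.csv (0-based atom index, weight, selected flag), one
#' residue CSV per protein entity (1-based indices), and the raw per-head 3D
#' maps as attention_maps.rds.
#'
#' @param maps list of per-head `AttentionMap`s for one sample.
#' @param out_dir output directory (created if needed).
#' @param smiles optional SMILES recorded alongside the atom table.
#' @param fraction atom selection fraction (default 0.6).
#' @param k residues per entity (default 5).
#' @param heads_mode head combination (default "mean").
#' @return named character vector of the files written, invisibly.
#' @export
export_attribution <- function(maps, out_dir, smiles = NULL, fraction = 0.6,
                               k = 5L, heads_mode = "mean") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  aw <- atom_weights(maps, fraction = fraction, heads_mode = heads_mode)
  atom_df <- data.frame(
    atom_index = seq_along(aw$weights) - 1L,
    weight = unname(aw$weights),
    selected = (seq_along(aw$weights) - 1L) %in% aw$selected_atoms)
  if (!is.null(smiles)) atom_df$smiles <- smiles
  f <- file.path(out_dir, "atom_weights.csv")
  utils::write.csv(atom_df, f, row.names = FALSE)
  files["atom_weights"] <- f

  tensor <- .combine_heads(maps, heads_mode)
  for (entity in c("poi", "e3")) {
    axis_len <- dim(tensor)[if (entity == "poi") 1L else 3L]
    if (axis_len > 1L) {
      rt <- residue_topk(maps, entity, k = k, heads_mode = heads_mode)
      f <- file.path(out_dir, paste0(entity, "_residue_weights.csv"))
      utils::write.csv(rt, f, row.names = FALSE)
      files[paste0(entity, "_residues")] <- f
    }
  }
  f <- file.path(out_dir, "attention_maps.rds")
  saveRDS(lapply(maps, .map_tensor), f)
  files["attention_maps"] <- f
  invisible(files)
}
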