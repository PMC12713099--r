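# Hierarchical PROTAC featurization: per-atom descriptors plus a molecule-level
# global feature (SMILES character codes + physicochemical properties),
# broadcast onto every node of the molecular graph.

.ptan_env <- new.env(parent = emptyenv())

.ATOMIC_NUMBERS <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Se = 2, Br = 1, I = 1
)

#' Names of the nine default molecule-level properties
#'
#' Molecular weight, heavy-atom count, hydrogen-bond acceptors and donors,
#' rotatable bonds, topological polar surface area, calculated logP, ring
#' count, and aromatic ring count. A curated table may override any of them.
#'
#' @export
ptan_property_names <- c(
  "mol_weight", "heavy_atoms", "hba", "hbd", "rotatable_bonds",
  "tpsa", "logp", "ring_count", "aromatic_rings"
)

# Syntax pre-validation. OpenBabel accepts some malformed strings silently
# (e.g. an unclosed branch), so balance of branches, brackets and ring-bond
# labels is checked before conversion.
.validate_smiles_syntax <- function(smiles) {
  fail <- function(why) {
    stop("SMILES string could not be parsed: '", smiles, "' (", why, ")",
         call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (any(!grepl("[A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]",
                 chars, perl = TRUE))) fail("illegal character")
  depth <- 0L; bracket <- FALSE
  ring_open <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (bracket) {
      if (ch == "[") fail("nested bracket")
      if (ch == "]") bracket <- FALSE
    } else if (ch == "[") {
      bracket <- TRUE
    } else if (ch == "]") {
      fail("unmatched ']'")
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) fail("unmatched ')'")
    } else if (grepl("[0-9]", ch) || ch == "%") {
      label <- ch
      if (ch == "%") {
        if (i + 2L > length(chars)) fail("truncated ring label")
        label <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 2L
      }
      if (label %in% ring_open) {
        ring_open <- ring_open[-match(label, ring_open)]
      } else {
        ring_open <- c(ring_open, label)
      }
    }
    i <- i + 1L
  }
  if (bracket) fail("unclosed bracket")
  if (depth != 0L) fail("unclosed branch")
  if (length(ring_open) > 0L) fail("unclosed ring bond")
  if (grepl("[=#$/\\\\(]$", smiles)) fail("dangling bond")
  invisible(TRUE)
}

# Parse a SMILES into atoms and bonds via OpenBabel's V2000 output. The
# atom/bond blocks are read directly from the text because the higher-level
# SDF container in ChemmineR cannot represent zero-bond molecules; a
# ChemmineR SDFset is still attached (when bonds exist) for ring perception
# and descriptors.
.parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("expected a single non-empty SMILES string", call. = FALSE)
  }
  key <- paste0("mol::", smiles)
  cached <- .ptan_env[[key]]
  if (!is.null(cached)) return(cached)
  .validate_smiles_syntax(smiles)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) {
    stop("SMILES string could not be parsed: '", smiles, "'", call. = FALSE)
  }
  counts <- lines[4L]
  n <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  m <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n) || is.na(m) || n < 1L) {
    stop("SMILES string could not be parsed: '", smiles, "'", call. = FALSE)
  }
  atom_lines <- lines[4L + seq_len(n)]
  fields <- strsplit(trimws(atom_lines), "\\s+")
  symbols <- vapply(fields, `[`, character(1), 4L)
  charge_code <- vapply(fields, function(f) {
    suppressWarnings(as.integer(f[6L]))
  }, integer(1))
  charge_code[is.na(charge_code)] <- 0L
  parity <- vapply(fields, function(f) {
    suppressWarnings(as.integer(f[7L]))
  }, integer(1))
  parity[is.na(parity)] <- 0L
  chg_map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
               `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- unname(chg_map[as.character(charge_code)])
  charge[is.na(charge)] <- 0L
  radicals <- as.integer(charge_code == 4L)
  bonds <- matrix(integer(0), ncol = 4L)
  if (m > 0L) {
    bond_lines <- lines[4L + n + seq_len(m)]
    bonds <- t(vapply(bond_lines, function(l) {
      as.integer(c(substr(l, 1L, 3L), substr(l, 4L, 6L),
                   substr(l, 7L, 9L), substr(l, 10L, 12L)))
    }, integer(4L), USE.NAMES = FALSE))
  }
  # property block: explicit charges / radicals override atom-block codes
  for (l in grep("^M  (CHG|RAD)", lines, value = TRUE)) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    kind <- f[2L]
    cnt <- as.integer(f[3L])
    for (e in seq_len(cnt)) {
      at <- as.integer(f[2L + 2L * e])
      vl <- as.integer(f[3L + 2L * e])
      if (kind == "CHG") charge[at] <- vl else radicals[at] <- vl
    }
  }
  sdfset <- NULL
  if (m > 0L) {
    sdfset <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(lines)),
      error = function(e) NULL)
  }
  mol <- list(n = n, m = m, symbols = symbols, charge = charge,
              radicals = radicals, parity = parity, bonds = bonds,
              sdfset = sdfset, smiles = smiles)
  .ptan_env[[key]] <- mol
  mol
}

#' Canonicalize SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES (OpenBabel canonical form).
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  out <- character(length(smiles))
  todo <- !vapply(smiles, function(s) {
    !is.null(.ptan_env[[paste0("can::", s)]])
  }, logical(1))
  if (any(todo)) {
    invisible(lapply(smiles[todo], .validate_smiles_syntax))
    raw <- ChemmineOB::convertFormat(
      "SMI", "CAN", paste0(paste(smiles[todo], collapse = "\n"), "\n"))
    lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
    lines <- sub("\t.*$", "", lines)
    lines <- trimws(lines)
    if (length(lines) != sum(todo) || any(!nzchar(lines))) {
      stop("SMILES canonicalization failed for at least one input",
           call. = FALSE)
    }
    for (i in seq_along(lines)) {
      .ptan_env[[paste0("can::", smiles[todo][i])]] <- lines[i]
    }
  }
  for (i in seq_along(smiles)) out[i] <- .ptan_env[[paste0("can::", smiles[i])]]
  out
}

.ring_info <- function(mol) {
  key <- paste0("rings::", mol$smiles)
  cached <- .ptan_env[[key]]
  if (!is.null(cached)) return(cached)
  in_ring <- rep(FALSE, mol$n)
  aromatic <- rep(FALSE, mol$n)
  ring_atom_sets <- list()
  aromatic_sets <- list()
  if (mol$n >= 3L && mol$m >= 3L && !is.null(mol$sdfset)) {
    ri <- tryCatch(
      suppressWarnings(ChemmineR::rings(mol$sdfset[[1]], type = "all",
                                        arom = TRUE)),
      error = function(e) NULL)
    if (!is.null(ri) && length(ri$RINGS) > 0L) {
      for (j in seq_along(ri$RINGS)) {
        idx <- as.integer(sub("^[^_]*_", "", ri$RINGS[[j]]))
        in_ring[idx] <- TRUE
        ring_atom_sets[[length(ring_atom_sets) + 1L]] <- idx
        if (isTRUE(ri$AROMATIC[[j]])) {
          aromatic[idx] <- TRUE
          aromatic_sets[[length(aromatic_sets) + 1L]] <- idx
        }
      }
    }
  }
  out <- list(in_ring = in_ring, aromatic = aromatic,
              rings = ring_atom_sets, aromatic_rings = aromatic_sets)
  .ptan_env[[key]] <- out
  out
}

#' Build a molecular graph from a SMILES string
#'
#' Parses the SMILES (implicit hydrogens; heavy-atom graph) and returns the
#' graph with nine integer-coded atom descriptors per node and three
#' integer-coded bond descriptors per directed edge. Both directions of every
#' bond are stored with identical attributes. Edge endpoint indices are
#' 0-based, matching the exported atom numbering of the interpretability
#' module.
#'
#' Atom columns: atomic number; chirality parity code (0 = unspecified);
#' degree (heavy neighbors); formal charge; implicit hydrogen count; radical
#' electrons; hybridization code (1 = sp, 2 = sp2, 3 = sp3); aromaticity
#' (0/1); ring membership (0/1). Bond columns: bond type (1 = single,
#' 2 = double, 3 = triple, 4 = aromatic), stereo code, conjugation (0/1).
#'
#' @param smiles a single SMILES string.
#' @return an object of class `MolecularGraph`: a list with `atom_features`
#'   (|V| x 9 integer matrix), `edge_index` (eps x 2, 0-based, both
#'   directions), `edge_attrs` (eps x 3), `num_atoms`, `num_edges`, `smiles`.
#' @export
build_molecular_graph <- function(smiles) {
  mol <- .parse_smiles(smiles)
  n <- mol$n
  symbols <- mol$symbols
  znum <- unname(.ATOMIC_NUMBERS[symbols])
  if (anyNA(znum)) {
    stop("unsupported element(s) in '", smiles, "': ",
         paste(unique(symbols[is.na(znum)]), collapse = ", "), call. = FALSE)
  }
  charge <- mol$charge
  parity <- mol$parity
  radicals <- mol$radicals

  m <- mol$m
  b_from <- b_to <- b_order <- b_stereo <- integer(0)
  if (m > 0L) {
    b_from <- mol$bonds[, 1L]; b_to <- mol$bonds[, 2L]
    b_order <- mol$bonds[, 3L]; b_stereo <- mol$bonds[, 4L]
  }

  rings <- .ring_info(mol)

  degree <- tabulate(c(b_from, b_to), nbins = n)
  order_sum <- rep(0, n)
  has_multiple <- rep(FALSE, n)
  n_double <- rep(0L, n)
  has_triple <- rep(FALSE, n)
  if (m > 0L) {
    for (b in seq_len(m)) {
      i <- b_from[b]; j <- b_to[b]; o <- b_order[b]
      order_sum[i] <- order_sum[i] + o
      order_sum[j] <- order_sum[j] + o
      if (o >= 2L) { has_multiple[i] <- TRUE; has_multiple[j] <- TRUE }
      if (o == 2L) { n_double[i] <- n_double[i] + 1L
                     n_double[j] <- n_double[j] + 1L }
      if (o == 3L) { has_triple[i] <- TRUE; has_triple[j] <- TRUE }
    }
  }

  valence <- unname(.DEFAULT_VALENCE[symbols])
  eff <- valence
  pos <- charge > 0L
  eff[pos & symbols %in% c("N", "P", "O", "S", "Se")] <-
    valence[pos & symbols %in% c("N", "P", "O", "S", "Se")] +
    charge[pos & symbols %in% c("N", "P", "O", "S", "Se")]
  eff[pos & symbols %in% c("C", "B", "Si")] <-
    valence[pos & symbols %in% c("C", "B", "Si")] -
    charge[pos & symbols %in% c("C", "B", "Si")]
  neg <- charge < 0L
  eff[neg] <- valence[neg] + charge[neg]
  n_h <- pmax(0L, as.integer(round(eff - order_sum - radicals)))

  sp2 <- rings$aromatic | (n_double >= 1L & !has_triple & n_double < 2L)
  sp1 <- has_triple | n_double >= 2L
  hybrid <- ifelse(sp1, 1L, ifelse(sp2, 2L, 3L))

  atom_features <- cbind(
    atomic_number = znum,
    chirality = parity,
    degree = degree,
    formal_charge = charge,
    num_h = n_h,
    radical_electrons = radicals,
    hybridization = hybrid,
    aromaticity = as.integer(rings$aromatic),
    in_ring = as.integer(rings$in_ring)
  )
  storage.mode(atom_features) <- "integer"

  bond_aromatic <- rep(FALSE, m)
  if (m > 0L && length(rings$aromatic_rings) > 0L) {
    for (ring in rings$aromatic_rings) {
      for (b in seq_len(m)) {
        if (b_from[b] %in% ring && b_to[b] %in% ring) bond_aromatic[b] <- TRUE
      }
    }
  }
  p_orbital <- sp1 | sp2                     # atom carries pi system
  bond_type <- ifelse(bond_aromatic, 4L, b_order)
  conjugated <- if (m > 0L) {
    as.integer(bond_aromatic | (p_orbital[b_from] & p_orbital[b_to]))
  } else integer(0)

  edge_index <- matrix(integer(0), ncol = 2L)
  edge_attrs <- matrix(integer(0), ncol = 3L,
                       dimnames = list(NULL, c("bond_type", "stereo",
                                               "conjugation")))
  if (m > 0L) {
    edge_index <- cbind(c(b_from, b_to), c(b_to, b_from)) - 1L
    edge_attrs <- cbind(bond_type = rep(bond_type, 2L),
                        stereo = rep(b_stereo, 2L),
                        conjugation = rep(conjugated, 2L))
    storage.mode(edge_attrs) <- "integer"
  }

  structure(
    list(atom_features = atom_features, edge_index = edge_index,
         edge_attrs = edge_attrs, num_atoms = n, num_edges = 2L * m,
         smiles = smiles),
    class = "MolecularGraph")
}

.tokenize_smiles <- function(smiles, two_char_tokens) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) return(character(0))
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (i < length(chars) &&
        paste0(chars[i], chars[i + 1L]) %in% two_char_tokens) {
      tokens <- c(tokens, paste0(chars[i], chars[i + 1L]))
      i <- i + 2L
    } else {
      tokens <- c(tokens, chars[i])
      i <- i + 1L
    }
  }
  tokens
}

#' Default 39-symbol SMILES character vocabulary
#'
#' Derived deterministically from a packaged sample of lead-like SMILES by
#' ranking token frequencies (two-character element symbols Cl and Br are
#' single tokens), ties broken lexicographically; the 39 most frequent tokens
#' receive codes 1..39. Any token outside the table encodes to 0.
#'
#' @return named integer vector mapping token to code in 1..39.
#' @export
default_smiles_vocab <- function() {
  cached <- .ptan_env[["vocab"]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "leadlike_smiles.txt", package = "protactan")
  smi <- readLines(path, warn = FALSE)
  smi <- smi[nzchar(smi) & !startsWith(smi, "#")]
  tokens <- unlist(lapply(smi, .tokenize_smiles,
                          two_char_tokens = c("Cl", "Br")))
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab))
  top <- names(tab)[ord][seq_len(min(39L, length(tab)))]
  vocab <- stats::setNames(seq_along(top), top)
  .ptan_env[["vocab"]] <- vocab
  vocab
}

#' Frequency-encode a SMILES string as integer codes
#'
#' Each character (Cl/Br as single tokens when the vocabulary defines them) is
#' mapped to its code; characters absent from the vocabulary map to 0. The
#' output has fixed length `max_len`: longer strings are truncated, shorter
#' ones right-padded with 0. Total on all strings; never raises.
#'
#' @param smiles a SMILES string.
#' @param vocab named integer vector mapping 39 tokens to codes 1..39.
#' @param max_len output length (default 128).
#' @return integer vector of length `max_len` with values in 0..39.
#' @export
encode_smiles_frequencies <- function(smiles, vocab = default_smiles_vocab(),
                                      max_len = 128L) {
  stopifnot(length(vocab) == 39L, all(sort(unname(vocab)) == 1:39))
  codes <- integer(max_len)
  if (is.character(smiles) && length(smiles) == 1L && !is.na(smiles) &&
      nzchar(smiles)) {
    two <- names(vocab)[nchar(names(vocab)) == 2L]
    tokens <- .tokenize_smiles(smiles, two_char_tokens = two)
    mapped <- unname(vocab[tokens])
    mapped[is.na(mapped)] <- 0L
    k <- min(length(mapped), max_len)
    if (k > 0L) codes[seq_len(k)] <- mapped[seq_len(k)]
  }
  codes
}

.count_rotatable <- function(graph, info) {
  if (graph$num_edges == 0L) return(0L)
  half <- graph$edge_index[, 1L] < graph$edge_index[, 2L]
  ei <- graph$edge_index[half, , drop = FALSE] + 1L
  ea <- graph$edge_attrs[half, , drop = FALSE]
  deg <- graph$atom_features[, "degree"]
  bond_in_ring <- function(i, j) {
    for (ring in info$rings) if (i %in% ring && j %in% ring) return(TRUE)
    FALSE
  }
  n <- 0L
  for (b in seq_len(nrow(ei))) {
    i <- ei[b, 1L]; j <- ei[b, 2L]
    if (ea[b, "bond_type"] == 1L && deg[i] >= 2L && deg[j] >= 2L &&
        !bond_in_ring(i, j)) {
      n <- n + 1L
    }
  }
  n
}

#' Compute the nine molecule-level properties of a SMILES
#'
#' Molecular weight, HBA, HBD, logP and TPSA come from OpenBabel descriptors;
#' heavy-atom, rotatable-bond, ring and aromatic-ring counts are derived from
#' the parsed graph. When a curated table supplies property columns, its
#' non-missing values override the computed ones element-wise.
#'
#' @param smiles a SMILES string.
#' @param table_row optional named numeric vector; names matching
#'   `ptan_property_names` override computed values where non-missing.
#' @return named numeric vector of length 9 in original units.
#' @export
compute_properties <- function(smiles, table_row = NULL) {
  mol <- .parse_smiles(smiles)
  graph <- build_molecular_graph(smiles)
  pr <- .ptan_env[[paste0("prop::", smiles)]]
  if (is.null(pr)) {
    pr <- ChemmineOB::forEachMol("SMILES", smiles, ChemmineOB::prop_OB)[[1]]
    .ptan_env[[paste0("prop::", smiles)]] <- pr
  }
  info <- .ring_info(mol)
  out <- c(
    mol_weight = as.numeric(pr$MW),
    heavy_atoms = as.numeric(graph$num_atoms),
    hba = as.numeric(pr$HBA1),
    hbd = as.numeric(pr$HBD),
    rotatable_bonds = as.numeric(.count_rotatable(graph, info)),
    tpsa = as.numeric(pr$TPSA),
    logp = as.numeric(pr$logP),
    ring_count = as.numeric(length(info$rings)),
    aromatic_rings = as.numeric(length(info$aromatic_rings))
  )
  if (!is.null(table_row)) {
    keep <- intersect(names(table_row), ptan_property_names)
    for (nm in keep) {
      if (!is.na(table_row[[nm]])) out[[nm]] <- as.numeric(table_row[[nm]])
    }
  }
  out
}

#' Fit a property scaler on training rows
#'
#' @param rows numeric matrix n x 9 of raw property values.
#' @return list with `means` and `stds` (zero-variance columns get std 1 with
#'   a warning); persist alongside the model and reuse on new data.
#' @export
fit_property_scaler <- function(rows) {
  rows <- as.matrix(rows)
  means <- colMeans(rows)
  stds <- apply(rows, 2L, stats::sd)
  if (nrow(rows) < 2L) stds[] <- NA_real_
  degenerate <- !is.finite(stds) | stds <= 0
  if (any(degenerate)) {
    warning("zero-variance property column(s): ",
            paste(which(degenerate), collapse = ", "),
            "; using std = 1")
    stds[degenerate] <- 1
  }
  list(means = means, stds = stds)
}

#' Standardize property rows with a fitted scaler
#'
#' @param rows numeric matrix n x 9.
#' @param means,stds numeric vectors of length 9 fit on the training split.
#' @return matrix of (x - mean) / std, column-wise.
#' @export
standardize_properties <- function(rows, means, stds) {
  rows <- as.matrix(rows)
  if (ncol(rows) != length(means) || length(means) != length(stds)) {
    stop("dimension mismatch between rows and scaler", call. = FALSE)
  }
  if (any(!is.finite(stds) | stds <= 0)) {
    stop("stds must be strictly positive; fit with fit_property_scaler()",
         call. = FALSE)
  }
  sweep(sweep(rows, 2L, means, "-"), 2L, stds, "/")
}

#' Assemble the hierarchical molecular graph
#'
#' Broadcasts the molecule-level global feature (SMILES codes followed by
#' standardized properties) onto every atom row: each node row is
#' Concat(atom 9-features, codes, properties), so the node width is
#' 9 + |S| + 9 (146 at the default |S| = 128).
#'
#' @param graph a `MolecularGraph`.
#' @param codes integer vector of SMILES character codes (length |S|).
#' @param props numeric vector of 9 (standardized) properties.
#' @return an object of class `HierarchicalGraph` with `node_matrix`,
#'   `edge_index`, `edge_attrs`, `num_atoms`, `num_edges`.
#' @export
assemble_hierarchical_graph <- function(graph, codes, props) {
  stopifnot(inherits(graph, "MolecularGraph"), length(props) == 9L)
  n <- graph$num_atoms
  global <- c(as.numeric(codes), as.numeric(props))
  node_matrix <- cbind(
    graph$atom_features,
    matrix(global, nrow = n, ncol = length(global), byrow = TRUE))
  colnames(node_matrix) <- c(colnames(graph$atom_features),
                             paste0("s", seq_along(codes)),
                             ptan_property_names)
  structure(
    list(node_matrix = node_matrix, edge_index = graph$edge_index,
         edge_attrs = graph$edge_attrs, num_atoms = n,
         num_edges = graph$num_edges, smiles = graph$smiles),
    class = "HierarchicalGraph")
}

#' One-call hierarchical featurization of a PROTAC SMILES
#'
#' @param smiles a SMILES string.
#' @param vocab SMILES character vocabulary (default packaged table).
#' @param max_len SMILES code length |S| (default 128).
#' @param scaler optional list(means, stds) from [fit_property_scaler()]; when
#'   NULL, raw properties are used unscaled.
#' @param table_row optional curated property overrides, see
#'   [compute_properties()].
#' @return a `HierarchicalGraph`.
#' @export
featurize_protac <- function(smiles, vocab = default_smiles_vocab(),
                             max_len = 128L, scaler = NULL, table_row = NULL) {
  graph <- build_molecular_graph(smiles)
  # encode the canonical form so the global feature, like the properties,
  # depends on the molecule rather than on how its SMILES was written
  codes <- encode_smiles_frequencies(canonical_smiles(smiles), vocab, max_len)
  props <- compute_properties(smiles, table_row)
  if (!is.null(scaler)) {
    props <- drop(standardize_properties(matrix(props, nrow = 1L),
                                         scaler$means, scaler$stds))
  }
  assemble_hierarchical_graph(graph, codes, props)
}

#' Write / read a hierarchical graph bundle as plain-text arrays
#'
#' The bundle layout is three CSV files in `dir`: node_matrix.csv,
#' edge_index.csv, edge_attrs.csv.
#'
#' @param hgraph a `HierarchicalGraph`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_graph_bundle <- function(hgraph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(hgraph$node_matrix, file.path(dir, "node_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(hgraph$edge_index, file.path(dir, "edge_index.csv"),
                   row.names = FALSE)
  utils::write.csv(hgraph$edge_attrs, file.path(dir, "edge_attrs.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_graph_bundle
#' @export
read_graph_bundle <- function(dir) {
  node_matrix <- as.matrix(utils::read.csv(file.path(dir, "node_matrix.csv")))
  edge_index <- as.matrix(utils::read.csv(file.path(dir, "edge_index.csv")))
  edge_attrs <- as.matrix(utils::read.csv(file.path(dir, "edge_attrs.csv")))
  structure(
    list(node_matrix = node_matrix, edge_index = edge_index,
         edge_attrs = edge_attrs, num_atoms = nrow(node_matrix),
         num_edges = nrow(edge_index), smiles = NA_character_),
    class = "HierarchicalGraph")
}
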