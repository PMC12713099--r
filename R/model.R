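# Full degradation classifier: hierarchical PROTAC encoder (linear +
# edge-aware GCN), protein adapters, multi-head ternary attention, average
# pooling, and a 2-layer MLP with log-softmax. Training runs on the autodiff
# tape with Adam; prediction uses a plain-matrix forward that additionally
# returns the per-head attention maps.

#' Model configuration
#'
#' Default architecture and training setup: SMILES code
#' length 128 (node width 9 + 128 + 9 = 146), protein cap 1022, PLM width
#' 1280, adapter [128, 64], GCN [128, 128] with edge dimension 3, two
#' attention heads, MLP hidden 64, Adam lr 5e-4, batch 4, up to 100 epochs
#' with early-stop patience 30. The TAN latent width `kappa` and pooling
#' stride are configuration (256 and 2). `protein_mode` "pooled" feeds the
#' averaged sequence representation (alpha = 1); "token" keeps per-residue
#' columns for residue-level attribution.
#'
#' @param ... overrides of any default field.
#' @return object of class `ptan_config`.
#' @export
ptan_config <- function(...) {
  cfg <- list(
    smiles_max_len = 128L,
    protein_max_len = 1022L,
    plm_dim = 1280L,
    protac_hidden = 64L,
    gcn_hidden = c(128L, 128L),
    edge_dim = 3L,
    adapter = c(128L, 64L),
    kappa = 256L,
    stride = 2L,
    heads = 2L,
    mlp_hidden = 64L,
    lr = 5e-4,
    batch_size = 4L,
    max_epochs = 100L,
    patience = 30L,
    seed = 1L,
    protein_mode = "pooled",
    val_fraction = 0.1,
    class_weights = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$kappa %% cfg$stride == 0L, cfg$heads >= 1L,
            cfg$protein_mode %in% c("pooled", "token"))
  cfg$node_width <- 9L + cfg$smiles_max_len + 9L
  structure(cfg, class = "ptan_config")
}

.rand_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Initialize model parameters
#'
#' @param config a `ptan_config`.
#' @return object of class `ptan_model` (parameters, config; the property
#'   scaler is attached by [ptan_train()]).
#' @export
ptan_init_model <- function(config = ptan_config()) {
  .with_local_rng(config$seed, {
    nw <- config$node_width
    ph <- config$protac_hidden
    g1 <- config$gcn_hidden[1L]; g2 <- config$gcn_hidden[2L]
    a1 <- config$adapter[1L]; a2 <- config$adapter[2L]
    k <- config$kappa
    p <- list(
      protac_W1 = .rand_mat(nw, ph, nw), protac_b1 = matrix(0, 1L, ph),
      gcn_Wg1 = .rand_mat(ph, g1, ph), gcn_We1 = .rand_mat(config$edge_dim, g1, config$edge_dim),
      gcn_bg1 = matrix(0, 1L, g1),
      gcn_Wg2 = .rand_mat(g1, g2, g1), gcn_We2 = .rand_mat(config$edge_dim, g2, config$edge_dim),
      gcn_bg2 = matrix(0, 1L, g2),
      poi_A1 = .rand_mat(a1, config$plm_dim, config$plm_dim),
      poi_a1 = matrix(0, a1, 1L),
      poi_A2 = .rand_mat(a2, a1, a1), poi_a2 = matrix(0, a2, 1L),
      e3_A1 = .rand_mat(a1, config$plm_dim, config$plm_dim),
      e3_a1 = matrix(0, a1, 1L),
      e3_A2 = .rand_mat(a2, a1, a1), e3_a2 = matrix(0, a2, 1L),
      tan_U = .rand_mat(a2, k, a2),
      tan_W = .rand_mat(g2, k, g2),
      tan_V = .rand_mat(a2, k, a2),
      mlp_W1 = .rand_mat(config$mlp_hidden, k %/% config$stride,
                         k %/% config$stride),
      mlp_b1 = matrix(0, config$mlp_hidden, 1L),
      mlp_W2 = .rand_mat(2L, config$mlp_hidden, config$mlp_hidden),
      mlp_b2 = matrix(0, 2L, 1L)
    )
    for (h in seq_len(config$heads)) {
      p[[paste0("tan_q", h)]] <- matrix(stats::rnorm(k, sd = sqrt(1 / k)),
                                        k, 1L)
    }
    structure(list(params = p, config = config, scaler = NULL,
                   history = NULL, embedder_name = NULL),
              class = "ptan_model")
  })
}

#' TAN parameters of a fitted model
#'
#' @param model a `ptan_model`.
#' @return a `TanParameters` view of the model's attention weights.
#' @export
ptan_tan_parameters <- function(model) {
  p <- model$params
  structure(
    list(U = p$tan_U, W = p$tan_W, V = p$tan_V,
         q_heads = lapply(seq_len(model$config$heads), function(h) {
           drop(p[[paste0("tan_q", h)]])
         }),
         kappa = model$config$kappa, heads = model$config$heads),
    class = "TanParameters")
}

# Symmetric-normalized adjacency with self-loops, and the per-node
# norm-weighted sum of incident edge attributes (self-loops contribute
# nothing to the edge term).
.graph_operators <- function(hgraph) {
  n <- hgraph$num_atoms
  A <- diag(1, n)
  if (hgraph$num_edges > 0L) {
    idx <- hgraph$edge_index + 1L
    A[idx] <- 1
  }
  d <- rowSums(A)
  dis <- 1 / sqrt(d)
  Anorm <- A * (dis %o% dis)
  S <- matrix(0, n, 3L)
  if (hgraph$num_edges > 0L) {
    idx <- hgraph$edge_index + 1L
    for (e in seq_len(nrow(idx))) {
      i <- idx[e, 1L]; j <- idx[e, 2L]
      S[i, ] <- S[i, ] + dis[i] * dis[j] * hgraph$edge_attrs[e, ]
    }
  }
  list(Anorm = Anorm, S = S)
}

#' Encode a PROTAC hierarchical graph
#'
#' One linear layer followed by two edge-aware GCN layers. Each GCN layer
#' aggregates neighbor messages under symmetric normalization with
#' self-loops; edge attributes pass through a learned linear embedding added
#' to the aggregated messages.
#'
#' @param hgraph a `HierarchicalGraph`.
#' @param params model parameter list (fields protac_W1, protac_b1, gcn_*).
#' @param activation nonlinearity (default ReLU).
#' @return D_t x beta matrix, one column per atom.
#' @export
encode_protac <- function(hgraph, params, activation = .relu) {
  if (ncol(hgraph$node_matrix) != nrow(params$protac_W1)) {
    stop("node width ", ncol(hgraph$node_matrix),
         " does not match encoder input ", nrow(params$protac_W1),
         call. = FALSE)
  }
  ops <- .graph_operators(hgraph)
  H <- activation(sweep(hgraph$node_matrix %*% params$protac_W1, 2L,
                        drop(params$protac_b1), "+"))
  H <- activation(sweep(ops$Anorm %*% (H %*% params$gcn_Wg1) +
                          ops$S %*% params$gcn_We1,
                        2L, drop(params$gcn_bg1), "+"))
  H <- activation(sweep(ops$Anorm %*% (H %*% params$gcn_Wg2) +
                          ops$S %*% params$gcn_We2,
                        2L, drop(params$gcn_bg2), "+"))
  t(H)
}

# ---- sample compilation ----------------------------------------------------

# Precompute every constant tensor of one (POI, PROTAC, E3, label) sample.
.compile_sample <- function(smiles, poi, e3, label, model, embedder,
                            emb_cache = new.env(parent = emptyenv()),
                            protein_mode = NULL) {
  cfg <- model$config
  mode <- if (is.null(protein_mode)) cfg$protein_mode else protein_mode
  hgraph <- featurize_protac(smiles, max_len = cfg$smiles_max_len,
                             scaler = model$scaler)
  ops <- .graph_operators(hgraph)
  get_emb <- function(rec) {
    key <- paste0(rec$uniprot_id, "::", mode)
    x <- emb_cache[[key]]
    if (is.null(x)) {
      e <- embed_protein(rec, embedder, mode = mode,
                         max_len = cfg$protein_max_len)
      x <- if (mode == "pooled") matrix(e$pooled_vector, ncol = 1L)
           else t(e$token_matrix)
      emb_cache[[key]] <- x
    }
    x
  }
  list(X = hgraph$node_matrix, Anorm = ops$Anorm, S = ops$S,
       Xp_raw = get_emb(poi), Xe_raw = get_emb(e3),
       label = label, smiles = smiles,
       poi_id = poi$uniprot_id, e3_id = e3$uniprot_id,
       num_atoms = hgraph$num_atoms)
}

.as_record_list <- function(sequences) {
  if (inherits(sequences, "AAStringSet")) {
    ids <- vapply(strsplit(names(sequences), "\\s+"), `[`, character(1), 1L)
    sequences <- stats::setNames(as.character(sequences), ids)
  }
  if (is.character(sequences)) {
    return(lapply(stats::setNames(names(sequences), names(sequences)),
                  function(id) protein_record(id, sequences[[id]])))
  }
  if (is.list(sequences) && all(vapply(sequences, inherits, logical(1),
                                       "ProteinRecord"))) {
    return(stats::setNames(sequences,
                           vapply(sequences, `[[`, character(1),
                                  "uniprot_id")))
  }
  stop("sequences must be a named character vector, AAStringSet, or list of ",
       "ProteinRecord", call. = FALSE)
}

.compile_records <- function(records, seq_map, model, embedder, emb_cache,
                             protein_mode = NULL) {
  need <- unique(c(records$poi_uniprot, records$e3_uniprot))
  absent <- setdiff(need, names(seq_map))
  if (length(absent) > 0L) {
    stop("no sequence for accession(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(records)), function(i) {
    .compile_sample(records$smiles[i],
                    seq_map[[records$poi_uniprot[i]]],
                    seq_map[[records$e3_uniprot[i]]],
                    if ("label" %in% names(records)) records$label[i] else NA,
                    model, embedder, emb_cache, protein_mode)
  })
}

# ---- forward passes --------------------------------------------------------

# Plain-matrix forward; optionally materializes per-head attention maps.
.forward_plain <- function(sample, model, return_maps = FALSE) {
  p <- model$params
  cfg <- model$config
  act <- .relu
  H <- act(sweep(sample$X %*% p$protac_W1, 2L, drop(p$protac_b1), "+"))
  H <- act(sweep(sample$Anorm %*% (H %*% p$gcn_Wg1) + sample$S %*% p$gcn_We1,
                 2L, drop(p$gcn_bg1), "+"))
  H <- act(sweep(sample$Anorm %*% (H %*% p$gcn_Wg2) + sample$S %*% p$gcn_We2,
                 2L, drop(p$gcn_bg2), "+"))
  Xt <- t(H)
  Xp <- act(sweep(p$poi_A2 %*% act(sweep(p$poi_A1 %*% sample$Xp_raw, 1L,
                                         drop(p$poi_a1), "+")),
                  1L, drop(p$poi_a2), "+"))
  Xe <- act(sweep(p$e3_A2 %*% act(sweep(p$e3_A1 %*% sample$Xe_raw, 1L,
                                        drop(p$e3_a1), "+")),
                  1L, drop(p$e3_a2), "+"))
  tanp <- ptan_tan_parameters(model)
  mh <- tan_multi_head(Xp, Xt, Xe, tanp, return_maps = return_maps)
  fp <- tan_pool(mh$f_sum, cfg$stride)
  h <- act(p$mlp_W1 %*% matrix(fp, ncol = 1L) + drop(p$mlp_b1))
  z <- drop(p$mlp_W2 %*% h + drop(p$mlp_b2))
  m <- max(z)
  logp <- z - (m + log(sum(exp(z - m))))
  list(log_probs = logp, prob1 = exp(logp[2L]),
       label = as.integer(logp[2L] > logp[1L]),
       attention_maps = if (return_maps) mh$maps else NULL)
}

# Tape forward for one sample; returns the loss node.
.forward_tape <- function(tape, sample, P, config, weight = 1) {
  X <- ad_const(tape, sample$X)
  An <- ad_const(tape, sample$Anorm)
  S <- ad_const(tape, sample$S)
  H <- ad_relu(tape, ad_add(tape, ad_mm(tape, X, P$protac_W1), P$protac_b1))
  H <- ad_relu(tape, ad_add(tape, ad_add(
    tape,
    ad_mm(tape, An, ad_mm(tape, H, P$gcn_Wg1)),
    ad_mm(tape, S, P$gcn_We1)), P$gcn_bg1))
  H <- ad_relu(tape, ad_add(tape, ad_add(
    tape,
    ad_mm(tape, An, ad_mm(tape, H, P$gcn_Wg2)),
    ad_mm(tape, S, P$gcn_We2)), P$gcn_bg2))
  Zt <- ad_relu(tape, ad_mm(tape, H, P$tan_W))

  adapt_tape <- function(raw, A1, a1, A2, a2) {
    x <- ad_const(tape, raw)
    z <- ad_relu(tape, ad_add(tape, ad_mm(tape, A1, x), a1))
    ad_relu(tape, ad_add(tape, ad_mm(tape, A2, z), a2))
  }
  Xp <- adapt_tape(sample$Xp_raw, P$poi_A1, P$poi_a1, P$poi_A2, P$poi_a2)
  Xe <- adapt_tape(sample$Xe_raw, P$e3_A1, P$e3_a1, P$e3_A2, P$e3_a2)
  Zp <- ad_relu(tape, ad_mm(tape, ad_transpose(tape, Xp), P$tan_U))
  Ze <- ad_relu(tape, ad_mm(tape, ad_transpose(tape, Xe), P$tan_V))

  f <- NULL
  if (ncol(sample$Xp_raw) == 1L && ncol(sample$Xe_raw) == 1L) {
    # pooled proteins: the POI/E3 Grams are rank one, so
    # f = (zp * ze) * Gt' (q * zp * ze) without forming the full Gram product
    zp <- ad_transpose(tape, Zp)
    ze <- ad_transpose(tape, Ze)
    pe <- ad_hadamard(tape, zp, ze)
    Gt <- ad_gram(tape, Zt)
    for (h in seq_len(config$heads)) {
      v <- ad_hadamard(tape, P[[paste0("tan_q", h)]], pe)
      fh <- ad_hadamard(tape, ad_tmv(tape, Gt, v), pe)
      f <- if (is.null(f)) fh else ad_add(tape, f, fh)
    }
  } else {
    G <- ad_hadamard(tape, ad_hadamard(tape, ad_gram(tape, Zp),
                                       ad_gram(tape, Zt)),
                     ad_gram(tape, Ze))
    for (h in seq_len(config$heads)) {
      fh <- ad_tmv(tape, G, P[[paste0("tan_q", h)]])
      f <- if (is.null(f)) fh else ad_add(tape, f, fh)
    }
  }
  k <- config$kappa; s <- config$stride
  pool_mat <- matrix(0, k %/% s, k)
  for (r in seq_len(k %/% s)) pool_mat[r, ((r - 1L) * s + 1L):(r * s)] <- 1 / s
  fp <- ad_mm(tape, ad_const(tape, pool_mat), f)
  hmlp <- ad_relu(tape, ad_add(tape, ad_mm(tape, P$mlp_W1, fp), P$mlp_b1))
  logits <- ad_add(tape, ad_mm(tape, P$mlp_W2, hmlp), P$mlp_b2)
  loss <- ad_nll(tape, logits, sample$label + 1L)
  if (weight != 1) loss <- ad_scale(tape, loss, weight)
  loss
}

# ---- training --------------------------------------------------------------

.adam_state <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.scores_for <- function(samples, model) {
  vapply(samples, function(s) .forward_plain(s, model)$prob1, numeric(1))
}

#' Train the degradation classifier
#'
#' NLL loss on log-softmax outputs, Adam, mini-batches, early stopping on
#' validation AUROC (best-epoch checkpoint is returned). When no validation
#' set is given, a stratified fraction of the training set (default 10%) is
#' carved out as an internal validation monitor so the test set never drives
#' epoch selection.
#'
#' @param train_records data.frame with columns smiles, poi_uniprot,
#'   e3_uniprot, label (0/1).
#' @param sequences named character vector / AAStringSet / list of
#'   `ProteinRecord` covering every accession in the records.
#' @param val_records optional validation data.frame in the same layout.
#' @param config a `ptan_config`.
#' @param embedder an `Embedder`; defaults to the deterministic stub seeded
#'   from the config.
#' @param verbose print per-epoch progress.
#' @return a fitted `ptan_model` with `history` (epoch, train_loss,
#'   val_auroc) and `best_epoch`.
#' @export
ptan_train <- function(train_records, sequences, val_records = NULL,
                       config = ptan_config(),
                       embedder = stub_embedder(config$seed),
                       verbose = FALSE) {
  if (length(unique(train_records$label)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  seq_map <- .as_record_list(sequences)
  model <- ptan_init_model(config)
  model$embedder_name <- embedder$name

  .with_local_rng(config$seed * 7L + 13L, {
    if (is.null(val_records)) {
      idx_pos <- which(train_records$label == 1L)
      idx_neg <- which(train_records$label == 0L)
      n_val <- function(idx) max(1L, round(config$val_fraction * length(idx)))
      val_idx <- c(sample(idx_pos, n_val(idx_pos)),
                   sample(idx_neg, n_val(idx_neg)))
      val_records <- train_records[val_idx, , drop = FALSE]
      train_records <- train_records[-val_idx, , drop = FALSE]
    }

    raw_props <- t(vapply(unique(train_records$smiles), compute_properties,
                          numeric(9L)))
    model$scaler <- fit_property_scaler(raw_props)

    emb_cache <- new.env(parent = emptyenv())
    train_samples <- .compile_records(train_records, seq_map, model,
                                      embedder, emb_cache)
    val_samples <- .compile_records(val_records, seq_map, model,
                                    embedder, emb_cache)
    val_labels <- vapply(val_samples, `[[`, numeric(1), "label")

    cw <- config$class_weights
    state <- .adam_state(model$params)
    best <- list(auroc = -Inf, params = model$params, epoch = 0L)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_auroc = numeric())
    n <- length(train_samples)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        batch <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        grads <- list()
        for (i in batch) {
          tape <- ad_tape()
          Pn <- lapply(model$params, function(x) ad_param(tape, x))
          w <- if (is.null(cw)) 1 else cw[train_samples[[i]]$label + 1L]
          loss <- .forward_tape(tape, train_samples[[i]], Pn, config, w)
          ad_backward(tape, loss)
          epoch_loss <- epoch_loss + loss$value[1L, 1L]
          for (nm in names(Pn)) {
            g <- Pn[[nm]]$grad
            if (is.null(g)) next
            grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
          }
        }
        grads <- lapply(grads, function(g) g / length(batch))
        upd <- .adam_step(model$params, grads, state, config$lr)
        model$params <- upd$params
        state <- upd$state
      }
      val_auroc <- .auroc(.scores_for(val_samples, model), val_labels)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                  val_auroc = val_auroc))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val AUROC %.4f",
                        epoch, epoch_loss / n, val_auroc))
      }
      if (val_auroc > best$auroc) {
        best <- list(auroc = val_auroc, params = model$params, epoch = epoch)
      }
      if (epoch - best$epoch >= config$patience) break
    }
    model$params <- best$params
    model$best_epoch <- best$epoch
    model$history <- history
  })
  model
}

#' Predict degradation for new triplets
#'
#' @param model fitted `ptan_model`.
#' @param records data.frame with smiles, poi_uniprot, e3_uniprot.
#' @param sequences sequences covering every accession (see [ptan_train()]).
#' @param embedder an `Embedder`; must match the one used in training for
#'   meaningful outputs (defaults to the stub seeded from the config).
#' @param return_maps also return per-head attention maps per sample.
#' @param protein_mode override the config's protein mode (e.g. "token" for
#'   residue-level attribution with a model trained in pooled mode).
#' @return data.frame log_prob0, log_prob1, prob1, label; when `return_maps`,
#'   attribute "attention_maps" holds a list (per sample) of `AttentionMap`
#'   lists (per head).
#' @export
ptan_predict <- function(model, records, sequences,
                         embedder = stub_embedder(model$config$seed),
                         return_maps = FALSE, protein_mode = NULL) {
  seq_map <- .as_record_list(sequences)
  samples <- .compile_records(records, seq_map, model, embedder,
                              new.env(parent = emptyenv()), protein_mode)
  out <- lapply(samples, .forward_plain, model = model,
                return_maps = return_maps)
  res <- data.frame(
    log_prob0 = vapply(out, function(o) o$log_probs[1L], numeric(1)),
    log_prob1 = vapply(out, function(o) o$log_probs[2L], numeric(1)),
    prob1 = vapply(out, function(o) o$prob1, numeric(1)),
    label = vapply(out, function(o) o$label, integer(1)))
  if (return_maps) {
    attr(res, "attention_maps") <- lapply(out, `[[`, "attention_maps")
  }
  res
}

# ---- metrics ---------------------------------------------------------------

.auroc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

#' Classification metrics: accuracy, AUROC, F1, confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); F1 is the harmonic mean of precision
#' TP/(TP+FP) and recall TP/(TP+FN); AUROC is the area under the ROC curve
#' over all thresholds (trapezoidal). Scores are probabilities of class 1;
#' the accuracy/F1 threshold is 0.5.
#'
#' @param scores numeric vector of class-1 probabilities.
#' @param labels 0/1 vector of the same length.
#' @param threshold decision threshold on the probability (default 0.5).
#' @return list(accuracy, auroc, f1, precision, recall, confusion).
#' @export
ptan_evaluate <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("AUROC is undefined for single-class labels", call. = FALSE)
  }
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(accuracy = (tp + tn) / length(labels),
       auroc = .auroc(scores, labels),
       f1 = f1, precision = precision, recall = recall,
       confusion = c(TP = tp, TN = tn, FP = fp, FN = fn))
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The parameter tensors go to `model.rds`; the configuration and scaler are
#' additionally written to a human-readable `config.json` sidecar.
#'
#' @param model a `ptan_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (save) or the restored `ptan_model` (load).
#' @export
ptan_save <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  sidecar <- list(config = unclass(model$config),
                  scaler = model$scaler,
                  embedder = model$embedder_name,
                  best_epoch = model$best_epoch)
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname ptan_save
#' @export
ptan_load <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
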