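ns <- asNamespace("protactan")

make_tiny_model <- function(seed = 5, ...) {
  cfg <- ptan_config(seed = seed, kappa = 16L, stride = 2L, ...)
  m <- ptan_init_model(cfg)
  m$scaler <- list(means = rep(0, 9), stds = rep(1, 9))
  m
}

test_that("protac encoder yields one column per atom", {
  m <- make_tiny_model()
  for (smi in c("CCO", "c1ccccc1CCNC(=O)C", "C")) {
    hg <- featurize_protac(smi, scaler = m$scaler)
    enc <- encode_protac(hg, m$params)
    expect_equal(ncol(enc), hg$num_atoms)
    expect_equal(nrow(enc), 128L)
  }
})

test_that("zero encoder weights give zero output; one-atom closed form holds", {
  m <- make_tiny_model()
  hg <- featurize_protac("CCO", scaler = m$scaler)
  pz <- m$params
  for (nm in grep("^(protac|gcn)", names(pz), value = TRUE)) pz[[nm]][] <- 0
  expect_true(all(encode_protac(hg, pz) == 0))

  # single-atom molecule: self-loop-only GCN step reduces to dense layers
  hg1 <- featurize_protac("C", scaler = m$scaler)
  p <- m$params
  h0 <- pmax(hg1$node_matrix %*% p$protac_W1 + drop(p$protac_b1), 0)
  h1 <- pmax(h0 %*% p$gcn_Wg1 + drop(p$gcn_bg1), 0)   # Anorm = 1, no edges
  h2 <- pmax(h1 %*% p$gcn_Wg2 + drop(p$gcn_bg2), 0)
  expect_equal(encode_protac(hg1, p), t(h2), tolerance = 1e-12)
})

test_that("forward returns normalized log-probs, per-head maps, and is deterministic", {
  ds <- tiny_dataset()
  m <- make_tiny_model()
  rec <- ds$records[1:2, ]
  p1 <- ptan_predict(m, rec, ds$sequences, return_maps = TRUE)
  p2 <- ptan_predict(m, rec, ds$sequences, return_maps = TRUE)
  expect_identical(p1$log_prob1, p2$log_prob1)
  expect_equal(exp(p1$log_prob0) + exp(p1$log_prob1), c(1, 1),
               tolerance = 1e-6)
  maps <- attr(p1, "attention_maps")[[1]]
  expect_length(maps, m$config$heads)
  n_atoms <- build_molecular_graph(rec$smiles[1])$num_atoms
  expect_equal(dim(maps[[1]]$tensor)[2], n_atoms)
})

test_that("predictions are invariant to atom-index permutation", {
  ds <- tiny_dataset()
  m <- make_tiny_model()
  smi <- "c1ccncc1CCOCCC1CCNCC1"
  # a permuted atom ordering of the same molecule, written from a different
  # starting atom
  smi_perm <- "C1(CCOCCc2cccnc2)CCNCC1"
  expect_equal(canonical_smiles(smi), canonical_smiles(smi_perm))
  rec <- data.frame(smiles = c(smi, smi_perm),
                    poi_uniprot = "POI01", e3_uniprot = "E3L01")
  p <- ptan_predict(m, rec, ds$sequences)
  expect_equal(p$log_prob1[1], p$log_prob1[2], tolerance = 1e-5)
  expect_equal(p$log_prob0[1], p$log_prob0[2], tolerance = 1e-5)
})

test_that("tape forward agrees with the plain forward pass", {
  ds <- tiny_dataset()
  for (mode in c("pooled", "token")) {
    m <- make_tiny_model(protein_mode = mode)
    emb <- stub_embedder(m$config$seed)
    seq_map <- ns$.as_record_list(ds$sequences)
    rec <- ds$records[3, ]
    rec$label <- 1L
    samp <- ns$.compile_records(rec, seq_map, m, emb,
                                new.env(parent = emptyenv()))[[1]]
    tape <- ns$ad_tape()
    Pn <- lapply(m$params, function(x) ns$ad_param(tape, x))
    loss <- ns$.forward_tape(tape, samp, Pn, m$config)
    plain <- ns$.forward_plain(samp, m)
    expect_equal(drop(loss$log_probs), plain$log_probs, tolerance = 1e-10)
  }
})

test_that("autodiff gradient of the full model matches finite differences", {
  ds <- tiny_dataset()
  m <- make_tiny_model()
  emb <- stub_embedder(m$config$seed)
  seq_map <- ns$.as_record_list(ds$sequences)
  rec <- ds$records[1, ]; rec$label <- 1L
  samp <- ns$.compile_records(rec, seq_map, m, emb,
                              new.env(parent = emptyenv()))[[1]]
  loss_at <- function(params) {
    tape <- ns$ad_tape()
    Pn <- lapply(params, function(x) ns$ad_param(tape, x))
    ns$.forward_tape(tape, samp, Pn, m$config)$value[1, 1]
  }
  tape <- ns$ad_tape()
  Pn <- lapply(m$params, function(x) ns$ad_param(tape, x))
  loss <- ns$.forward_tape(tape, samp, Pn, m$config)
  ns$ad_backward(tape, loss)
  eps <- 1e-5
  for (nm in c("tan_q1", "tan_U", "mlp_W2", "gcn_We1", "poi_A2")) {
    idx <- which(Pn[[nm]]$grad != 0)[1]
    if (is.na(idx)) next
    pp <- m$params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
    pm <- m$params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    ad <- Pn[[nm]]$grad[idx]
    expect_equal(ad, fd, tolerance = 1e-3)
  }
})

test_that("training history respects bounds and best-epoch selection", {
  ds <- tiny_dataset(n = 30, seed = 9)
  cfg <- ptan_config(seed = 2, kappa = 16L, max_epochs = 4L)
  m <- ptan_train(ds$records, ds$sequences, config = cfg)
  expect_lte(nrow(m$history), 4L)
  expect_equal(m$history$val_auroc[m$best_epoch],
               max(m$history$val_auroc))

  single <- ds$records
  single$label <- 1L
  expect_error(ptan_train(single, ds$sequences, config = cfg),
               "both classes")
})

test_that("checkpoints round-trip to identical predictions", {
  ds <- tiny_dataset(n = 30, seed = 9)
  cfg <- ptan_config(seed = 2, kappa = 16L, max_epochs = 2L)
  m <- ptan_train(ds$records, ds$sequences, config = cfg)
  dir <- withr::local_tempdir()
  ptan_save(m, dir)
  m2 <- ptan_load(dir)
  rec <- ds$records[1:4, ]
  expect_identical(ptan_predict(m, rec, ds$sequences),
                   ptan_predict(m2, rec, ds$sequences))
  expect_true(file.exists(file.path(dir, "config.json")))
})

test_that("metrics match hand-computed confusion tables", {
  # TP=3 TN=2 FP=1 FN=2
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.45)
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0)
  met <- ptan_evaluate(scores, labels)
  expect_equal(unname(met$confusion), c(3L, 2L, 1L, 2L))
  expect_equal(met$accuracy, 5 / 8)
  expect_equal(met$precision, 0.75)
  expect_equal(met$recall, 0.6)
  expect_equal(met$f1, 2 / 3, tolerance = 1e-12)

  perfect <- ptan_evaluate(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$f1, 1)

  expect_error(ptan_evaluate(c(0.1, 0.9), c(1, 1)), "single-class")
})

test_that("AUROC agrees with the rank-based oracle and is ~0.5 under null", {
  set.seed(31)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.5)
  met <- ptan_evaluate(scores, labels)
  expect_equal(met$auroc, oracle_auroc(scores, labels), tolerance = 1e-10)

  scores2 <- runif(2000)
  labels2 <- rbinom(2000, 1, 0.5)
  expect_equal(ptan_evaluate(scores2, labels2)$auroc, 0.5, tolerance = 0.05)
})
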