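# Brute-force oracles and tiny fixtures shared by the tests. The oracles
# implement the attention and fusion definitions as literal loops over
# substructure triplets, independent of the vectorized implementation.

relu_ref <- function(x) pmax(x, 0)

# A[i,j,l] = q' (sigma(U' xp_i) * sigma(W' xt_j) * sigma(V' xe_l))
oracle_attention_map <- function(Xp, Xt, Xe, params, head) {
  Zp <- relu_ref(crossprod(Xp, params$U))
  Zt <- relu_ref(crossprod(Xt, params$W))
  Ze <- relu_ref(crossprod(Xe, params$V))
  q <- params$q_heads[[head]]
  A <- array(0, dim = c(nrow(Zp), nrow(Zt), nrow(Ze)))
  for (i in seq_len(nrow(Zp))) {
    for (j in seq_len(nrow(Zt))) {
      for (l in seq_len(nrow(Ze))) {
        A[i, j, l] <- sum(q * Zp[i, ] * Zt[j, ] * Ze[l, ])
      }
    }
  }
  A
}

# f[k] = sum_{i,j,l} A[i,j,l] Zp[i,k] Zt[j,k] Ze[l,k]
oracle_fusion <- function(Xp, Xt, Xe, A, params) {
  Zp <- relu_ref(crossprod(Xp, params$U))
  Zt <- relu_ref(crossprod(Xt, params$W))
  Ze <- relu_ref(crossprod(Xe, params$V))
  kappa <- ncol(Zp)
  f <- numeric(kappa)
  for (k in seq_len(kappa)) {
    s <- 0
    for (i in seq_len(nrow(Zp))) {
      for (j in seq_len(nrow(Zt))) {
        for (l in seq_len(nrow(Ze))) {
          s <- s + A[i, j, l] * Zp[i, k] * Zt[j, k] * Ze[l, k]
        }
      }
    }
    f[k] <- s
  }
  f
}

# Independent bilinear attention: map and fusion over two entities only
oracle_bilinear <- function(Xa, Xb, params, head) {
  Za <- relu_ref(crossprod(Xa, params$U))
  Zb <- relu_ref(crossprod(Xb, params$W))
  q <- params$q_heads[[head]]
  alpha <- nrow(Za); beta <- nrow(Zb); kappa <- ncol(Za)
  M <- matrix(0, alpha, beta)
  for (i in seq_len(alpha)) {
    for (j in seq_len(beta)) {
      M[i, j] <- sum(q * Za[i, ] * Zb[j, ])
    }
  }
  f <- numeric(kappa)
  for (k in seq_len(kappa)) {
    s <- 0
    for (i in seq_len(alpha)) {
      for (j in seq_len(beta)) {
        s <- s + M[i, j] * Za[i, k] * Zb[j, k]
      }
    }
    f[k] <- s
  }
  list(map = M, f = f)
}

random_tan_instance <- function(seed) {
  set.seed(seed)
  dims <- sample(1:5, 7, replace = TRUE)  # d_p d_t d_e alpha beta gamma kappa
  params <- tan_parameters(dims[1], dims[2], dims[3], kappa = dims[7],
                           heads = 2, seed = seed + 1000)
  list(Xp = matrix(rnorm(dims[1] * dims[4]), dims[1]),
       Xt = matrix(rnorm(dims[2] * dims[5]), dims[2]),
       Xe = matrix(rnorm(dims[3] * dims[6]), dims[3]),
       params = params)
}

# Small labeled dataset + sequences for model-level tests
tiny_dataset <- function(n = 24, seed = 42) {
  generate_dataset(n, seed = seed,
                   signal = signal_spec(bayes_error = 0,
                                        implicit_fraction = 0))
}

# Mann-Whitney AUROC, independent of the ROC-curve implementation
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
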