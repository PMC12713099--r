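# Ternary attention network (TAN). Scores every (POI substructure, PROTAC
# atom, E3 substructure) triplet with a low-rank three-way attention map and
# fuses the three entities into a joint representation, reusing the same
# projection matrices so the fusion layer adds no parameters. Bilinear
# attention (BAN) is the two-entity special case obtained by collapsing the
# third axis.
#
# Shapes: Xp is D_p x alpha (POI), Xt is D_t x beta (PROTAC), Xe is D_e x
# gamma (E3). Projections U (D_p x kappa), W (D_t x kappa), V (D_e x kappa)
# are shared across heads; each head owns only its kappa-vector q.

.relu <- function(x) pmax(x, 0)

#' Initialize ternary attention parameters
#'
#' @param d_p,d_t,d_e input widths of the POI, PROTAC and E3 representations.
#' @param kappa latent width of the shared projections (default 256).
#' @param heads number of attention heads (default 2); each head adds only
#'   one kappa-vector q.
#' @param seed integer seed.
#' @return object of class `TanParameters`: list(U, W, V, q_heads, kappa,
#'   heads).
#' @export
tan_parameters <- function(d_p, d_t, d_e, kappa = 256L, heads = 2L,
                           seed = 0L) {
  stopifnot(heads >= 1L, kappa >= 1L)
  .with_local_rng(seed, {
    structure(
      list(
        U = matrix(stats::rnorm(d_p * kappa, sd = sqrt(1 / d_p)), nrow = d_p),
        W = matrix(stats::rnorm(d_t * kappa, sd = sqrt(1 / d_t)), nrow = d_t),
        V = matrix(stats::rnorm(d_e * kappa, sd = sqrt(1 / d_e)), nrow = d_e),
        q_heads = lapply(seq_len(heads), function(h) {
          stats::rnorm(kappa, sd = sqrt(1 / kappa))
        }),
        kappa = as.integer(kappa),
        heads = as.integer(heads)
      ),
      class = "TanParameters")
  })
}

#' Count trainable TAN parameters
#'
#' kappa * (d_p + d_t + d_e) for the shared projections plus kappa per head.
#'
#' @param params a `TanParameters`, or missing if dims given explicitly.
#' @param d_p,d_t,d_e,kappa,heads explicit dimensions (ignored when `params`
#'   is supplied).
#' @return integer parameter count.
#' @export
tan_param_count <- function(params = NULL, d_p, d_t, d_e, kappa, heads) {
  if (!is.null(params)) {
    d_p <- nrow(params$U); d_t <- nrow(params$W); d_e <- nrow(params$V)
    kappa <- params$kappa; heads <- params$heads
  }
  as.integer(kappa * (d_p + d_t + d_e) + heads * kappa)
}

.tan_project <- function(Xp, Xt, Xe, params, activation) {
  if (nrow(Xp) != nrow(params$U)) {
    stop("POI axis mismatch: representation width ", nrow(Xp),
         " vs projection input ", nrow(params$U), call. = FALSE)
  }
  if (nrow(Xt) != nrow(params$W)) {
    stop("PROTAC axis mismatch: representation width ", nrow(Xt),
         " vs projection input ", nrow(params$W), call. = FALSE)
  }
  if (nrow(Xe) != nrow(params$V)) {
    stop("E3 axis mismatch: representation width ", nrow(Xe),
         " vs projection input ", nrow(params$V), call. = FALSE)
  }
  list(Zp = activation(crossprod(Xp, params$U)),
       Zt = activation(crossprod(Xt, params$W)),
       Ze = activation(crossprod(Xe, params$V)))
}

# Attention map from projected representations:
# A[i,j,l] = sum_k q[k] Zp[i,k] Zt[j,k] Ze[l,k]
.tan_map_core <- function(Zp, Zt, Ze, q) {
  alpha <- nrow(Zp); beta <- nrow(Zt); gamma <- nrow(Ze)
  QZp <- sweep(Zp, 2L, q, "*")
  # einsum ik,jk->ijk, rows ordered i-major
  M2 <- QZp[rep(seq_len(alpha), each = beta), , drop = FALSE] *
    Zt[rep(seq_len(beta), times = alpha), , drop = FALSE]
  A_flat <- M2 %*% t(Ze)                       # (alpha*beta) x gamma
  aperm(array(A_flat, dim = c(beta, alpha, gamma)), c(2L, 1L, 3L))
}

# Fusion from an explicit attention map:
# f[k] = sum_{i,j,l} A[i,j,l] Zp[i,k] Zt[j,k] Ze[l,k]
.tan_fusion_core <- function(A, Zp, Zt, Ze) {
  alpha <- nrow(Zp); gamma <- nrow(Ze); kappa <- ncol(Zp)
  A2 <- matrix(A, nrow = alpha)                # alpha x (beta*gamma), j inner
  P <- crossprod(Zp, A2)                       # kappa x (beta*gamma)
  Parr <- array(P, dim = c(kappa, nrow(Zt), gamma))
  R <- matrix(0, kappa, gamma)
  for (l in seq_len(gamma)) {
    R[, l] <- colSums(Zt * t(matrix(Parr[, , l], kappa, nrow(Zt))))
  }
  rowSums(R * t(Ze))
}

#' Compute the ternary attention map of one head
#'
#' A[i,j,l] = q' (sigma(U' xp_i) * sigma(W' xt_j) * sigma(V' xe_l)), computed
#' in tensor form over all (i, j, l) at once.
#'
#' @param Xp,Xt,Xe entity representations: D_p x alpha, D_t x beta,
#'   D_e x gamma.
#' @param params a `TanParameters`.
#' @param head head index (1-based).
#' @param activation nonlinearity sigma (default ReLU).
#' @return object of class `AttentionMap`: list(tensor = alpha x beta x gamma
#'   array, head_index).
#' @export
tan_attention_map <- function(Xp, Xt, Xe, params, head = 1L,
                              activation = .relu) {
  Z <- .tan_project(Xp, Xt, Xe, params, activation)
  tensor <- .tan_map_core(Z$Zp, Z$Zt, Z$Ze, params$q_heads[[head]])
  structure(list(tensor = tensor, head_index = as.integer(head)),
            class = "AttentionMap")
}

#' Ternary fusion of one head
#'
#' Attention-weighted triple product reusing the shared projections;
#' introduces no new parameters. When `A` is omitted it is computed from the
#' inputs.
#'
#' @inheritParams tan_attention_map
#' @param A optional `AttentionMap` produced from the same inputs/params.
#' @return numeric kappa-vector f.
#' @export
tan_fusion <- function(Xp, Xt, Xe, params, head = 1L, A = NULL,
                       activation = .relu) {
  Z <- .tan_project(Xp, Xt, Xe, params, activation)
  tensor <- if (is.null(A)) {
    .tan_map_core(Z$Zp, Z$Zt, Z$Ze, params$q_heads[[head]])
  } else {
    stopifnot(inherits(A, "AttentionMap"))
    A$tensor
  }
  .tan_fusion_core(tensor, Z$Zp, Z$Zt, Z$Ze)
}

# Gram-matrix shortcut for the fused vector, never materializing A:
# f = t(Gp * Gt * Ge) q with G* the kappa x kappa Gram matrices of the
# projected representations. Algebraically identical to tan_fusion(); used
# on the training path and checked against the loop oracle in tests.
.tan_fusion_gram <- function(Zp, Zt, Ze, q) {
  G <- crossprod(Zp) * crossprod(Zt) * crossprod(Ze)
  drop(crossprod(G, q))
}

#' Multi-head ternary attention
#'
#' Computes every head's fusion with the shared projections and sums them;
#' returns the per-head attention maps for interpretability.
#'
#' @inheritParams tan_attention_map
#' @param return_maps set FALSE to skip materializing the 3D maps.
#' @return list(f_sum = kappa-vector, maps = list of `AttentionMap`).
#' @export
tan_multi_head <- function(Xp, Xt, Xe, params, activation = .relu,
                           return_maps = TRUE) {
  Z <- .tan_project(Xp, Xt, Xe, params, activation)
  f_sum <- numeric(params$kappa)
  maps <- list()
  for (h in seq_len(params$heads)) {
    q <- params$q_heads[[h]]
    f_sum <- f_sum + .tan_fusion_gram(Z$Zp, Z$Zt, Z$Ze, q)
    if (return_maps) {
      maps[[h]] <- structure(
        list(tensor = .tan_map_core(Z$Zp, Z$Zt, Z$Ze, q),
             head_index = h),
        class = "AttentionMap")
    }
  }
  list(f_sum = f_sum, maps = maps)
}

#' 1D average pooling of the joint representation
#'
#' Non-overlapping window means of width `stride`.
#'
#' @param f numeric kappa-vector.
#' @param stride window width s; must divide length(f).
#' @return numeric vector of length kappa / s.
#' @export
tan_pool <- function(f, stride) {
  k <- length(f)
  if (stride < 1L || k %% stride != 0L) {
    stop("stride ", stride, " does not divide the representation length ",
         k, call. = FALSE)
  }
  colMeans(matrix(f, nrow = stride))
}

#' Bilinear (two-entity) reduction of the TAN
#'
#' Runs the ternary machinery with the third entity collapsed to a single
#' substructure whose projected representation is forced to ones, which
#' reproduces bilinear attention exactly: map[i,j] = q' (sigma(U' xa_i) *
#' sigma(W' xb_j)) and the corresponding bilinear fusion. Used for the
#' pairwise model variant.
#'
#' @param Xa,Xb entity representations D_a x alpha, D_b x beta (projected
#'   through U and W of `params`).
#' @param params a `TanParameters`.
#' @param head head index.
#' @param activation nonlinearity (default ReLU).
#' @return list(map = alpha x beta matrix, f = kappa-vector).
#' @export
tan_bilinear_reduction <- function(Xa, Xb, params, head = 1L,
                                   activation = .relu) {
  Za <- activation(crossprod(Xa, params$U))
  Zb <- activation(crossprod(Xb, params$W))
  Ze <- matrix(1, nrow = 1L, ncol = params$kappa)    # degenerate third axis
  q <- params$q_heads[[head]]
  tensor <- .tan_map_core(Za, Zb, Ze, q)
  f <- .tan_fusion_core(tensor, Za, Zb, Ze)
  list(map = matrix(tensor[, , 1L], nrow(Za), nrow(Zb)), f = f)
}
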