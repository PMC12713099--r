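# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records nodes in creation order; ad_backward() walks it in reverse,
# accumulating gradients into parameter leaves. Only the handful of operations
# the degradation model needs are implemented (matmul, bias add, Hadamard
# product, ReLU, transpose, Gram matrix, scaling, log-softmax NLL). Every
# op's gradient is covered by finite-difference tests.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 64L)
  tape$n <- 0L
  tape
}

ad_push <- function(tape, value, parents = list(), backward = NULL,
                    track = TRUE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$track <- track
  if (track) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      length(tape$nodes) <- 2L * length(tape$nodes)
    }
    tape$nodes[[tape$n]] <- node
  }
  node
}

ad_accum <- function(node, g) {
  if (!node$track) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' @noRd
ad_const <- function(tape, x) {
  ad_push(tape, as.matrix(x), track = FALSE)
}

#' @noRd
ad_param <- function(tape, x) {
  ad_push(tape, as.matrix(x), track = TRUE)
}

# a %*% b
ad_mm <- function(tape, a, b) {
  ad_push(tape, a$value %*% b$value, list(a, b), function(node) {
    g <- node$grad
    if (a$track) ad_accum(a, tcrossprod(g, b$value))
    if (b$track) ad_accum(b, crossprod(a$value, g))
  })
}

# t(a) %*% q for a column vector q (fused, no transpose materialized)
ad_tmv <- function(tape, a, q) {
  ad_push(tape, crossprod(a$value, q$value), list(a, q), function(node) {
    g <- node$grad
    if (a$track) ad_accum(a, tcrossprod(q$value, g))
    if (q$track) ad_accum(q, a$value %*% g)
  })
}

# a + b; b may be a column vector (broadcast across columns of a) or a row
# vector (broadcast across rows of a)
ad_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  mode <- if (identical(dim(av), dim(bv))) "full"
          else if (ncol(bv) == 1L && nrow(bv) == nrow(av)) "col"
          else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) "row"
          else stop("ad_add: incompatible shapes", call. = FALSE)
  val <- switch(mode,
    full = av + bv,
    col = av + bv[, rep(1L, ncol(av)), drop = FALSE],
    row = sweep(av, 2L, drop(bv), "+"))
  ad_push(tape, val, list(a, b), function(node) {
    g <- node$grad
    ad_accum(a, g)
    ad_accum(b, switch(mode,
      full = g,
      col = matrix(rowSums(g), ncol = 1L),
      row = matrix(colSums(g), nrow = 1L)))
  })
}

ad_relu <- function(tape, a) {
  mask <- a$value > 0
  ad_push(tape, a$value * mask, list(a), function(node) {
    ad_accum(a, node$grad * mask)
  })
}

# elementwise product, identical shapes
ad_hadamard <- function(tape, a, b) {
  ad_push(tape, a$value * b$value, list(a, b), function(node) {
    g <- node$grad
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  })
}

ad_transpose <- function(tape, a) {
  ad_push(tape, t(a$value), list(a), function(node) {
    ad_accum(a, t(node$grad))
  })
}

# t(A) %*% A (Gram matrix over columns)
ad_gram <- function(tape, a) {
  ad_push(tape, crossprod(a$value), list(a), function(node) {
    g <- node$grad
    ad_accum(a, a$value %*% (g + t(g)))
  })
}

ad_scale <- function(tape, a, s) {
  ad_push(tape, a$value * s, list(a), function(node) {
    ad_accum(a, node$grad * s)
  })
}

# Negative log-likelihood of class `label` (1-based) under log-softmax of a
# logit column vector. Returns a 1x1 node; log-probs kept as an attribute.
ad_nll <- function(tape, logits, label) {
  z <- logits$value
  m <- max(z)
  lse <- m + log(sum(exp(z - m)))
  logp <- z - lse
  loss <- -logp[label, 1L]
  node <- ad_push(tape, matrix(loss, 1L, 1L), list(logits), function(node) {
    g <- node$grad[1L, 1L]
    soft <- exp(logp)
    soft[label, 1L] <- soft[label, 1L] - 1
    ad_accum(logits, g * soft)
  })
  node$log_probs <- logp
  node
}

#' @noRd
ad_backward <- function(tape, node) {
  node$grad <- matrix(1, nrow(node$value), ncol(node$value))
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}
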