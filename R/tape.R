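# Tape-based reverse-mode automatic differentiation on dense matrices.
#
# Every value is a base-R numeric matrix; a node records its value, its
# parent nodes and a backward closure that expresses parent gradients in
# terms of the same node operations. Because backward passes build ordinary
# graph nodes, nn_grad() output is itself differentiable, which is what the
# WGAN gradient penalty needs (a second backward through an input-gradient).
#
# Internal: not exported. Operations cover exactly what the generator,
# discriminator (conv -> residual blocks -> capsule routing -> linear) and
# the penalty term require.

.tape <- new.env(parent = emptyenv())
.tape$counter <- 0L

node_key <- function(n) as.character(n$id)

new_node <- function(value, parents = list(), bw = NULL) {
  stopifnot(is.matrix(value))
  n <- new.env(parent = emptyenv())
  .tape$counter <- .tape$counter + 1L
  n$id <- .tape$counter
  n$value <- value
  n$parents <- parents
  n$bw <- bw
  n$requires <- if (length(parents)) {
    any(vapply(parents, function(p) p$requires, logical(1)))
  } else {
    FALSE
  }
  class(n) <- "nn_node"
  n
}

as_mat <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.null(dim(x))) return(matrix(as.numeric(x), nrow = 1))
  stop("cannot coerce object with dim of length ", length(dim(x)), " to matrix")
}

# leaf: differentiable parameter / input
nn_leaf <- function(value) {
  n <- new_node(as_mat(value))
  n$requires <- TRUE
  n
}

# constant: gradient never flows into it
nn_const <- function(value) new_node(as_mat(value))

nn_value <- function(n) n$value

## ---- primitive operations -------------------------------------------------

nn_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

nn_sub <- function(a, b) {
  new_node(a$value - b$value, list(a, b), function(g) list(g, nn_smul(g, -1)))
}

nn_mul <- function(a, b) {
  new_node(a$value * b$value, list(a, b),
           function(g) list(nn_mul(g, b), nn_mul(g, a)))
}

# multiply / add a plain numeric scalar (treated as a constant)
nn_smul <- function(a, k) {
  new_node(a$value * k, list(a), function(g) list(nn_smul(g, k)))
}

nn_sadd <- function(a, k) {
  new_node(a$value + k, list(a), function(g) list(g))
}

nn_pow <- function(a, p) {
  new_node(a$value^p, list(a),
           function(g) list(nn_mul(g, nn_smul(nn_pow(a, p - 1), p))))
}

nn_exp <- function(a) {
  out <- new_node(exp(a$value), list(a), NULL)
  out$bw <- function(g) list(nn_mul(g, out))
  out
}

nn_matmul <- function(a, b) {
  new_node(a$value %*% b$value, list(a, b),
           function(g) list(nn_matmul(g, nn_t(b)), nn_matmul(nn_t(a), g)))
}

nn_t <- function(a) {
  new_node(t(a$value), list(a), function(g) list(nn_t(g)))
}

nn_lrelu <- function(a, slope = 0.2) {
  mask <- ifelse(a$value > 0, 1, slope)
  new_node(a$value * mask, list(a),
           function(g) list(nn_mul(g, nn_const(mask))))
}

nn_reshape <- function(a, nr, nc) {
  or <- nrow(a$value)
  oc <- ncol(a$value)
  stopifnot(or * oc == nr * nc)
  v <- a$value
  dim(v) <- c(nr, nc)
  new_node(v, list(a), function(g) list(nn_reshape(g, or, oc)))
}

scatter_val <- function(m, idx, n) {
  rs <- rowsum(m, group = idx)
  out <- matrix(0, n, ncol(m))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

nn_gather_rows <- function(a, idx) {
  n <- nrow(a$value)
  new_node(a$value[idx, , drop = FALSE], list(a),
           function(g) list(nn_scatter_rows(g, idx, n)))
}

# scatter-add rows of a into an n-row zero matrix at positions idx
nn_scatter_rows <- function(a, idx, n) {
  new_node(scatter_val(a$value, idx, n), list(a),
           function(g) list(nn_gather_rows(g, idx)))
}

nn_gather_cols <- function(a, idx) {
  n <- ncol(a$value)
  new_node(a$value[, idx, drop = FALSE], list(a),
           function(g) list(nn_scatter_cols(g, idx, n)))
}

nn_scatter_cols <- function(a, idx, n) {
  new_node(t(scatter_val(t(a$value), idx, n)), list(a),
           function(g) list(nn_gather_cols(g, idx)))
}

## ---- composed helpers (all built from primitives; stay differentiable) ----

nn_rowsum <- function(a) nn_matmul(a, nn_const(matrix(1, ncol(a$value), 1)))

nn_colsum <- function(a) nn_matmul(nn_const(matrix(1, 1, nrow(a$value))), a)

nn_repcol <- function(a, k) nn_matmul(a, nn_const(matrix(1, 1, k)))

nn_reprow <- function(a, n) nn_matmul(nn_const(matrix(1, n, 1)), a)

nn_sum <- function(a) nn_colsum(nn_rowsum(a))

nn_mean <- function(a) nn_smul(nn_sum(a), 1 / length(a$value))

# row-wise softmax; the per-row max shift is a constant (softmax is exactly
# invariant to it, so values and gradients are both unchanged)
nn_softmax_rows <- function(a) {
  k <- ncol(a$value)
  m <- matrix(apply(a$value, 1, max), nrow(a$value), k)
  e <- nn_exp(nn_sub(a, nn_const(m)))
  nn_mul(e, nn_pow(nn_repcol(nn_rowsum(e), k), -1))
}

# row-wise capsule squash: v = (|s|^2 / (1 + |s|^2)) * s / |s|
# eps guards the norm division; a zero row maps to a zero row.
nn_squash_rows <- function(a, eps = 1e-8) {
  n2 <- nn_rowsum(nn_mul(a, a))
  norm <- nn_pow(nn_sadd(n2, eps), 0.5)
  scale <- nn_mul(n2, nn_pow(nn_mul(nn_sadd(n2, 1), norm), -1))
  nn_mul(a, nn_repcol(scale, ncol(a$value)))
}

# stack node blocks vertically (used to assemble per-capsule vote blocks)
nn_vstack <- function(nodes) {
  rows <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  new_node(do.call(rbind, lapply(nodes, nn_value)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) nn_gather_rows(g, starts[i]:ends[i]))
  })
}

## ---- backward pass --------------------------------------------------------

# iterative post-order topological sort restricted to gradient-requiring nodes
topo_sort <- function(root) {
  if (!root$requires) return(list())
  topo <- vector("list", 256L)
  nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- vector("list", 256L)
  stack[[1L]] <- list(node = root, i = 0L)
  ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    node <- fr$node
    parents <- node$parents
    advanced <- FALSE
    i <- fr$i
    while (i < length(parents)) {
      i <- i + 1L
      p <- parents[[i]]
      if (p$requires && is.null(seen[[node_key(p)]])) {
        seen[[node_key(p)]] <- TRUE
        stack[[ns]]$i <- i
        ns <- ns + 1L
        if (ns > length(stack)) length(stack) <- 2L * length(stack)
        stack[[ns]] <- list(node = p, i = 0L)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      nt <- nt + 1L
      if (nt > length(topo)) length(topo) <- 2L * length(topo)
      topo[[nt]] <- node
      ns <- ns - 1L
    }
  }
  topo[seq_len(nt)]
}

# gradients of scalar node `out` with respect to list of nodes `wrt`;
# returns a list of nodes (differentiable again)
nn_grad <- function(out, wrt) {
  stopifnot(length(out$value) == 1L)
  grads <- new.env(parent = emptyenv())
  grads[[node_key(out)]] <- nn_const(matrix(1, 1, 1))
  topo <- topo_sort(out)
  for (node in rev(topo)) {
    g <- grads[[node_key(node)]]
    if (is.null(g) || is.null(node$bw)) next
    pg <- node$bw(g)
    parents <- node$parents
    for (i in seq_along(parents)) {
      p <- parents[[i]]
      if (!p$requires || is.null(pg[[i]])) next
      key <- node_key(p)
      cur <- grads[[key]]
      grads[[key]] <- if (is.null(cur)) pg[[i]] else nn_add(cur, pg[[i]])
    }
  }
  lapply(wrt, function(w) {
    g <- grads[[node_key(w)]]
    if (is.null(g)) nn_const(matrix(0, nrow(w$value), ncol(w$value))) else g
  })
}
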