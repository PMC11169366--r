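# Minimal reverse-mode differentiation tape over 4-d (h, w, c, n) arrays.
# Forward evaluation is eager; every op pushes a node holding its value and a
# closure that maps the node's output gradient to gradients for its parents.
# Parameter gradients are accumulated directly into the model's grad
# environment by the closures.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$val <- list()
  tp$parents <- list()
  tp$back <- list()
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = integer(), back = NULL) {
  tp$n <- tp$n + 1L
  tp$val[[tp$n]] <- value
  tp$parents[[tp$n]] <- parents
  tp$back[[tp$n]] <- back
  tp$n
}

tp_value <- function(tp, id) {
  force(id)
  tp$val[[id]]
}

acc_grad <- function(m, name, g) {
  if (is.null(m$grad[[name]])) m$grad[[name]] <- g else m$grad[[name]] <- m$grad[[name]] + g
  invisible(NULL)
}

tp_input <- function(tp, x) tp_push(tp, x)

tp_conv <- function(tp, id, m, name, stride = 1L, pad = 0L) {
  x <- tp$val[[id]]
  W <- m$par[[paste0(name, ".W")]]
  b <- m$par[[paste0(name, ".b")]]
  y <- cpp_conv2d_fw(x, W, b, as.integer(stride), as.integer(pad))
  tp_push(tp, y, id, function(g) {
    r <- cpp_conv2d_bw(x, W, g, as.integer(stride), as.integer(pad))
    acc_grad(m, paste0(name, ".W"), r$gw)
    acc_grad(m, paste0(name, ".b"), r$gb)
    list(r$gx)
  })
}

tp_upconv <- function(tp, id, m, name) {
  x <- tp$val[[id]]
  W <- m$par[[paste0(name, ".W")]]
  b <- m$par[[paste0(name, ".b")]]
  y <- cpp_upconv2_fw(x, W, b)
  tp_push(tp, y, id, function(g) {
    r <- cpp_upconv2_bw(x, W, g)
    acc_grad(m, paste0(name, ".W"), r$gw)
    acc_grad(m, paste0(name, ".b"), r$gb)
    list(r$gx)
  })
}

tp_dwconv <- function(tp, id, m, name) {
  x <- tp$val[[id]]
  W <- m$par[[paste0(name, ".W")]]
  b <- m$par[[paste0(name, ".b")]]
  y <- cpp_dwconv3_fw(x, W, b)
  tp_push(tp, y, id, function(g) {
    r <- cpp_dwconv3_bw(x, W, g)
    acc_grad(m, paste0(name, ".W"), r$gw)
    acc_grad(m, paste0(name, ".b"), r$gb)
    list(r$gx)
  })
}

tp_avgpool <- function(tp, id) {
  x <- tp$val[[id]]
  d <- dim(x)
  y <- cpp_avgpool2_fw(x)
  tp_push(tp, y, id, function(g) list(cpp_avgpool2_bw(g, d[1L], d[2L])))
}

tp_prelu <- function(tp, id, m, name) {
  x <- tp$val[[id]]
  a <- m$par[[paste0(name, ".a")]]
  y <- cpp_prelu_fw(x, a)
  tp_push(tp, y, id, function(g) {
    r <- cpp_prelu_bw(x, a, g)
    acc_grad(m, paste0(name, ".a"), r$ga)
    list(r$gx)
  })
}

tp_sigmoid <- function(tp, id) {
  y <- cpp_sigmoid_fw(tp$val[[id]])
  tp_push(tp, y, id, function(g) list(g * y * (1 - y)))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  y <- tp$val[[a]] + tp$val[[b]]
  tp_push(tp, y, c(a, b), function(g) list(g, g))
}

# x: (h, w, c, n); v: (1, 1, c, n) broadcast over positions (additive)
tp_add_chan <- function(tp, a, b) {
  force(a); force(b)
  x <- tp$val[[a]]
  v <- tp$val[[b]]
  tp_push(tp, cpp_bcast_fw(x, v, 0L), c(a, b), function(g)
    list(g, cpp_chan_sum(g)))
}

# x: (h, w, c, n) scaled per channel by gate (1, 1, c, n)
tp_scale_chan <- function(tp, a, b) {
  force(a); force(b)
  x <- tp$val[[a]]
  v <- tp$val[[b]]
  tp_push(tp, cpp_bcast_fw(x, v, 1L), c(a, b), function(g)
    list(cpp_bcast_fw(g, v, 1L), cpp_chan_dot(g, x)))
}

tp_gap <- function(tp, id) {
  x <- tp$val[[id]]
  d <- dim(x)
  hw <- d[1L] * d[2L]
  y <- cpp_chan_sum(x) / hw
  dim(y) <- c(1L, 1L, d[3L], d[4L])
  tp_push(tp, y, id, function(g)
    list(cpp_chan_spread(g, d[1L], d[2L], 1 / hw)))
}

tp_concat <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp$val[[i]])
  d1 <- dim(vals[[1L]])
  cs <- vapply(vals, function(v) dim(v)[3L], integer(1))
  y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3L]), ] <- v
    at <- at + dim(v)[3L]
  }
  tp_push(tp, y, ids, function(g) {
    out <- vector("list", length(ids))
    at <- 0L
    for (k in seq_along(ids)) {
      out[[k]] <- g[, , at + seq_len(cs[k]), , drop = FALSE]
      at <- at + cs[k]
    }
    out
  })
}

# Replicate per-channel logits (1, 1, c, n) across k^2 kernel taps to
# (1, 1, k2*c, n), tap index fastest (matching the SEKG theta layout).
tp_rep_taps <- function(tp, id, k2 = 9L) {
  v <- tp$val[[id]]
  d <- dim(v)
  idx <- rep(seq_len(d[3]), each = k2)
  y <- array(v[1, 1, idx, ], c(1, 1, d[3] * k2, d[4]))
  tp_push(tp, y, id, function(g) {
    gc <- array(g, c(k2, d[3], d[4]))
    gs <- apply(gc, c(2, 3), sum)
    list(array(gs, c(1, 1, d[3], d[4])))
  })
}

tp_sekg_apply <- function(tp, xid, thid) {
  force(xid); force(thid)
  x <- tp$val[[xid]]
  th <- tp$val[[thid]]
  y <- cpp_sekg_fw(x, th)
  tp_push(tp, y, c(xid, thid), function(g) {
    r <- cpp_sekg_bw(x, th, g)
    list(r$gx, r$gtheta)
  })
}

# Backward pass: seeds is a named list mapping node id (as integer) to the
# gradient of the scalar objective w.r.t. that node's value.
tp_backward <- function(tp, seed_ids, seed_grads) {
  g <- vector("list", tp$n)
  for (k in seq_along(seed_ids)) {
    id <- seed_ids[[k]]
    if (is.null(g[[id]])) g[[id]] <- seed_grads[[k]] else g[[id]] <- g[[id]] + seed_grads[[k]]
  }
  for (id in rev(seq_len(tp$n))) {
    if (is.null(g[[id]]) || is.null(tp$back[[id]])) next
    gs <- tp$back[[id]](g[[id]])
    ps <- tp$parents[[id]]
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      gp <- gs[[k]]
      if (!length(dim(gp))) dim(gp) <- dim(tp$val[[p]])
      if (is.null(g[[p]])) g[[p]] <- gp else g[[p]] <- g[[p]] + gp
    }
    g[id] <- list(NULL)  # free memory without shifting list indices
  }
  invisible(NULL)
}
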