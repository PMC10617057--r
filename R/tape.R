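# Reverse-mode autodiff over dense H x W x C x N arrays.
#
# A tape records nodes in forward order; each non-leaf node carries a
# closure that pushes its incoming gradient to its parents. Backward
# traverses the tape in reverse, so gradients reach every parameter in
# one pass. This is deliberately minimal: only the operations the two
# segmentation architectures need are implemented, and each op's
# gradient is validated against finite differences in the test suite.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

add_node <- function(tp, value, backward = NULL, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$name <- name
  tp$nodes[[length(tp$nodes) + 1L]] <- nd
  nd
}

accum_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Leaf holding a constant (inputs, targets): no backward.
op_leaf <- function(tp, value, name = NULL) add_node(tp, value, name = name)

tape_backward <- function(tp, loss) {
  loss$grad <- 1
  for (i in rev(seq_along(tp$nodes))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

op_conv <- function(tp, x, wn, bn, kh, kw) {
  add_node(tp, conv2d_fwd(x$value, wn$value, bn$value, kh, kw),
           backward = function(g) {
             r <- conv2d_bwd(x$value, wn$value, g, kh, kw)
             accum_grad(x, r$dx)
             accum_grad(wn, r$dw)
             accum_grad(bn, r$db)
           })
}

op_relu <- function(tp, x) {
  pos <- x$value > 0
  add_node(tp, x$value * pos,
           backward = function(g) accum_grad(x, g * pos))
}

op_sigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-x$value))
  add_node(tp, s,
           backward = function(g) accum_grad(x, g * s * (1 - s)))
}

op_add <- function(tp, a, b) {
  add_node(tp, a$value + b$value,
           backward = function(g) {
             accum_grad(a, g)
             accum_grad(b, g)
           })
}

op_concat <- function(tp, xs) {
  d1 <- dim(xs[[1]]$value)
  cs <- vapply(xs, function(x) dim(x$value)[3], numeric(1))
  y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (x in xs) {
    y[, , off + seq_len(dim(x$value)[3]), ] <- x$value
    off <- off + dim(x$value)[3]
  }
  add_node(tp, y, backward = function(g) {
    off <- 0L
    for (x in xs) {
      ck <- dim(x$value)[3]
      accum_grad(x, g[, , off + seq_len(ck), , drop = FALSE])
      off <- off + ck
    }
  })
}

op_maxpool2 <- function(tp, x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  a <- x$value[i1, j1, , , drop = FALSE]
  b <- x$value[i2, j1, , , drop = FALSE]
  cc <- x$value[i1, j2, , , drop = FALSE]
  dd <- x$value[i2, j2, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  add_node(tp, y, backward = function(g) {
    m1 <- a == y
    m2 <- (b == y) & !m1
    m3 <- (cc == y) & !(m1 | m2)
    m4 <- (dd == y) & !(m1 | m2 | m3)
    dx <- array(0, d)
    dx[i1, j1, , ] <- g * m1
    dx[i2, j1, , ] <- dx[i2, j1, , , drop = FALSE] + g * m2
    dx[i1, j2, , ] <- dx[i1, j2, , , drop = FALSE] + g * m3
    dx[i2, j2, , ] <- dx[i2, j2, , , drop = FALSE] + g * m4
    accum_grad(x, dx)
  })
}

# Nearest-neighbour upsampling by an integer factor.
op_upsample_nn <- function(tp, x, k) {
  if (k == 1L) return(x)
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  y <- x$value[rep(seq_len(H), each = k), rep(seq_len(W), each = k), , ,
               drop = FALSE]
  add_node(tp, y, backward = function(g) {
    dx <- array(0, d)
    for (di in seq_len(k) - 1L) {
      for (dj in seq_len(k) - 1L) {
        dx <- dx + g[seq(1L + di, by = k, length.out = H),
                     seq(1L + dj, by = k, length.out = W), , ,
                     drop = FALSE]
      }
    }
    accum_grad(x, dx)
  })
}

# 1-D linear-interpolation matrix (half-pixel centres), n_in -> n_out.
bilinear_matrix <- function(n_out, n_in) {
  s <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * s + 0.5
  i0 <- floor(src)
  w1 <- src - i0
  i0c <- pmin(pmax(i0, 1), n_in)
  i1c <- pmin(pmax(i0 + 1, 1), n_in)
  L <- matrix(0, n_out, n_in)
  for (r in seq_len(n_out)) {
    L[r, i0c[r]] <- L[r, i0c[r]] + (1 - w1[r])
    L[r, i1c[r]] <- L[r, i1c[r]] + w1[r]
  }
  L
}

# Separable bilinear resampling to (h_out, w_out).
op_bilinear_resize <- function(tp, x, h_out, w_out) {
  d <- dim(x$value)
  Lh <- bilinear_matrix(h_out, d[1])
  Lw <- bilinear_matrix(w_out, d[2])
  tLw <- t(Lw)
  y <- array(0, c(h_out, w_out, d[3], d[4]))
  for (n in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      y[, , c, n] <- Lh %*% x$value[, , c, n] %*% tLw
    }
  }
  add_node(tp, y, backward = function(g) {
    dx <- array(0, d)
    for (n in seq_len(d[4])) {
      for (c in seq_len(d[3])) {
        dx[, , c, n] <- crossprod(Lh, g[, , c, n]) %*% Lw
      }
    }
    accum_grad(x, dx)
  })
}

# Batch normalization over (H, W, N) per channel. `state` is an
# environment holding running moments under `<key>_mean` / `<key>_var`;
# training mode uses batch moments and updates the running ones
# (momentum 0.99), inference mode uses the running moments.
op_batchnorm <- function(tp, x, gn, bn, state, key, training,
                         eps = 1e-3, momentum = 0.99) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- channel_sum(x$value) / m
    va <- channel_sum(x$value^2) / m - mu^2
    va <- pmax(va, 0)
    state[[paste0(key, "_mean")]] <-
      momentum * state[[paste0(key, "_mean")]] + (1 - momentum) * mu
    state[[paste0(key, "_var")]] <-
      momentum * state[[paste0(key, "_var")]] + (1 - momentum) * va
  } else {
    mu <- state[[paste0(key, "_mean")]]
    va <- state[[paste0(key, "_var")]]
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- (x$value - bc_channel(mu, d)) * bc_channel(inv, d)
  y <- bc_channel(gn$value, d) * xhat + bc_channel(bn$value, d)
  add_node(tp, y, backward = function(g) {
    accum_grad(gn, channel_sum(g * xhat))
    accum_grad(bn, channel_sum(g))
    dxhat <- g * bc_channel(gn$value, d)
    if (training) {
      s1 <- channel_sum(dxhat)
      s2 <- channel_sum(dxhat * xhat)
      dx <- bc_channel(inv / m, d) *
        (m * dxhat - bc_channel(s1, d) - xhat * bc_channel(s2, d))
    } else {
      dx <- dxhat * bc_channel(inv, d)
    }
    accum_grad(x, dx)
  })
}

# Smoothed Dice loss on probability maps (see dice_loss() for the
# formula). Pooled over the whole batch by default; per_image averages
# per-sample losses instead.
op_dice_loss <- function(tp, p, target, xi = 100, per_image = FALSE) {
  d <- dim(p$value)
  if (per_image) {
    n <- d[4]
    I <- S <- numeric(n)
    for (k in seq_len(n)) {
      pk <- p$value[, , , k]
      gk <- target[, , , k]
      I[k] <- sum(pk * gk)
      S[k] <- sum(pk) + sum(gk)
    }
    val <- mean(1 - (2 * I + xi) / (S + xi))
    add_node(tp, val, backward = function(g) {
      dp <- array(0, d)
      for (k in seq_len(n)) {
        gk <- target[, , , k, drop = FALSE]
        dp[, , , k] <- -(2 * gk * (S[k] + xi) - (2 * I[k] + xi)) /
          (S[k] + xi)^2 / n
      }
      accum_grad(p, g * dp)
    })
  } else {
    I <- sum(p$value * target)
    S <- sum(p$value) + sum(target)
    val <- 1 - (2 * I + xi) / (S + xi)
    add_node(tp, val, backward = function(g) {
      dp <- -(2 * target * (S + xi) - (2 * I + xi)) / (S + xi)^2
      accum_grad(p, g * dp)
    })
  }
}

# Mean binary cross-entropy (optional compound-loss component).
op_bce_loss <- function(tp, p, target, eps = 1e-7) {
  pc <- pmin(pmax(p$value, eps), 1 - eps)
  n <- length(pc)
  val <- -sum(target * log(pc) + (1 - target) * log(1 - pc)) / n
  add_node(tp, val, backward = function(g) {
    inside <- p$value > eps & p$value < 1 - eps
    dp <- -(target / pc - (1 - target) / (1 - pc)) / n * inside
    accum_grad(p, g * dp)
  })
}

op_scale_add <- function(tp, a, b, wa = 1, wb = 1) {
  add_node(tp, wa * a$value + wb * b$value,
           backward = function(g) {
             accum_grad(a, wa * g)
             accum_grad(b, wb * g)
           })
}
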