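# A minimal reverse-mode tape over the C++ layer primitives.
#
# Feature maps are (H*W) x C matrices, column-major spatial order (index
# i + j*H).  A tape records every operation during the forward pass; walking
# it backwards accumulates parameter gradients and input gradients.  This is
# all the autodiff the three architectures need: convolution (strided,
# dilated), depthwise convolution, transposed 2x2 convolution, 2x2 max
# pooling, nearest upsampling, concatenation, addition, ReLU, and global
# average pooling with broadcast.

tape_new <- function(params) {
  tp <- new.env(parent = emptyenv())
  tp$params <- params
  tp$ops <- list()
  tp$vals <- list()
  tp$n <- 0L
  tp
}

tp_push <- function(tp, type, a, H, W, ins = integer(), name = NULL,
                    extra = NULL) {
  id <- tp$n + 1L
  tp$n <- id
  tp$vals[[id]] <- a
  tp$ops[[id]] <- list(type = type, ins = ins, name = name, H = H, W = W,
                       extra = extra)
  list(id = id, H = H, W = W)
}

op_input <- function(tp, a, H, W) tp_push(tp, "input", a, H, W)

op_conv <- function(tp, name, x, k, stride = 1L, dil = 1L, act = "relu") {
  force(x)
  p <- tp$params
  r <- nn_conv_fwd(tp$vals[[x$id]], x$H, x$W,
                   p[[paste0(name, ".w")]], p[[paste0(name, ".b")]],
                   as.integer(k), as.integer(stride), as.integer(dil))
  a <- r$y
  if (act == "relu") a[a < 0] <- 0
  tp_push(tp, "conv", a, r$H, r$W, ins = x$id, name = name,
          extra = list(k = as.integer(k), stride = as.integer(stride),
                       dil = as.integer(dil), act = act))
}

op_dwconv <- function(tp, name, x, k = 3L, dil = 1L) {
  force(x)
  p <- tp$params
  r <- nn_dwconv_fwd(tp$vals[[x$id]], x$H, x$W,
                     p[[paste0(name, ".w")]], p[[paste0(name, ".b")]],
                     as.integer(k), as.integer(dil))
  tp_push(tp, "dwconv", r$y, r$H, r$W, ins = x$id, name = name,
          extra = list(k = as.integer(k), dil = as.integer(dil)))
}

op_convt <- function(tp, name, x) {
  force(x)
  p <- tp$params
  r <- nn_convt_fwd(tp$vals[[x$id]], x$H, x$W,
                    p[[paste0(name, ".w")]], p[[paste0(name, ".b")]])
  tp_push(tp, "convt", r$y, r$H, r$W, ins = x$id, name = name)
}

op_pool <- function(tp, x) {
  force(x)
  r <- nn_maxpool_fwd(tp$vals[[x$id]], x$H, x$W)
  tp_push(tp, "pool", r$y, r$H, r$W, ins = x$id, extra = list(idx = r$idx))
}

op_up <- function(tp, x, th, tw) {
  force(x)
  y <- nn_upsample_fwd(tp$vals[[x$id]], x$H, x$W, as.integer(th), as.integer(tw))
  tp_push(tp, "up", y, th, tw, ins = x$id)
}

op_concat <- function(tp, x1, x2) {
  force(x1); force(x2)
  stopifnot(x1$H == x2$H, x1$W == x2$W)
  a <- cbind(tp$vals[[x1$id]], tp$vals[[x2$id]])
  tp_push(tp, "concat", a, x1$H, x1$W, ins = c(x1$id, x2$id),
          extra = list(c1 = ncol(tp$vals[[x1$id]])))
}

op_add <- function(tp, x1, x2) {
  force(x1); force(x2)
  a <- tp$vals[[x1$id]] + tp$vals[[x2$id]]
  tp_push(tp, "add", a, x1$H, x1$W, ins = c(x1$id, x2$id))
}

op_relu <- function(tp, x) {
  force(x)
  a <- tp$vals[[x$id]]
  a[a < 0] <- 0
  tp_push(tp, "relu", a, x$H, x$W, ins = x$id)
}

op_gap <- function(tp, x) {
  force(x)
  a <- matrix(colMeans(tp$vals[[x$id]]), 1)
  tp_push(tp, "gap", a, 1L, 1L, ins = x$id)
}

op_broadcast <- function(tp, x, th, tw) {
  force(x)
  a <- tp$vals[[x$id]][rep(1L, th * tw), , drop = FALSE]
  tp_push(tp, "broadcast", a, th, tw, ins = x$id)
}

# Walk the tape backwards from `out_id` seeded with gradient `dout`.
# Returns the parameter gradient list (names matching tp$params).
tape_backward <- function(tp, out_id, dout) {
  d <- vector("list", tp$n)
  d[[out_id]] <- dout
  grads <- list()
  p <- tp$params
  for (id in tp$n:1) {
    op <- tp$ops[[id]]
    dy <- d[[id]]
    d[id] <- list(NULL)   # release
    if (is.null(dy) || op$type == "input") next
    ins <- op$ins
    prop <- function(i, g) {
      d[[i]] <<- if (is.null(d[[i]])) g else d[[i]] + g
    }
    if (op$type == "conv") {
      e <- op$extra
      if (e$act == "relu") dy <- dy * (tp$vals[[id]] > 0)
      i1 <- ins[1]
      r <- nn_conv_bwd(tp$vals[[i1]], tp$ops[[i1]]$H, tp$ops[[i1]]$W,
                       p[[paste0(op$name, ".w")]], dy, e$k, e$stride, e$dil)
      wn <- paste0(op$name, ".w"); bn <- paste0(op$name, ".b")
      grads[[wn]] <- if (is.null(grads[[wn]])) r$dw else grads[[wn]] + r$dw
      grads[[bn]] <- if (is.null(grads[[bn]])) drop(r$db) else grads[[bn]] + drop(r$db)
      prop(i1, r$dx)
    } else if (op$type == "dwconv") {
      e <- op$extra
      i1 <- ins[1]
      r <- nn_dwconv_bwd(tp$vals[[i1]], tp$ops[[i1]]$H, tp$ops[[i1]]$W,
                         p[[paste0(op$name, ".w")]], dy, e$k, e$dil)
      wn <- paste0(op$name, ".w"); bn <- paste0(op$name, ".b")
      grads[[wn]] <- if (is.null(grads[[wn]])) r$dw else grads[[wn]] + r$dw
      grads[[bn]] <- if (is.null(grads[[bn]])) drop(r$db) else grads[[bn]] + drop(r$db)
      prop(i1, r$dx)
    } else if (op$type == "convt") {
      i1 <- ins[1]
      r <- nn_convt_bwd(tp$vals[[i1]], tp$ops[[i1]]$H, tp$ops[[i1]]$W,
                        p[[paste0(op$name, ".w")]], dy)
      wn <- paste0(op$name, ".w"); bn <- paste0(op$name, ".b")
      grads[[wn]] <- if (is.null(grads[[wn]])) r$dw else grads[[wn]] + r$dw
      grads[[bn]] <- if (is.null(grads[[bn]])) drop(r$db) else grads[[bn]] + drop(r$db)
      prop(i1, r$dx)
    } else if (op$type == "pool") {
      i1 <- ins[1]
      prop(i1, nn_maxpool_bwd(dy, op$extra$idx,
                              tp$ops[[i1]]$H, tp$ops[[i1]]$W))
    } else if (op$type == "up") {
      i1 <- ins[1]
      prop(i1, nn_upsample_bwd(dy, tp$ops[[i1]]$H, tp$ops[[i1]]$W,
                               op$H, op$W))
    } else if (op$type == "concat") {
      c1 <- op$extra$c1
      prop(ins[1], dy[, seq_len(c1), drop = FALSE])
      prop(ins[2], dy[, -seq_len(c1), drop = FALSE])
    } else if (op$type == "add") {
      prop(ins[1], dy)
      prop(ins[2], dy)
    } else if (op$type == "relu") {
      prop(ins[1], dy * (tp$vals[[id]] > 0))
    } else if (op$type == "gap") {
      i1 <- ins[1]
      npix <- tp$ops[[i1]]$H * tp$ops[[i1]]$W
      prop(i1, matrix(dy, npix, ncol(dy), byrow = TRUE) / npix)
    } else if (op$type == "broadcast") {
      prop(ins[1], matrix(colSums(dy), 1))
    } else {
      stopf("unknown tape op '%s'", op$type)
    }
  }
  grads
}

# He-style seeded initialisers.  Weights are drawn from the ambient RNG
# stream; callers seed it (see build_seg_model).
init_conv <- function(k, cin, cout, gain = 2) {
  list(w = matrix(rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
                  k * k * cin, cout),
       b = rep(0, cout))
}

init_dwconv <- function(k, ch, gain = 2) {
  list(w = matrix(rnorm(k * k * ch, sd = sqrt(gain / (k * k))), k * k, ch),
       b = rep(0, ch))
}

init_convt <- function(cin, cout, gain = 2) {
  list(w = matrix(rnorm(cin * 4 * cout, sd = sqrt(gain / cin)), cin, 4 * cout),
       b = rep(0, cout))
}

add_param <- function(store, name, pair) {
  store[[paste0(name, ".w")]] <- pair$w
  store[[paste0(name, ".b")]] <- pair$b
  store
}
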