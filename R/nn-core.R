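# A compact CNN engine: a static computational graph of convolution,
# activation, concatenation, pixel-shuffle and median-pool nodes, with exact
# reverse-mode gradients and an Adam optimizer. Feature maps are (H, W, C, N)
# arrays; convolutions use reflective 'same' padding (reflect-101).

nn_new <- function() {
  net <- new.env(parent = emptyenv())
  net$nodes <- list()
  net$out <- NA_integer_
  net
}

nn_add <- function(net, node) {
  net$nodes[[length(net$nodes) + 1L]] <- node
  length(net$nodes)
}

nn_input <- function(net) nn_add(net, list(op = "input", inputs = integer()))

# He-normal initialized convolution; weights stored as (k^2*cin) x cout with
# patch-element order (channel, kx, ky) matching the C++ im2col
nn_conv <- function(net, from, k, cin, cout, stride = 1L) {
  W <- matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
              nrow = k * k * cin, ncol = cout)
  nn_add(net, list(op = "conv", inputs = from, k = as.integer(k),
                   stride = as.integer(stride), cin = cin, cout = cout,
                   W = W, b = numeric(cout)))
}

nn_lrelu <- function(net, from, slope = 0.2)
  nn_add(net, list(op = "lrelu", inputs = from, slope = slope))

nn_sigmoid <- function(net, from)
  nn_add(net, list(op = "sigmoid", inputs = from))

nn_concat <- function(net, froms)
  nn_add(net, list(op = "concat", inputs = as.integer(froms)))

nn_pshuffle <- function(net, from, r = 2L)
  nn_add(net, list(op = "pshuffle", inputs = from, r = as.integer(r)))

# gradient does not propagate through the pooled input branch (it ends at the
# raw network input anyway)
nn_mpool <- function(net, from, factor)
  nn_add(net, list(op = "mpool", inputs = from, factor = as.integer(factor)))

concat_channels <- function(arrs) {
  d <- dim(arrs[[1]])
  cs <- vapply(arrs, function(a) dim(a)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  off <- 0L
  for (a in arrs) {
    nc <- dim(a)[3]
    out[, , off + seq_len(nc), ] <- a
    off <- off + nc
  }
  out
}

nn_forward <- function(net, x, keep = TRUE) {
  acts <- vector("list", length(net$nodes))
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    acts[[i]] <- switch(nd$op,
      input = as_batch(x),
      conv = cpp_conv2d_forward(acts[[nd$inputs]], nd$W, nd$b, nd$k, nd$stride),
      lrelu = {
        a <- acts[[nd$inputs]]
        pmax(a, 0) + nd$slope * pmin(a, 0)
      },
      sigmoid = 1 / (1 + exp(-acts[[nd$inputs]])),
      concat = concat_channels(acts[nd$inputs]),
      pshuffle = cpp_pixel_shuffle(acts[[nd$inputs]], nd$r),
      mpool = if (nd$factor == 1L) acts[[nd$inputs]]
              else cpp_median_pool(acts[[nd$inputs]], nd$factor),
      stop("unknown op ", nd$op))
  }
  if (keep) list(out = acts[[net$out]], acts = acts)
  else list(out = acts[[net$out]], acts = NULL)
}

# reverse-mode pass; returns per-node parameter gradients and the gradient
# with respect to the graph input
nn_backward <- function(net, acts, dout) {
  n <- length(net$nodes)
  grads <- vector("list", n)
  pgrads <- vector("list", n)
  grads[[net$out]] <- dout
  dinput <- NULL
  for (i in rev(seq_len(n))) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- net$nodes[[i]]
    if (nd$op == "input") { dinput <- g; next }
    if (nd$op == "conv") {
      res <- cpp_conv2d_backward(acts[[nd$inputs]], nd$W, g, nd$k, nd$stride)
      pgrads[[i]] <- list(dW = res$dW, db = as.numeric(res$db))
      grads[[nd$inputs]] <- if (is.null(grads[[nd$inputs]])) res$dx
                            else grads[[nd$inputs]] + res$dx
    } else if (nd$op == "lrelu") {
      a <- acts[[nd$inputs]]
      din <- g * ifelse(a > 0, 1, nd$slope)
      dim(din) <- dim(a)
      grads[[nd$inputs]] <- if (is.null(grads[[nd$inputs]])) din
                            else grads[[nd$inputs]] + din
    } else if (nd$op == "sigmoid") {
      y <- acts[[i]]
      din <- g * y * (1 - y)
      grads[[nd$inputs]] <- if (is.null(grads[[nd$inputs]])) din
                            else grads[[nd$inputs]] + din
    } else if (nd$op == "concat") {
      off <- 0L
      for (j in nd$inputs) {
        nc <- dim(acts[[j]])[3]
        dj <- g[, , off + seq_len(nc), , drop = FALSE]
        grads[[j]] <- if (is.null(grads[[j]])) dj else grads[[j]] + dj
        off <- off + nc
      }
    } else if (nd$op == "pshuffle") {
      din <- cpp_pixel_unshuffle(g, nd$r)
      grads[[nd$inputs]] <- if (is.null(grads[[nd$inputs]])) din
                            else grads[[nd$inputs]] + din
    }
    # mpool: gradient intentionally stops (input branch)
    grads[[i]] <- NULL
  }
  list(pgrads = pgrads, dinput = dinput)
}

nn_params <- function(net) {
  idx <- which(vapply(net$nodes, function(nd) nd$op == "conv", logical(1)))
  idx
}

nn_get_weights <- function(net) {
  lapply(net$nodes, function(nd) if (nd$op == "conv") list(W = nd$W, b = nd$b) else NULL)
}

nn_set_weights <- function(net, ws) {
  for (i in seq_along(ws)) {
    if (!is.null(ws[[i]])) {
      net$nodes[[i]]$W <- ws[[i]]$W
      net$nodes[[i]]$b <- ws[[i]]$b
    }
  }
  invisible(net)
}

#' Count trainable parameters of a network
#'
#' Sums every trainable scalar (convolution weights and biases) of a network
#' built by [build_generator()] or [build_discriminator()].
#'
#' @param network a `biraster_net` object.
#' @return integer parameter count.
#' @export
count_parameters <- function(network) {
  net <- network$graph
  s <- 0
  for (nd in net$nodes)
    if (nd$op == "conv") s <- s + length(nd$W) + length(nd$b)
  as.integer(s)
}

# Adam with L2 weight decay (decay added to the raw gradient)
adam_new <- function(net, lr, beta1, beta2, weight_decay, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$wd <- weight_decay
  st$eps <- eps; st$t <- 0L
  st$m <- lapply(net$nodes, function(nd)
    if (nd$op == "conv") list(W = nd$W * 0, b = nd$b * 0) else NULL)
  st$v <- st$m
  st
}

adam_step <- function(net, pgrads, st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(net$nodes)) {
    pg <- pgrads[[i]]
    if (is.null(pg)) next
    nd <- net$nodes[[i]]
    for (p in c("W", "b")) {
      g <- if (p == "W") pg$dW else pg$db
      g <- g + st$wd * nd[[p]]
      st$m[[i]][[p]] <- st$b1 * st$m[[i]][[p]] + (1 - st$b1) * g
      st$v[[i]][[p]] <- st$b2 * st$v[[i]][[p]] + (1 - st$b2) * g^2
      nd[[p]] <- nd[[p]] - st$lr * (st$m[[i]][[p]] / bc1) /
        (sqrt(st$v[[i]][[p]] / bc2) + st$eps)
    }
    net$nodes[[i]] <- nd
  }
  invisible(net)
}
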