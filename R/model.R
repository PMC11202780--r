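# A small 3-D CNN engine (forward + backprop over conv3d / maxpool / global
# average pooling / dense layers and residual blocks) sufficient to train
# the classifier on CPU. Volumes are [H, W, D, C] arrays; convolutions use
# "same" padding with configurable per-axis strides. Depth is never strided
# (a 5-slice input leaves no room for depth downsampling); the global
# average pool collapses it.

.same_pad <- function(in_dim, k, stride) {
  out <- ceiling(in_dim / stride)
  pad_total <- pmax((out - 1L) * stride + k - in_dim, 0L)
  list(out = as.integer(out), beg = as.integer(pad_total %/% 2L))
}

.conv_layer <- function(ci, co, k, stride) {
  fan_in <- prod(k) * ci
  w <- array(stats::rnorm(prod(k) * ci * co, sd = sqrt(2 / fan_in)),
             dim = c(k, ci, co))
  list(type = "conv", w = w, b = numeric(co), stride = as.integer(stride))
}

.resblock <- function(ci, co, stride) {
  proj <- if (any(stride != 1L) || ci != co)
    .conv_layer(ci, co, c(1L, 1L, 1L), stride) else NULL
  list(type = "resblock",
       conv1 = .conv_layer(ci, co, c(3L, 3L, 3L), stride),
       conv2 = .conv_layer(co, co, c(3L, 3L, 3L), c(1L, 1L, 1L)),
       proj = proj)
}

.conv_fw <- function(layer, x) {
  xd <- dim(x); wd <- dim(layer$w)
  p <- Map(.same_pad, xd[1:3], wd[1:3], layer$stride)
  odim <- vapply(p, `[[`, 0L, "out")
  pad <- vapply(p, `[[`, 0L, "beg")
  y <- .conv3_fw(x, as.integer(xd), layer$w, as.integer(wd), layer$b,
                 layer$stride, pad, odim)
  list(out = y, cache = list(x = x, pad = pad, odim = odim))
}

.conv_bw <- function(layer, cache, gy) {
  xd <- dim(cache$x); wd <- dim(layer$w)
  r <- .conv3_bw(cache$x, as.integer(xd), layer$w, as.integer(wd), gy,
                 layer$stride, cache$pad, cache$odim)
  list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
}

.layer_fw <- function(layer, x) {
  switch(layer$type,
    conv = .conv_fw(layer, x),
    relu = list(out = pmax(x, 0) * 1, cache = list(pos = x > 0, dim = dim(x))),
    maxpool = {
      xd <- dim(x)
      p <- Map(.same_pad, xd[1:3], layer$k, layer$stride)
      odim <- vapply(p, `[[`, 0L, "out")
      pad <- vapply(p, `[[`, 0L, "beg")
      r <- .maxpool3_fw(x, as.integer(xd), layer$k, layer$stride, pad, odim)
      list(out = r$y, cache = list(amax = r$amax, xdim = as.integer(xd)))
    },
    gap = {
      xd <- dim(x)
      feat <- apply(x, 4, mean)
      list(out = feat, cache = list(xdim = xd))
    },
    dense = list(out = drop(layer$w %*% x + layer$b), cache = list(x = x)),
    resblock = {
      f1 <- .conv_fw(layer$conv1, x)
      a1 <- pmax(f1$out, 0)
      f2 <- .conv_fw(layer$conv2, a1)
      s <- if (is.null(layer$proj)) list(out = x, cache = NULL)
           else .conv_fw(layer$proj, x)
      pre <- f2$out + s$out
      list(out = pmax(pre, 0),
           cache = list(c1 = f1$cache, pos1 = f1$out > 0, c2 = f2$cache,
                        cs = s$cache, pos_out = pre > 0, xdim = dim(x)))
    },
    stop("unknown layer type ", layer$type)
  )
}

.layer_bw <- function(layer, cache, gy) {
  switch(layer$type,
    conv = .conv_bw(layer, cache, gy),
    relu = {
      gx <- gy * cache$pos
      dim(gx) <- cache$dim
      list(gx = gx, grads = NULL)
    },
    maxpool = list(gx = .maxpool3_bw(gy, cache$amax, prod(cache$xdim),
                                     cache$xdim),
                   grads = NULL),
    gap = {
      xd <- cache$xdim
      per <- prod(xd[1:3])
      gx <- array(rep(gy / per, each = per), dim = xd)
      list(gx = gx, grads = NULL)
    },
    dense = list(gx = as.numeric(t(layer$w) %*% gy),
                 grads = list(w = gy %*% t(cache$x), b = gy)),
    resblock = {
      g_pre <- gy * cache$pos_out
      dim(g_pre) <- dim(cache$pos_out)
      b2 <- .conv_bw(layer$conv2, cache$c2, g_pre)
      g_a1 <- b2$gx * cache$pos1
      dim(g_a1) <- dim(cache$pos1)
      b1 <- .conv_bw(layer$conv1, cache$c1, g_a1)
      if (is.null(layer$proj)) {
        gx <- b1$gx + g_pre
        gp <- NULL
      } else {
        bp <- .conv_bw(layer$proj, cache$cs, g_pre)
        gx <- b1$gx + bp$gx
        gp <- bp$grads
      }
      list(gx = gx, grads = list(conv1 = b1$grads, conv2 = b2$grads, proj = gp))
    }
  )
}

#' Build a 3-D convolutional survival classifier
#'
#' Two architectures share one engine: `"resnet34_3d"`, a 3-D residual
#' network with basic-block stages (3, 4, 6, 3) at 64/128/256/512 channels,
#' a (7, 7, 3) stem, global average pooling and a single sigmoid output; and
#' `"tiny3d"`, a two-convolution variant of the same design used for fast
#' CPU experiments and tests. In-plane resolution is strided down; the
#' slice (depth) axis keeps stride 1 throughout and is collapsed by the
#' global pool. Weights are He-normal initialized from the current RNG
#' state, so a fixed seed reproduces the initialization bit for bit.
#'
#' @param arch `"tiny3d"` or `"resnet34_3d"`.
#' @param in_shape input volume shape `c(H, W, D)` (one channel).
#' @param seed optional seed applied before initialization.
#' @return object of class `ctsurv_model`.
#' @export
build_model <- function(arch = c("tiny3d", "resnet34_3d"),
                        in_shape = c(240L, 240L, 5L), seed = NULL) {
  arch <- match.arg(arch)
  if (!is.null(seed)) set.seed(seed)
  if (min(in_shape[1:2]) < 8L)
    ctsurv_abort("in-plane size too small for the strided stages; need >= 8",
                 "ctsurv_bad_shape")
  layers <- if (arch == "tiny3d") {
    list(.conv_layer(1L, 8L, c(3L, 3L, 3L), c(2L, 2L, 1L)),
         list(type = "relu"),
         .conv_layer(8L, 16L, c(3L, 3L, 3L), c(2L, 2L, 1L)),
         list(type = "relu"),
         list(type = "gap"),
         list(type = "dense",
              w = matrix(stats::rnorm(16, sd = sqrt(2 / 16)), 1L), b = 0))
  } else {
    stages <- list(c(64L, 3L, 1L), c(128L, 4L, 2L), c(256L, 6L, 2L),
                   c(512L, 3L, 2L))
    ll <- list(.conv_layer(1L, 64L, c(7L, 7L, 3L), c(2L, 2L, 1L)),
               list(type = "relu"),
               list(type = "maxpool", k = c(3L, 3L, 1L),
                    stride = c(2L, 2L, 1L)))
    ci <- 64L
    for (st in stages) {
      co <- st[1]; nb <- st[2]; s <- st[3]
      for (bi in seq_len(nb)) {
        stride <- if (bi == 1L) c(s, s, 1L) else c(1L, 1L, 1L)
        ll[[length(ll) + 1L]] <- .resblock(ci, co, stride)
        ci <- co
      }
    }
    ll[[length(ll) + 1L]] <- list(type = "gap")
    ll[[length(ll) + 1L]] <- list(
      type = "dense", w = matrix(stats::rnorm(512, sd = sqrt(2 / 512)), 1L),
      b = 0)
    ll
  }
  structure(list(arch = arch, in_shape = as.integer(in_shape),
                 layers = layers),
            class = "ctsurv_model")
}

# Forward pass for one sample. Returns prob, the pre-sigmoid logit z, and
# per-layer caches for backprop.
.model_fw <- function(model, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    r <- .layer_fw(model$layers[[i]], x)
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  z <- as.numeric(x)
  list(prob = 1 / (1 + exp(-z)), z = z, caches = caches)
}

# Backward pass from d loss / d z (z = pre-sigmoid logit). Returns a grads
# list parallel to model$layers.
.model_bw <- function(model, caches, gz) {
  grads <- vector("list", length(model$layers))
  g <- gz
  for (i in rev(seq_along(model$layers))) {
    r <- .layer_bw(model$layers[[i]], caches[[i]], g)
    grads[i] <- list(r$grads)   # [[<- would drop NULL entries
    g <- r$gx
  }
  grads
}

.zero_like_grads <- function(model) {
  lapply(model$layers, function(l) {
    if (l$type == "conv")
      list(w = array(0, dim(l$w)), b = numeric(length(l$b)))
    else if (l$type == "dense")
      list(w = matrix(0, nrow(l$w), ncol(l$w)), b = 0)
    else if (l$type == "resblock")
      list(conv1 = list(w = array(0, dim(l$conv1$w)),
                        b = numeric(length(l$conv1$b))),
           conv2 = list(w = array(0, dim(l$conv2$w)),
                        b = numeric(length(l$conv2$b))),
           proj = if (is.null(l$proj)) NULL
                  else list(w = array(0, dim(l$proj$w)),
                            b = numeric(length(l$proj$b))))
    else NULL
  })
}

.acc_grads <- function(a, b) {
  if (is.null(b)) return(a)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    if (is.list(b[[i]]) && is.null(b[[i]]$w)) {
      a[[i]] <- .acc_grads(a[[i]], b[[i]])
    } else if (is.list(b[[i]])) {
      a[[i]]$w <- a[[i]]$w + b[[i]]$w
      a[[i]]$b <- a[[i]]$b + b[[i]]$b
    }
  }
  a
}

# SGD with Nesterov momentum and decoupled-from-nothing classic L2 weight
# decay folded into the gradient. Updates model in place (functionally).
.sgd_step <- function(params, grads, vel, lr, momentum, nesterov, wd) {
  upd_one <- function(p, g, v) {
    g <- g + wd * p
    v_new <- momentum * v - lr * g
    p_new <- if (nesterov) p + momentum * v_new - lr * g else p + v_new
    list(p = p_new, v = v_new)
  }
  walk <- function(p, g, v) {
    if (is.null(g)) return(list(p = p, v = v))
    if (!is.null(g$w)) {
      rw <- upd_one(p$w, g$w, v$w); rb <- upd_one(p$b, g$b, v$b)
      p$w <- rw$p; p$b <- rb$p; v$w <- rw$v; v$b <- rb$v
      return(list(p = p, v = v))
    }
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      r <- walk(p[[nm]], g[[nm]], v[[nm]])
      p[[nm]] <- r$p; v[[nm]] <- r$v
    }
    list(p = p, v = v)
  }
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    r <- walk(params$layers[[i]], grads[[i]], vel[[i]])
    params$layers[[i]] <- r$p
    vel[[i]] <- r$v
  }
  list(model = params, vel = vel)
}

#' Number of trainable parameters of a model
#'
#' @param model a `ctsurv_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  cnt <- function(l) {
    if (is.null(l)) return(0)
    if (l$type %in% c("conv", "dense")) return(length(l$w) + length(l$b))
    if (l$type == "resblock")
      return(cnt(l$conv1) + cnt(l$conv2) +
               if (is.null(l$proj)) 0 else cnt(l$proj))
    0
  }
  sum(vapply(model$layers, cnt, 0))
}

#' Predict survival probabilities for a set of input stacks
#'
#' @param object a `ctsurv_model`.
#' @param stacks list of `H x W x D` arrays (or `input_stack` objects).
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.ctsurv_model <- function(object, stacks, ...) {
  vapply(stacks, function(x) {
    if (inherits(x, "input_stack")) x <- x$volume
    .model_fw(object, x)$prob
  }, 0)
}

#' @export
print.ctsurv_model <- function(x, ...) {
  cat("<ctsurv_model>", x$arch, "- input",
      paste(x$in_shape, collapse = " x "), "x 1,",
      format(n_params(x), big.mark = ","), "parameters\n")
  invisible(x)
}
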