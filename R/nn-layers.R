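# Minimal convolutional-network engine used by the cycle-GAN core.
# Activations are 4D arrays [h, w, c, n]; every layer implements an explicit
# forward (with cache) and backward (returning input gradient and parameter
# gradients). All computation is double precision and deterministic.

# per-channel mean over (h, w, n) of an [h, w, c, n] array
chan_mean <- function(x) {
  d <- dim(x)
  .rowMeans(.colMeans(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
}

# per-(channel, sample) mean over (h, w); returns a length c*n vector that
# recycles across the array when rep()ed by h*w
inst_mean <- function(x) {
  d <- dim(x)
  .colMeans(x, d[1] * d[2], d[3] * d[4])
}

new_layer_counter <- function(prefix) {
  i <- 0L
  function() { i <<- i + 1L; sprintf("%s_%03d", prefix, i) }
}

layer_conv <- function(id, cin, cout, k, stride, pad) {
  list(type = "conv", id = id, stride = stride, pad = pad,
       W = array(rnorm(k * k * cin * cout, 0, 0.02), c(k, k, cin, cout)),
       b = numeric(cout))
}
layer_bn <- function(id, c) {
  list(type = "bn", id = id, gamma = rnorm(c, 1, 0.02), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c), mom = 0.1, eps = 1e-5)
}
layer_in <- function() list(type = "in", eps = 1e-5)
layer_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
layer_relu <- function() list(type = "lrelu", slope = 0)
layer_tanh <- function() list(type = "tanh")
layer_up2 <- function() list(type = "up2")

layer_fw <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      y <- conv2d_fw_cpp(x, dim(x), layer$W, dim(layer$W), layer$b,
                         layer$stride, layer$pad)
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x); hw <- d[1] * d[2]
      if (training) {
        mu <- chan_mean(x)
        xc <- x - rep(mu, each = hw)
        v <- chan_mean(xc * xc)
        ivstd <- 1 / sqrt(v + layer$eps)
        xhat <- xc * rep(ivstd, each = hw)
        layer$rm <- (1 - layer$mom) * layer$rm + layer$mom * mu
        layer$rv <- (1 - layer$mom) * layer$rv + layer$mom * v
        y <- xhat * rep(layer$gamma, each = hw) + rep(layer$beta, each = hw)
        list(y = y, cache = list(xhat = xhat, ivstd = ivstd), layer = layer)
      } else {
        xhat <- (x - rep(layer$rm, each = hw)) *
          rep(1 / sqrt(layer$rv + layer$eps), each = hw)
        y <- xhat * rep(layer$gamma, each = hw) + rep(layer$beta, each = hw)
        list(y = y, cache = list(eval = TRUE), layer = layer)
      }
    },
    "in" = {
      d <- dim(x); hw <- d[1] * d[2]
      mu <- inst_mean(x)
      xc <- x - rep(mu, each = hw)
      v <- inst_mean(xc * xc)
      ivstd <- 1 / sqrt(v + layer$eps)
      xhat <- xc * rep(ivstd, each = hw)
      list(y = xhat, cache = list(xhat = xhat, ivstd = ivstd), layer = layer)
    },
    lrelu = {
      pos <- (x > 0)
      m <- pos + layer$slope * (1 - pos)
      list(y = x * m, cache = list(m = m), layer = layer)
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = list(y = y), layer = layer)
    },
    up2 = {
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
             drop = FALSE]
      list(y = y, cache = list(d = d), layer = layer)
    },
    stop("unknown layer type ", layer$type)
  )
}

layer_bw <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- conv2d_bw_cpp(cache$x, dim(cache$x), layer$W, dim(layer$W),
                         dy, layer$stride, layer$pad, TRUE)
      list(dx = g$dx, grads = list(W = g$dW, b = g$db))
    },
    bn = {
      if (isTRUE(cache$eval)) stop("batch-norm backward requires training mode")
      xhat <- cache$xhat
      d <- dim(xhat); hw <- d[1] * d[2]; m <- hw * d[4]
      dgamma <- chan_mean(dy * xhat) * m
      dbeta <- chan_mean(dy) * m
      dxhat <- dy * rep(layer$gamma, each = hw)
      m_d <- chan_mean(dxhat)
      m_dx <- chan_mean(dxhat * xhat)
      dx <- (dxhat - rep(m_d, each = hw) - xhat * rep(m_dx, each = hw)) *
        rep(cache$ivstd, each = hw)
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    "in" = {
      xhat <- cache$xhat
      hw <- dim(xhat)[1] * dim(xhat)[2]
      m_d <- inst_mean(dy)
      m_dx <- inst_mean(dy * xhat)
      dx <- (dy - rep(m_d, each = hw) - xhat * rep(m_dx, each = hw)) *
        rep(cache$ivstd, each = hw)
      list(dx = dx, grads = NULL)
    },
    lrelu = list(dx = dy * cache$m, grads = NULL),
    tanh = list(dx = dy * (1 - cache$y^2), grads = NULL),
    up2 = {
      d <- cache$d
      i1 <- seq(1, 2 * d[1], by = 2); j1 <- seq(1, 2 * d[2], by = 2)
      dx <- dy[i1, j1, , , drop = FALSE] + dy[i1 + 1, j1, , , drop = FALSE] +
            dy[i1, j1 + 1, , , drop = FALSE] + dy[i1 + 1, j1 + 1, , , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    stop("unknown layer type ", layer$type)
  )
}

seq_fw <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fw(layers[[i]], x, training)
    x <- r$y; caches[[i]] <- r$cache; layers[[i]] <- r$layer
  }
  list(y = x, caches = caches, layers = layers)
}

seq_bw <- function(layers, caches, dy) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    r <- layer_bw(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    if (!is.null(r$grads)) grads[[layers[[i]]$id]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

# elementwise sum of two (possibly partial) gradient trees keyed by layer id
acc_grads <- function(a, b) {
  for (id in names(b)) {
    if (is.null(a[[id]])) a[[id]] <- b[[id]]
    else a[[id]] <- Map(`+`, a[[id]], b[[id]])
  }
  a
}
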