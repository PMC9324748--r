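# Network builders: U-Net-style encoder-decoder generator with skip
# connections, and a patch-based convolutional discriminator. Upsampling in
# the decoder is nearest-neighbour x2 followed by a 3x3 convolution (same
# receptive growth as a strided transposed convolution, without checkerboard
# artifacts). Weight init: normal(0, 0.02); norm gains normal(1, 0.02).

.mk_norm <- function(norm, c, nextid) {
  if (norm == "batch") layer_bn(nextid(), c) else layer_in()
}

# One skip-connection block: down-convolution, inner submodule, up-convolution;
# non-outermost blocks return channel-concat(input, upsampled output).
.ublock <- function(outer_nc, inner_nc, input_nc, sub, norm, nextid,
                    outermost = FALSE, innermost = FALSE) {
  down <- if (outermost) {
    list(layer_conv(nextid(), input_nc, inner_nc, 4, 2, 1))
  } else if (innermost) {
    list(layer_lrelu(), layer_conv(nextid(), input_nc, inner_nc, 4, 2, 1))
  } else {
    list(layer_lrelu(), layer_conv(nextid(), input_nc, inner_nc, 4, 2, 1),
         .mk_norm(norm, inner_nc, nextid))
  }
  upin <- if (innermost) inner_nc else 2L * inner_nc
  up <- if (outermost) {
    list(layer_relu(), layer_up2(), layer_conv(nextid(), upin, outer_nc, 3, 1, 1),
         layer_tanh())
  } else {
    list(layer_relu(), layer_up2(), layer_conv(nextid(), upin, outer_nc, 3, 1, 1),
         .mk_norm(norm, outer_nc, nextid))
  }
  list(type = "unet", down = down, sub = sub, up = up,
       outermost = outermost, in_ch = input_nc)
}

build_unet <- function(in_ch, out_ch, num_downs, ngf, norm, prefix) {
  stopifnot(num_downs >= 5)
  nextid <- new_layer_counter(prefix)
  blk <- .ublock(8L * ngf, 8L * ngf, 8L * ngf, NULL, norm, nextid,
                 innermost = TRUE)
  for (i in seq_len(num_downs - 5L))
    blk <- .ublock(8L * ngf, 8L * ngf, 8L * ngf, blk, norm, nextid)
  blk <- .ublock(4L * ngf, 8L * ngf, 4L * ngf, blk, norm, nextid)
  blk <- .ublock(2L * ngf, 4L * ngf, 2L * ngf, blk, norm, nextid)
  blk <- .ublock(ngf, 2L * ngf, ngf, blk, norm, nextid)
  .ublock(out_ch, ngf, in_ch, blk, norm, nextid, outermost = TRUE)
}

build_patchgan <- function(in_ch, ndf, norm, prefix, n_layers = 3L) {
  nextid <- new_layer_counter(prefix)
  layers <- list(layer_conv(nextid(), in_ch, ndf, 4, 2, 1), layer_lrelu())
  nf <- ndf
  for (n in seq_len(n_layers - 1L)) {
    nf_prev <- nf; nf <- min(ndf * 2^n, ndf * 8L)
    layers <- c(layers, list(layer_conv(nextid(), nf_prev, nf, 4, 2, 1),
                             .mk_norm(norm, nf, nextid), layer_lrelu()))
  }
  nf_prev <- nf; nf <- min(ndf * 2^n_layers, ndf * 8L)
  layers <- c(layers, list(layer_conv(nextid(), nf_prev, nf, 4, 1, 1),
                           .mk_norm(norm, nf, nextid), layer_lrelu(),
                           layer_conv(nextid(), nf, 1L, 4, 1, 1)))
  list(type = "seq", layers = layers)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

net_fw <- function(net, x, training) {
  if (net$type == "seq") {
    r <- seq_fw(net$layers, x, training)
    net$layers <- r$layers
    return(list(y = r$y, cache = list(caches = r$caches), net = net))
  }
  d <- seq_fw(net$down, x, training); net$down <- d$layers
  if (!is.null(net$sub)) {
    s <- net_fw(net$sub, d$y, training); net$sub <- s$net
    sy <- s$y; scache <- s$cache
  } else { sy <- d$y; scache <- NULL }
  u <- seq_fw(net$up, sy, training); net$up <- u$layers
  y <- if (net$outermost) u$y else concat_c(x, u$y)
  list(y = y, cache = list(down = d$caches, sub = scache, up = u$caches),
       net = net)
}

net_bw <- function(net, cache, dy) {
  if (net$type == "seq") {
    r <- seq_bw(net$layers, cache$caches, dy)
    return(list(dx = r$dx, grads = r$grads))
  }
  if (net$outermost) {
    du <- dy; dxcat <- NULL
  } else {
    c1 <- net$in_ch
    dxcat <- dy[, , seq_len(c1), , drop = FALSE]
    du <- dy[, , (c1 + 1):dim(dy)[3], , drop = FALSE]
  }
  r_up <- seq_bw(net$up, cache$up, du)
  grads <- r_up$grads
  if (!is.null(net$sub)) {
    r_sub <- net_bw(net$sub, cache$sub, r_up$dx)
    grads <- acc_grads(grads, r_sub$grads)
    dd <- r_sub$dx
  } else dd <- r_up$dx
  r_down <- seq_bw(net$down, cache$down, dd)
  grads <- acc_grads(grads, r_down$grads)
  dx <- r_down$dx
  if (!is.null(dxcat)) dx <- dx + dxcat
  list(dx = dx, grads = grads)
}

net_map_layers <- function(net, f) {
  if (net$type == "seq") { net$layers <- lapply(net$layers, f); return(net) }
  net$down <- lapply(net$down, f)
  if (!is.null(net$sub)) net$sub <- net_map_layers(net$sub, f)
  net$up <- lapply(net$up, f)
  net
}

net_params <- function(net) {
  out <- list()
  collect <- function(layer) {
    if (layer$type == "conv") out[[layer$id]] <<- list(W = layer$W, b = layer$b)
    if (layer$type == "bn")
      out[[layer$id]] <<- list(gamma = layer$gamma, beta = layer$beta)
    layer
  }
  net_map_layers(net, collect)
  out
}

# One Adam step over a network's parameters (beta1 = 0.5 as in adversarial
# training practice). `state` is a flat list keyed "<id>.<param>"; returns
# the updated net and state.
adam_update_net <- function(net, grads, state, lr, t,
                            b1 = 0.5, b2 = 0.999, eps = 1e-8) {
  upd <- function(layer) {
    if (is.null(layer$id)) return(layer)
    g <- grads[[layer$id]]
    if (is.null(g)) return(layer)
    for (pn in names(g)) {
      key <- paste0(layer$id, ".", pn)
      mv <- state[[key]]
      if (is.null(mv)) mv <- list(m = g[[pn]] * 0, v = g[[pn]] * 0)
      mv$m <- b1 * mv$m + (1 - b1) * g[[pn]]
      mv$v <- b2 * mv$v + (1 - b2) * g[[pn]]^2
      state[[key]] <<- mv
      layer[[pn]] <- layer[[pn]] -
        lr * (mv$m / (1 - b1^t)) / (sqrt(mv$v / (1 - b2^t)) + eps)
    }
    layer
  }
  net <- net_map_layers(net, upd)
  list(net = net, state = state)
}
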