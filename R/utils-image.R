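# Low-level image helpers shared across modules. Images are plain numeric
# matrices in 8-bit range [0, 255] unless stated otherwise.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations are pure
#' functions of their arguments and never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' One-dimensional Gaussian kernel
#' @keywords internal
gaussian_kernel <- function(sigma, truncate = 3) {
  r <- max(1L, as.integer(floor(truncate * sigma + 0.5)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve each column of X with kernel w, with "nearest" (replicate) or
# "reflect" boundary handling. Vectorised over columns.
conv_cols <- function(X, w, mode = "nearest") {
  r <- (length(w) - 1L) / 2L
  h <- nrow(X)
  out <- matrix(0, h, ncol(X))
  base <- seq_len(h)
  for (k in seq_along(w)) {
    off <- k - r - 1L
    idx <- base + off
    idx <- switch(mode,
      nearest = pmin(pmax(idx, 1L), h),
      reflect = {
        i <- idx
        i[i < 1L] <- 1L - i[i < 1L]
        i[i > h] <- 2L * h + 1L - i[i > h]
        i
      },
      stop("unknown boundary mode: ", mode)
    )
    out <- out + w[k] * X[idx, , drop = FALSE]
  }
  out
}

#' Separable Gaussian filter
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; 0 returns the input unchanged.
#' @param truncate kernel radius in standard deviations.
#' @param mode boundary handling, "nearest" (replicate) or "reflect".
#' @return filtered matrix of the same size.
#' @keywords internal
gaussian_filter2d <- function(img, sigma, truncate = 3, mode = "nearest") {
  if (sigma <= 0) return(img)
  w <- gaussian_kernel(sigma, truncate)
  t(conv_cols(t(conv_cols(img, w, mode)), w, mode))
}

#' Bilinear resize of a grayscale matrix
#'
#' Uses the half-pixel (area-centre) sampling convention. Aspect ratio is not
#' preserved: the image is stretched to exactly `oh` x `ow`.
#'
#' @param img numeric matrix.
#' @param oh,ow output height and width.
#' @return `oh` x `ow` numeric matrix.
#' @keywords internal
resize_bilinear <- function(img, oh, ow) {
  h <- nrow(img); w <- ncol(img)
  if (oh == h && ow == w) return(img)
  interp_mat <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    i0 <- pmin(floor(src), n_in - 1)
    f <- src - i0
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), i0 + 1)] <- 1 - f
    i1 <- pmin(i0 + 1, n_in - 1)
    A[cbind(seq_len(n_out), i1 + 1)] <- A[cbind(seq_len(n_out), i1 + 1)] + f
    A
  }
  interp_mat(oh, h) %*% img %*% t(interp_mat(ow, w))
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# mode (most frequent rounded intensity) of a pixel vector
intensity_mode <- function(v) {
  tab <- tabulate(as.integer(round(v)) + 1L, nbins = 256L)
  which.max(tab) - 1L
}
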