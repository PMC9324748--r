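#' Accessors for karyoCycle containers
#'
#' `pixels()` returns the grayscale pixel matrix of a [KaryogramImage-class]
#' or [PairTile-class]; `karyoLayout()` the layout map (named list of
#' 0-based, half-open `c(x0, y0, x1, y1)` boxes); `tiles()` the list of
#' [PairTile-class] in a [TileSet-class]; `tileLabel()` a tile's chromosome
#' group; `sourceId()` the provenance identifier; `lossHistory()` the
#' per-iteration training losses of a [CycleGANBundle-class].
#'
#' @param x the object.
#' @param value replacement value.
#' @return the slot contents (a matrix, list, character or data.frame).
#' @name accessors
#' @aliases pixels karyoLayout tiles tileLabel sourceId lossHistory
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixels<-", function(x, value) standardGeneric("pixels<-"))
#' @rdname accessors
#' @export
setGeneric("karyoLayout", function(x) standardGeneric("karyoLayout"))
#' @rdname accessors
#' @export
setGeneric("tiles", function(x) standardGeneric("tiles"))
#' @rdname accessors
#' @export
setGeneric("tileLabel", function(x) standardGeneric("tileLabel"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' @rdname accessors
setMethod("pixels", "KaryogramImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "PairTile", function(x) x@pixels)
#' @rdname accessors
setReplaceMethod("pixels", "KaryogramImage", function(x, value) {
  x@pixels <- value; validObject(x); x
})
#' @rdname accessors
setReplaceMethod("pixels", "PairTile", function(x, value) {
  x@pixels <- value; x
})
#' @rdname accessors
setMethod("karyoLayout", "KaryogramImage", function(x) x@layout)
#' @rdname accessors
setMethod("tiles", "TileSet", function(x) x@tiles)
#' @rdname accessors
setMethod("tileLabel", "PairTile", function(x) x@label)
#' @rdname accessors
setMethod("sourceId", "KaryogramImage", function(x) x@sourceId)
#' @rdname accessors
setMethod("sourceId", "PairTile", function(x) x@sourceId)
#' @rdname accessors
setMethod("lossHistory", "CycleGANBundle", function(x) x@history)

setMethod("show", "KaryogramImage", function(object) {
  cat(sprintf("KaryogramImage '%s' (%s): %d x %d px, %d layout regions\n",
              object@sourceId, object@qualityLabel,
              nrow(object@pixels), ncol(object@pixels),
              length(object@layout)))
})

setMethod("show", "PairTile", function(object) {
  norm <- if (length(object@normStats)) "normalized" else "raw"
  cat(sprintf("PairTile chr %s from '%s': %d x %d px (%s)\n",
              object@label, object@sourceId,
              nrow(object@pixels), ncol(object@pixels), norm))
})

setMethod("show", "TileSet", function(object) {
  cat(sprintf("TileSet: %d tiles from karyogram '%s'\n",
              length(object@tiles), object@source@sourceId))
})

setMethod("show", "CycleGANBundle", function(object) {
  it <- if (nrow(object@history)) max(object@history$iteration) else 0L
  cat(sprintf(
    "CycleGANBundle: %s generators (%s norm, base width %d), %d training iterations\n",
    object@netConfig@generatorArch, object@netConfig@norm,
    object@netConfig@baseWidth, it))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d tiles (%d infinite PSNR excluded)\n",
              object@n, object@nInfinite))
  print(round(object@averages, 4))
})
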