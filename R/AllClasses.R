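#' @import methods
NULL

#' Multichannel intracranial recording
#'
#' Container for a multichannel electrocorticography (ECoG) recording:
#' a channels-by-samples numeric matrix with its sampling rate, channel
#' identifiers and the epoch start offset. Amplitude units are passed through
#' unchanged from the source file; they affect the raw modulation-index scale
#' but not downstream z-scores.
#'
#' @slot samples numeric matrix, channels x time (microvolts by convention).
#' @slot rate sampling rate in Hz; must be positive.
#' @slot channelIds character vector of unique channel labels, one per row.
#' @slot t0 start offset of the first sample in seconds.
#'
#' @seealso [ecogRecording()], [readSignal()], [commonAverageReference()]
#' @export
setClass("EcogRecording",
  representation(
    samples = "matrix",
    rate = "numeric",
    channelIds = "character",
    t0 = "numeric"
  ),
  prototype(
    samples = matrix(numeric(0), nrow = 0, ncol = 0),
    rate = 1000, channelIds = character(0), t0 = 0
  )
)

setValidity("EcogRecording", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive number")
  if (nrow(object@samples) != length(object@channelIds))
    msg <- c(msg, "number of channelIds must equal the number of sample rows")
  if (anyDuplicated(object@channelIds))
    msg <- c(msg, "channelIds must be unique")
  if (length(object@samples) && anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA/NaN (drop artifact channels)")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "'t0' must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct an EcogRecording
#'
#' @param samples channels x time numeric matrix.
#' @param rate sampling rate in Hz.
#' @param channelIds channel labels; defaults to the matrix rownames or
#'   `"ch1"`, `"ch2"`, ...
#' @param t0 start offset in seconds.
#' @return An [EcogRecording-class] object.
#' @examples
#' rec <- ecogRecording(matrix(rnorm(2000), nrow = 2), rate = 1000)
#' nChannels(rec)
#' @export
ecogRecording <- function(samples, rate, channelIds = NULL, t0 = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channelIds)) {
    channelIds <- rownames(samples)
    if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(nrow(samples)))
  }
  rownames(samples) <- channelIds
  new("EcogRecording", samples = samples, rate = as.numeric(rate),
      channelIds = as.character(channelIds), t0 = as.numeric(t0))
}

#' Epoch specification
#'
#' Start times and common duration of the analysis epochs (by default ten
#' 30-second epochs of slow-wave sleep). Epoch selection (sleep staging) is
#' caller-supplied; this class only carries the chosen windows.
#'
#' @slot onsets epoch start times in seconds, non-overlapping given `duration`.
#' @slot duration epoch duration in seconds.
#' @export
setClass("EpochSpec",
  representation(onsets = "numeric", duration = "numeric"),
  prototype(onsets = numeric(0), duration = 30)
)

setValidity("EpochSpec", function(object) {
  msg <- character(0)
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0)
    msg <- c(msg, "'duration' must be a single positive number")
  if (length(object@onsets)) {
    if (anyNA(object@onsets)) msg <- c(msg, "'onsets' must be finite")
    o <- sort(object@onsets)
    if (length(o) > 1L && any(diff(o) < object@duration - 1e-9))
      msg <- c(msg, "epochs overlap given 'duration'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSpec
#'
#' @param onsets epoch start times (s).
#' @param duration epoch length (s); default 30.
#' @return An [EpochSpec-class] object.
#' @examples
#' epochSpec(seq(0, by = 30, length.out = 10))
#' @export
epochSpec <- function(onsets, duration = 30) {
  new("EpochSpec", onsets = as.numeric(onsets), duration = as.numeric(duration))
}

#' Triangulated cortical surface mesh
#'
#' Vertices and triangles of the average-brain surface onto which electrodes
#' are spatially normalised. Coordinates are millimetres in average-brain
#' space; vertex and face indices are 1-based throughout the package
#' (converted at format boundaries where a file format differs).
#'
#' @slot vertices V x 3 numeric matrix of coordinates (mm).
#' @slot faces F x 3 integer matrix of vertex indices (1-based).
#' @seealso [readSurface()], [assignVertex()], [sphereMesh()]
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix")
)

setValidity("SurfaceMesh", function(object) {
  msg <- character(0)
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) msg <- c(msg, "'vertices' must have 3 columns")
  if (nrow(v) < 3L) msg <- c(msg, "a mesh needs at least 3 vertices")
  if (ncol(f) != 3L) msg <- c(msg, "'faces' must have 3 columns")
  if (length(f)) {
    if (min(f) < 1L || max(f) > nrow(v))
      msg <- c(msg, "face indices must lie in 1..V")
    degen <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(degen))
      msg <- c(msg, sprintf("degenerate face(s) with repeated vertex: %s",
                            paste(which(degen)[1:min(3, sum(degen))],
                                  collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SurfaceMesh
#'
#' @param vertices V x 3 coordinate matrix (mm).
#' @param faces F x 3 matrix of 1-based vertex indices.
#' @return A [SurfaceMesh-class] object.
#' @export
surfaceMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  new("SurfaceMesh", vertices = vertices, faces = faces)
}

#' Normative modulation-index atlas
#'
#' Per-vertex mean and standard deviation of the modulation index over the
#' k closest non-epileptic recording sites, computed on a given surface mesh.
#' Scoring an electrode against the atlas yields its MI z-score.
#'
#' @slot meanMi numeric vector, mean MI at each mesh vertex.
#' @slot sdMi numeric vector, sample SD (k - 1 denominator) at each vertex.
#' @slot k neighbourhood size used (number of closest sites).
#' @slot nPool total number of non-epileptic sites in the pool.
#' @slot kthDist optional diagnostic: per-vertex distance (mm) to the k-th
#'   closest pool site (empty when read from file).
#' @seealso [buildAtlas()], [miZscore()], [readAtlas()]
#' @export
setClass("NormativeAtlas",
  representation(meanMi = "numeric", sdMi = "numeric",
                 k = "integer", nPool = "integer", kthDist = "numeric"),
  prototype(kthDist = numeric(0))
)

setValidity("NormativeAtlas", function(object) {
  msg <- character(0)
  if (length(object@meanMi) != length(object@sdMi))
    msg <- c(msg, "meanMi and sdMi must have one value per vertex")
  if (any(object@sdMi < 0, na.rm = TRUE)) msg <- c(msg, "sdMi must be >= 0")
  if (length(object@k) != 1L || object@k < 2L)
    msg <- c(msg, "'k' must be a single integer >= 2")
  if (length(object@nPool) != 1L || object@nPool < object@k)
    msg <- c(msg, "'nPool' must be >= k")
  if (length(msg)) msg else TRUE
})

normativeAtlas <- function(meanMi, sdMi, k, nPool) {
  new("NormativeAtlas", meanMi = as.numeric(meanMi), sdMi = as.numeric(sdMi),
      k = as.integer(k), nPool = as.integer(nPool))
}

## ---- accessors ----

#' @describeIn EcogRecording-class number of channels
#' @param x,object an object of the documented class.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setMethod("nChannels", "EcogRecording", function(x) nrow(x@samples))

#' @describeIn EcogRecording-class number of samples per channel
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setMethod("nSamples", "EcogRecording", function(x) ncol(x@samples))

#' @describeIn EcogRecording-class sampling rate (Hz)
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setMethod("samplingRate", "EcogRecording", function(x) x@rate)

#' @describeIn EcogRecording-class channel labels
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @export
setMethod("channelIds", "EcogRecording", function(x) x@channelIds)

#' @describeIn EcogRecording-class channels x time sample matrix
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @export
setMethod("samples", "EcogRecording", function(x) x@samples)

#' @describeIn SurfaceMesh-class vertex coordinate matrix
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)

#' @describeIn SurfaceMesh-class face index matrix
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)

#' @describeIn SurfaceMesh-class number of vertices
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))

#' @describeIn NormativeAtlas-class per-vertex mean MI
#' @export
setGeneric("atlasMean", function(x) standardGeneric("atlasMean"))
#' @export
setMethod("atlasMean", "NormativeAtlas", function(x) x@meanMi)

#' @describeIn NormativeAtlas-class per-vertex sample SD of MI
#' @export
setGeneric("atlasSd", function(x) standardGeneric("atlasSd"))
#' @export
setMethod("atlasSd", "NormativeAtlas", function(x) x@sdMi)

#' @describeIn NormativeAtlas-class neighbourhood size k
#' @export
setGeneric("atlasK", function(x) standardGeneric("atlasK"))
#' @export
setMethod("atlasK", "NormativeAtlas", function(x) x@k)

#' @describeIn NormativeAtlas-class size of the non-epileptic pool
#' @export
setGeneric("atlasPoolSize", function(x) standardGeneric("atlasPoolSize"))
#' @export
setMethod("atlasPoolSize", "NormativeAtlas", function(x) x@nPool)

## ---- show methods ----

#' @rdname EcogRecording-class
#' @export
setMethod("show", "EcogRecording", function(object) {
  cat(sprintf("EcogRecording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nChannels(object), nSamples(object), object@rate,
              nSamples(object) / object@rate))
  if (nChannels(object))
    cat("  channels:", paste(utils::head(object@channelIds, 6),
                             collapse = ", "),
        if (nChannels(object) > 6) "..." else "", "\n")
})

#' @rdname EpochSpec-class
#' @export
setMethod("show", "EpochSpec", function(object) {
  cat(sprintf("EpochSpec: %d epoch(s) of %g s\n",
              length(object@onsets), object@duration))
})

#' @rdname SurfaceMesh-class
#' @export
setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

#' @rdname NormativeAtlas-class
#' @export
setMethod("show", "NormativeAtlas", function(object) {
  cat(sprintf(
    "NormativeAtlas: %d vertices; k = %d of %d non-epileptic sites\n",
    length(object@meanMi), object@k, object@nPool))
  cat(sprintf("  mean MI range: [%.4g, %.4g]\n",
              min(object@meanMi), max(object@meanMi)))
})

#' @describeIn EpochSpec-class number of epochs
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @export
setMethod("nEpochs", "EpochSpec", function(x) length(x@onsets))

#' @describeIn EpochSpec-class epoch onset times (s)
#' @export
setGeneric("epochOnsets", function(x) standardGeneric("epochOnsets"))
#' @export
setMethod("epochOnsets", "EpochSpec", function(x) x@onsets)

#' @describeIn EpochSpec-class epoch duration (s)
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))
#' @export
setMethod("epochDuration", "EpochSpec", function(x) x@duration)
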