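#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small family of accessor generics shared by the imaging containers:
#' `frameRate()` (frames per second), `pixelSize()` (micrometres per pixel),
#' `nFrames()` (number of frames/time points), `frames()` (the raw intensity
#' array), `dff()` (the \eqn{\Delta F/F_0} matrix of an [STMap]) and
#' `binSize()` (micrometres per spatial bin of an [STMap]).
#'
#' @param x an object.
#' @return `frameRate`, `pixelSize`, `binSize` return a single numeric;
#'   `nFrames` an integer; `frames` a 3-D numeric array; `dff` a numeric
#'   matrix (space bins x frames).
#' @name accessors
#' @aliases frameRate pixelSize nFrames frames dff binSize
#' @examples
#' mv <- CalciumMovie(array(1, c(4, 4, 5)), frameRate = 33, pixelSize = 0.5)
#' frameRate(mv)
#' nFrames(mv)
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
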