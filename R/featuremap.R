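#' Feature maps
#'
#' A feature map is a rank-4 numeric array in `(batch, channels, height,
#' width)` order, the carrier passed between all network blocks.  Internally
#' the package computes on an `(h, w, c, n)` layout (spatial dimensions first
#' so window extraction is contiguous); [feature_map()] and [fm_array()]
#' convert between the two.
#'
#' @param data numeric array with dimensions `(n, c, h, w)`, all `>= 1`,
#'   finite values.
#' @return an object of class `feature_map` wrapping the internal array.
#' @examples
#' x <- feature_map(array(rnorm(1 * 3 * 8 * 8), dim = c(1, 3, 8, 8)))
#' fm_shape(x)
#' @export
feature_map <- function(data) {
  d <- dim(data)
  if (is.null(d) || length(d) != 4L)
    stop("feature_map: `data` must be a rank-4 array (batch, channels, height, width)")
  if (any(d < 1L)) stop("feature_map: all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("feature_map: values must be finite")
  internal <- aperm(data, c(3L, 4L, 2L, 1L))
  structure(list(a = internal), class = "feature_map")
}

fm_internal <- function(x) {
  if (inherits(x, "feature_map")) x$a
  else if (is.array(x) && length(dim(x)) == 4L) x  # already internal
  else stop("expected a feature_map")
}

fm_wrap <- function(internal) structure(list(a = internal), class = "feature_map")

#' @describeIn feature_map recover the `(n, c, h, w)` array.
#' @param x a `feature_map`.
#' @export
fm_array <- function(x) aperm(fm_internal(x), c(4L, 3L, 1L, 2L))

#' @describeIn feature_map shape as `c(n, c, h, w)`.
#' @export
fm_shape <- function(x) dim(fm_internal(x))[c(4L, 3L, 1L, 2L)]

#' @export
print.feature_map <- function(x, ...) {
  s <- fm_shape(x)
  cat(sprintf("<feature_map %d x %d x %d x %d (n,c,h,w)>\n", s[1L], s[2L], s[3L], s[4L]))
  invisible(x)
}

## run a seeded block of code without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
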