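#' Construct a circular morph wheel
#'
#' A morph wheel is a closed circular continuum of face images built from
#' three anchor ("prototype") identities with `n_between` morphs interpolated
#' between each consecutive pair, giving `3 + 3 * n_between` positions in
#' total. The default (`n_between = 46`) is the 141-image wheel; with a
#' category half-width of 23 steps the three prototype categories partition
#' the wheel exactly (3 x 47 = 141).
#'
#' Positions are 0-based wheel indices; the anchors sit at
#' `0, n_between + 1, 2 * (n_between + 1)`.
#'
#' @param n_between number of morphed images between each pair of anchors
#'   (default 46).
#' @param boundary_halfwidth category extent in morph steps on either side
#'   of each anchor (default 23).
#' @param allow_nonpartition logical; if `FALSE` (default) the constructor
#'   rejects a `boundary_halfwidth` whose categories do not tile the wheel
#'   exactly.
#' @return an object of class `"morph_wheel"`: a list with `n_positions`,
#'   `n_between`, `anchors` (integer vector of three 0-based indices),
#'   `boundary_halfwidth`, and `partitions` (logical).
#' @examples
#' w <- morph_wheel()
#' w$n_positions        # 141
#' w$anchors            # 0 47 94
#' @export
morph_wheel <- function(n_between = 46L, boundary_halfwidth = 23L,
                        allow_nonpartition = FALSE) {
  n_between <- as.integer(n_between)
  boundary_halfwidth <- as.integer(boundary_halfwidth)
  if (length(n_between) != 1L || is.na(n_between) || n_between < 1L)
    stop("`n_between` must be a positive integer")
  if (length(boundary_halfwidth) != 1L || is.na(boundary_halfwidth) ||
      boundary_halfwidth < 0L)
    stop("`boundary_halfwidth` must be a non-negative integer")
  n <- 3L + 3L * n_between
  partitions <- 3L * (2L * boundary_halfwidth + 1L) == n
  if (!partitions && !allow_nonpartition)
    stop("categories with halfwidth ", boundary_halfwidth,
         " do not partition a wheel of ", n,
         " positions; pass allow_nonpartition = TRUE to override")
  structure(
    list(n_positions = n,
         n_between = n_between,
         anchors = c(0L, n_between + 1L, 2L * (n_between + 1L)),
         boundary_halfwidth = boundary_halfwidth,
         partitions = partitions),
    class = "morph_wheel")
}

#' @export
print.morph_wheel <- function(x, ...) {
  cat("Morph wheel:", x$n_positions, "positions,",
      "anchors at", paste(x$anchors, collapse = ", "),
      sprintf("(category halfwidth %d, %s)\n", x$boundary_halfwidth,
              if (x$partitions) "partitioning" else "non-partitioning"))
  invisible(x)
}

check_positions <- function(pos, wheel, arg = "position") {
  if (any(!is.finite(pos)) || any(pos != floor(pos)) ||
      any(pos < 0) || any(pos >= wheel$n_positions))
    stop(arg, " must be integer wheel indices in [0, ",
         wheel$n_positions - 1L, "]")
  invisible(TRUE)
}

#' Signed shortest circular distance between wheel positions
#'
#' Returns the signed shortest distance in morph steps from `from` to `to`
#' on the wheel, positive in the direction of increasing index (with
#' wraparound, "clockwise") and negative the other way. For an odd wheel
#' (141 positions) the result is unique in `[-(n-1)/2, (n-1)/2]`; for an
#' even wheel the antipodal tie is resolved to `+n/2`.
#'
#' @param from,to wheel indices (vectors recycle as usual).
#' @param wheel a [morph_wheel()].
#' @return integer vector of signed morph steps.
#' @examples
#' w <- morph_wheel()
#' signed_distance(140, 0, w)   # +1 across the wrap
#' signed_distance(0, 71, w)    # -70
#' @export
signed_distance <- function(from, to, wheel) {
  check_positions(from, wheel, "`from`")
  check_positions(to, wheel, "`to`")
  n <- wheel$n_positions
  d <- (to - from) %% n
  d[d > n / 2] <- d[d > n / 2] - n
  as.integer(d)
}

#' Prototype category of a wheel position
#'
#' Each of the three anchor faces is the prototype of one category whose
#' extent is `boundary_halfwidth` morph steps on either side of the anchor.
#' On the default wheel (141 positions, halfwidth 23) the categories tile
#' the wheel with 47 positions each.
#'
#' @param pos wheel index (vectorised).
#' @param wheel a [morph_wheel()]; must partition.
#' @return integer vector of category ids in `{1, 2, 3}`.
#' @examples
#' w <- morph_wheel()
#' category_of(c(0, 23, 24, 118), w)   # 1 1 2 1
#' @export
category_of <- function(pos, wheel) {
  check_positions(pos, wheel, "`pos`")
  if (!wheel$partitions)
    stop("category_of() requires a partitioning wheel")
  n <- wheel$n_positions
  out <- integer(length(pos))
  for (k in 1:3) {
    d <- (pos - wheel$anchors[k]) %% n
    d[d > n / 2] <- d[d > n / 2] - n
    out[abs(d) <= wheel$boundary_halfwidth] <- k
  }
  out
}
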