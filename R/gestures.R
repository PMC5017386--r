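#' The nine WHO hand-hygiene gestures
#'
#' The WHO hand-rub/hand-wash routine consists of six basic movements; the
#' ones performed once per leading hand expand into left/right variants,
#' giving nine gestures. The codes, in routine order, are: `G1` (palm to
#' palm), `G2L`/`G2R` (back of hand and between fingers), `G3` (palm to palm
#' with fingers interlaced), `G4` (back of fingers), `G5L`/`G5R` (thumbs),
#' `G6L`/`G6R` (fingertips and nails). `L`/`R` mark the leading hand.
#'
#' @return `gesture_codes()` returns the character vector of the nine codes
#'   in routine order.
#' @examples
#' gesture_codes()
#' gesture_ordinal(c("G3", "G1"))
#' @export
gesture_codes <- function() {
  c("G1", "G2L", "G2R", "G3", "G4", "G5L", "G5R", "G6L", "G6R")
}

#' @rdname gesture_codes
#' @param x A character vector (or factor) of gesture codes.
#' @return `gesture_factor()` returns `x` as a factor with the nine codes as
#'   levels in routine order; unknown codes are an error.
#' @export
gesture_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), gesture_codes())
  if (length(bad) > 0) {
    abort(sprintf("unknown gesture label(s): %s", paste(bad, collapse = ", ")),
          class = "handwashr_validation_error")
  }
  factor(x, levels = gesture_codes())
}

#' @rdname gesture_codes
#' @return `gesture_ordinal()` returns the 0-based routine position of each
#'   code (G1 = 0, ..., G6R = 8).
#' @export
gesture_ordinal <- function(x) {
  as.integer(gesture_factor(x)) - 1L
}
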