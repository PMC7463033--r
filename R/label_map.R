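#' Ordered label positions of an optical map
#'
#' A label map holds the ordered bp positions of labels on one map: an
#' in-silico digested genomic segment, an assembled consensus contig, or a
#' single molecule.
#'
#' @param map_id identifier (coerced to character).
#' @param length_bp total map length in bp (positive).
#' @param positions strictly increasing label coordinates in bp, 1-based,
#'   each in `(0, length_bp]`. May be empty (an unlabeled map).
#' @param channel label channel (default 1).
#' @return An object of class `label_map`.
#' @export
label_map <- function(map_id, length_bp, positions = numeric(0), channel = 1L) {
  positions <- as.numeric(positions)
  length_bp <- as.numeric(length_bp)
  if (!is.finite(length_bp) || length_bp <= 0)
    stop("label_map: length_bp must be positive (map ", map_id, ")")
  if (length(positions)) {
    if (any(diff(positions) <= 0))
      stop("label_map: positions must be strictly increasing (map ", map_id, ")")
    if (positions[1] <= 0 || positions[length(positions)] > length_bp)
      stop("label_map: positions must lie in (0, length_bp] (map ", map_id, ")")
  }
  structure(list(map_id = as.character(map_id), length_bp = length_bp,
                 positions = positions, channel = as.integer(channel)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s: %.0f bp, %d labels\n",
              x$map_id, x$length_bp, length(x$positions)))
  invisible(x)
}

#' Number of labels on a label map
#' @param x a `label_map`.
#' @return integer label count.
#' @export
n_labels <- function(x) length(x$positions)

#' Reverse a label map
#'
#' Returns the map read from the opposite end: positions become
#' `length_bp - rev(positions)`.
#' @param x a `label_map`.
#' @return a `label_map`.
#' @export
reverse_label_map <- function(x) {
  label_map(x$map_id, x$length_bp, rev(x$length_bp - x$positions), x$channel)
}
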