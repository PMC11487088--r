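# Injury outline stacks: per-z-plane polygon outlines of the wound,
# as produced by plane-after-plane manual outlining.

#' Create an outline stack
#'
#' @param outlines List of elements, each a list with `z_index` (integer)
#'   and `vertices` (two-column matrix, um). May be empty (fully closed
#'   wound).
#' @param z_step Spacing between outlined planes in micrometres.
#' @return An object of class `outline_stack`.
#' @export
outline_stack <- function(outlines, z_step) {
  if (!is.numeric(z_step) || z_step <= 0) stop("z_step must be positive")
  outlines <- lapply(outlines, function(o) {
    v <- as_polygon(o$vertices)
    if (!polygon_is_simple(v))
      stop("self-intersecting outline at z_index ", o$z_index)
    list(z_index = as.integer(o$z_index), vertices = v)
  })
  structure(list(outlines = outlines, z_step = as.numeric(z_step)),
            class = "outline_stack")
}

#' @export
print.outline_stack <- function(x, ...) {
  cat(sprintf("<outline_stack> %d plane(s), z_step %g um\n",
              length(x$outlines), x$z_step))
  invisible(x)
}

#' @export
length.outline_stack <- function(x) length(x$outlines)

#' Read an outline stack from JSON
#'
#' Expected layout: `{"z_step_um": s, "outlines": [{"z_index": i,
#' "x_um": [...], "y_um": [...]}, ...]}`.
#'
#' @param path Path to a JSON file.
#' @return An [outline_stack()].
#' @export
read_outline_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$z_step_um)) stop("missing 'z_step_um' metadata in ", path)
  outs <- obj$outlines
  if (is.null(outs) || (is.data.frame(outs) && !nrow(outs)) ||
      (!is.data.frame(outs) && !length(outs))) {
    return(outline_stack(list(), z_step = obj$z_step_um))
  }
  if (is.data.frame(outs)) {
    outs <- lapply(seq_len(nrow(outs)), function(i)
      list(z_index = outs$z_index[i],
           x_um = outs$x_um[[i]], y_um = outs$y_um[[i]]))
  }
  outlines <- lapply(outs, function(o) {
    if (is.null(o$z_index) || is.null(o$x_um) || is.null(o$y_um))
      stop("outline entries need z_index, x_um, y_um fields")
    list(z_index = o$z_index,
         vertices = cbind(as.numeric(unlist(o$x_um)),
                          as.numeric(unlist(o$y_um))))
  })
  outline_stack(outlines, z_step = obj$z_step_um)
}

#' Write an outline stack to JSON
#'
#' Inverse of [read_outline_stack()]; coordinates are written at full
#' double precision so the round trip is lossless.
#'
#' @param os An [outline_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outline_stack <- function(os, path) {
  stopifnot(inherits(os, "outline_stack"))
  obj <- list(
    z_step_um = os$z_step,
    outlines = lapply(os$outlines, function(o)
      list(z_index = o$z_index, x_um = o$vertices[, 1],
           y_um = o$vertices[, 2]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
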