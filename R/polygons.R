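#' Polygon label sets and their rasterisation
#'
#' Expert labels arrive as polygons in pixel coordinates with two classes:
#' `plumage` and `non_plumage`. Non-plumage polygons may nest inside plumage
#' polygons (eyes, feet), carving holes out of the plumage mask.
#'
#' Coordinate convention: 0-based continuous pixel coordinates with x along
#' columns and y along rows, row 0 at the top; the centre of matrix cell
#' `[i, j]` is `(x = j - 0.5, y = i - 0.5)`. A pixel belongs to a polygon if
#' its centre lies inside it.
#'
#' @param polygons list of polygons, each a list with `class`
#'   ("plumage"/"non_plumage") and `xy` (n x 2 matrix of vertices)
#' @return object of class `label_polygon_set`
#' @export
label_polygon_set <- function(polygons) {
  for (p in polygons) {
    stopifnot(is.list(p), p$class %in% c("plumage", "non_plumage"))
    if (nrow(p$xy) < 3) {
      uvp_stop("bounds_error", "polygons need at least 3 vertices")
    }
  }
  structure(list(polygons = polygons), class = "label_polygon_set")
}

#' Rasterise polygon labels to a binary plumage mask
#'
#' A pixel is plumage iff its centre lies inside at least one plumage polygon
#' and inside no non-plumage polygon (nested holes win). Point-in-polygon
#' testing uses `mgcv::in.out`.
#'
#' @param polys a `label_polygon_set` (or bare list accepted by it)
#' @param shape integer c(rows, cols) of the target mask
#' @return logical matrix, TRUE = plumage
#' @export
polygons_to_mask <- function(polys, shape) {
  if (!inherits(polys, "label_polygon_set")) polys <- label_polygon_set(polys)
  nr <- shape[1]; nc <- shape[2]
  for (p in polys$polygons) {
    if (any(p$xy[, 1] < 0 | p$xy[, 1] > nc | p$xy[, 2] < 0 | p$xy[, 2] > nr)) {
      uvp_stop("bounds_error", "polygon vertex outside image bounds")
    }
  }
  if (length(polys$polygons) == 0) return(matrix(FALSE, nr, nc))

  centres <- cbind(
    x = rep(seq_len(nc) - 0.5, each = nr),
    y = rep(seq_len(nr) - 0.5, times = nc)
  )
  inside <- function(p) {
    bnd <- rbind(p$xy, p$xy[1, , drop = FALSE]) # close the loop
    matrix(mgcv::in.out(bnd, centres), nr, nc)
  }
  plum <- matrix(FALSE, nr, nc)
  hole <- matrix(FALSE, nr, nc)
  for (p in polys$polygons) {
    if (p$class == "plumage") plum <- plum | inside(p) else hole <- hole | inside(p)
  }
  plum & !hole
}

#' Read / write polygon label sets as structured text
#'
#' Plain YAML: a list of polygons, each with a class and an n x 2 vertex list.
#'
#' @param polys a `label_polygon_set`
#' @param path file path
#' @export
write_polygons <- function(polys, path) {
  yaml::write_yaml(lapply(polys$polygons, function(p) {
    list(class = p$class, xy = lapply(seq_len(nrow(p$xy)),
                                      function(i) as.numeric(p$xy[i, ])))
  }), path)
  invisible(path)
}

#' @rdname write_polygons
#' @export
read_polygons <- function(path) {
  raw <- yaml::read_yaml(path)
  label_polygon_set(lapply(raw, function(p) {
    list(class = p$class, xy = do.call(rbind, lapply(p$xy, as.numeric)))
  }))
}
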