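#' Polygon annotation
#'
#' An ordered ring of `(x, y)` vertices in pixel coordinates (1-based,
#' `x` = column, `y` = row) together with a class name, as produced by
#' polygon annotation tools.
#'
#' @param vertices two-column numeric matrix (or data.frame) of `(x, y)`
#'   coordinates; at least 3 non-collinear vertices.
#' @param class_name character scalar.
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(vertices, class_name = "region") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3 || anyNA(v)) {
    cg_stop("cg_annotation_error",
            "polygon needs >= 3 finite (x, y) vertices, got %d", nrow(v))
  }
  # collinearity: every vertex triple has (near-)zero cross product
  x <- v[, 1]; y <- v[, 2]
  cross <- (x[2] - x[1]) * (y - y[1]) - (y[2] - y[1]) * (x - x[1])
  if (max(abs(cross)) < 1e-9) {
    cg_stop("cg_annotation_error", "degenerate polygon: all vertices collinear")
  }
  structure(list(vertices = unname(v), class_name = as.character(class_name)),
            class = "polygon_annotation")
}

# Even-odd point-in-polygon for a grid of pixel centers; points exactly on a
# boundary segment count as inside. Returns a logical h x w matrix.
polygon_interior <- function(vertices, h, w) {
  px <- rep(seq_len(w), each = h)   # x = column
  py <- rep(seq_len(h), times = w)  # y = row
  n <- nrow(vertices)
  xs <- vertices[, 1]; ys <- vertices[, 2]
  inside <- logical(h * w)
  onedge <- logical(h * w)
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # boundary test: collinear with the segment and within its bounding box
    d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (seg_len > eps) {
      on_seg <- d / seg_len < eps &
        px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
        py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
      onedge <- onedge | on_seg
    }
    j <- i
  }
  matrix(inside | onedge, nrow = h, ncol = w)
}

#' Rasterize polygon annotations into a label mask
#'
#' Fills each polygon's interior onto a blank mask in input order: the k-th
#' annotation receives label `k` and later polygons overwrite earlier ones
#' where they overlap. A pixel belongs to a polygon iff its center is inside
#' or on the boundary under the even-odd rule.
#'
#' @param annotations list of [polygon_annotation()] objects (may be empty).
#' @param image_size integer vector `c(height, width)`.
#' @return A [label_mask()].
#' @export
rasterize_polygons <- function(annotations, image_size) {
  stopifnot(length(image_size) == 2, all(image_size >= 1))
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  out <- matrix(0L, h, w)
  for (k in seq_along(annotations)) {
    ann <- annotations[[k]]
    if (!inherits(ann, "polygon_annotation")) {
      cg_stop("cg_annotation_error", "annotation %d is not a polygon_annotation", k)
    }
    v <- ann$vertices
    if (any(v[, 1] < 1 - 1e-9) || any(v[, 1] > w + 1e-9) ||
        any(v[, 2] < 1 - 1e-9) || any(v[, 2] > h + 1e-9)) {
      cg_stop("cg_coordinate_error",
              "annotation %d has vertices outside the %dx%d canvas", k, h, w)
    }
    out[polygon_interior(v, h, w)] <- k
  }
  label_mask(out)
}

#' Read LabelMe-style polygon annotations from JSON
#'
#' Expects the LabelMe layout: a top-level `shapes` list whose entries carry
#' `label` and `points` fields. LabelMe's 0-based coordinates are shifted to
#' this package's 1-based pixel frame.
#'
#' @param path path to a JSON annotation file.
#' @return List of [polygon_annotation()] objects.
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$shapes)) {
    cg_stop("cg_annotation_error", "no 'shapes' field in %s", path)
  }
  lapply(doc$shapes, function(sh) {
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    polygon_annotation(pts + 1, class_name = sh$label %||% "region")
  })
}
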