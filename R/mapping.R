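# Graph -> mask -> image correspondence for case reporting.

strip_stem <- function(path) {
  s <- sub("\\.[^.]+$", "", basename(path))
  sub("^(graph|mask|img|image)_", "", s)
}

#' Build the graph-to-mask-to-image mapping table
#'
#' Associates files by (class subdirectory, filename stem), where the stem
#' is the filename without extension and without a `graph_`/`mask_`/`img_`
#' role prefix. Every graph must map to exactly one (mask, image) pair; any
#' graph without a counterpart aborts with an orphan error naming the
#' missing stems.
#'
#' @param graph_dir directory of `<class>/graph_*.gml` files.
#' @param mask_dir directory of `<class>/mask_*.png` files.
#' @param image_dir directory of `<class>/img_*.png` files (may equal
#'   `mask_dir`).
#' @return Data.frame with columns `class`, `stem`, `graph_path`,
#'   `mask_path`, `image_path`.
#' @export
build_mapping <- function(graph_dir, mask_dir, image_dir = mask_dir) {
  for (d in c(graph_dir, mask_dir, image_dir)) {
    if (!dir.exists(d)) cg_stop("cg_io_error", "directory %s does not exist", d)
  }
  graphs <- list.files(graph_dir, pattern = "\\.gml$", recursive = TRUE,
                       full.names = FALSE)
  if (length(graphs) == 0) cg_stop("cg_io_error", "no graphs under %s", graph_dir)
  masks <- list.files(mask_dir, pattern = "^mask_.*\\.png$", recursive = TRUE)
  images <- list.files(image_dir, pattern = "^img_.*\\.png$", recursive = TRUE)
  key <- function(paths) paste(dirname(paths), strip_stem(paths), sep = "/")
  mask_key <- stats::setNames(masks, key(masks))
  img_key <- stats::setNames(images, key(images))
  gk <- key(graphs)
  orphans <- graphs[!(gk %in% names(mask_key)) | !(gk %in% names(img_key))]
  if (length(orphans) > 0) {
    cg_stop("cg_orphan_error", "graphs without mask/image counterpart: %s",
            paste(strip_stem(orphans), collapse = ", "))
  }
  if (anyDuplicated(gk)) {
    cg_stop("cg_orphan_error", "duplicate graph stems: mapping must be single-valued")
  }
  data.frame(class = dirname(graphs), stem = strip_stem(graphs),
             graph_path = file.path(graph_dir, graphs),
             mask_path = file.path(mask_dir, mask_key[gk]),
             image_path = file.path(image_dir, img_key[gk]),
             stringsAsFactors = FALSE)
}

#' Render a per-case report
#'
#' Writes a side-by-side PNG montage (original image, mask, lesion overlay)
#' and a JSON sidecar holding the true and predicted classes, the graph
#' summary and any metrics. Output paths derive deterministically from the
#' case stem.
#'
#' @param row one row of a [build_mapping()] table (as a list or 1-row
#'   data.frame).
#' @param prediction predicted class label (string or index).
#' @param metrics optional named list included verbatim in the sidecar.
#' @param out_dir output directory.
#' @return Named list with the written `png` and `json` paths, invisibly.
#' @export
render_case_report <- function(row, prediction, metrics = NULL, out_dir) {
  row <- as.list(row)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img <- read_gray_png(row$image_path)
  msk <- read_mask_png(row$mask_path)
  gr <- read_gml(row$graph_path)
  fg <- msk$labels > 0
  overlay <- img$pixels
  overlay[fg] <- 0.65 * overlay[fg] + 0.35
  mask_vis <- if (max(msk$labels) > 0) msk$labels / max(msk$labels) else msk$labels
  montage <- cbind(img$pixels, mask_vis, clip01(overlay))
  png_path <- file.path(out_dir, sprintf("%s_%s_report.png", row$class, row$stem))
  json_path <- sub("\\.png$", ".json", png_path)
  png::writePNG(montage, png_path)
  jsonlite::write_json(list(
    stem = row$stem, class_true = row$class,
    class_predicted = as.character(prediction),
    graph = list(nodes = nrow(gr$nodes), edges = nrow(gr$edges),
                 class_label = gr$class_label),
    mask_foreground_px = sum(fg),
    overlay_highlight_px = sum(fg),
    metrics = metrics
  ), json_path, auto_unbox = TRUE, digits = 10)
  invisible(list(png = png_path, json = json_path))
}
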