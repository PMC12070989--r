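# GML (Graph Modelling Language) serialization of lesion graphs.
#
# The writer/reader handle the package's fixed schema. GML keys may not
# contain underscores, so feature names are camelCased in the files and
# mapped back on read. Numbers are printed with 10 significant digits.

gml_key_map <- c(
  area = "area", perimeter = "perimeter", eccentricity = "eccentricity",
  solidity = "solidity", major_axis = "majorAxis", minor_axis = "minorAxis",
  aspect_ratio = "aspectRatio", compactness = "compactness",
  circularity = "circularity", glcm_contrast = "glcmContrast",
  glcm_correlation = "glcmCorrelation", glcm_energy = "glcmEnergy",
  glcm_homogeneity = "glcmHomogeneity", mean_intensity = "meanIntensity"
)

fmt_num <- function(x) sprintf("%.10g", x)

#' Write a lesion graph as GML
#'
#' Standard GML grammar: a `graph` block carrying `classLabel` and
#' `provenance` attributes (plus `seed` and `threshold` for augmented
#' graphs), one `node` block per region with the 14 named feature
#' attributes, and one `edge` block per edge with a `weight` attribute.
#' Node order is preserved and the round trip is lossless to 10 significant
#' digits.
#'
#' @param graph a [lesion_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gml <- function(graph, path) {
  stopifnot(inherits(graph, "lesion_graph"))
  out <- c("graph [", "  directed 0",
           sprintf('  classLabel "%s"', graph$class_label),
           sprintf('  provenance "%s"', graph$provenance$kind))
  if (!is.null(graph$provenance$seed)) {
    out <- c(out, sprintf("  seed %d", as.integer(graph$provenance$seed)))
  }
  if (!is.null(graph$provenance$u)) {
    out <- c(out, sprintf("  threshold %s", fmt_num(graph$provenance$u)))
  }
  for (r in seq_len(nrow(graph$nodes))) {
    out <- c(out, "  node [",
             sprintf("    id %d", as.integer(graph$nodes$node_id[r])),
             sprintf("    %s %s", gml_key_map,
                     fmt_num(unlist(graph$nodes[r, cg_feature_names]))),
             "  ]")
  }
  for (r in seq_len(nrow(graph$edges))) {
    out <- c(out, "  edge [",
             sprintf("    source %d", as.integer(graph$nodes$node_id[graph$edges$i[r]])),
             sprintf("    target %d", as.integer(graph$nodes$node_id[graph$edges$j[r]])),
             sprintf("    weight %s", fmt_num(graph$edges$weight[r])),
             "  ]")
  }
  out <- c(out, "]")
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_gml
#' @export
read_gml <- function(path) {
  lines <- readLines(path)
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[[:space:]]+"))
  toks <- toks[toks != ""]
  # re-join quoted strings
  i <- 1
  tokens <- list()
  while (i <= length(toks)) {
    t <- toks[i]
    if (startsWith(t, '"') && !(endsWith(t, '"') && nchar(t) > 1)) {
      j <- i + 1
      while (j <= length(toks) && !endsWith(toks[j], '"')) j <- j + 1
      t <- paste(toks[i:j], collapse = " ")
      i <- j
    }
    tokens[[length(tokens) + 1]] <- t
    i <- i + 1
  }
  toks <- unlist(tokens)
  pos <- 1
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1; t }
  parse_block <- function() {
    kv <- list()
    while (!is.na(peek()) && peek() != "]") {
      key <- advance()
      val <- peek()
      if (identical(val, "[")) {
        advance()
        sub <- parse_block()
        if (!identical(peek(), "]")) cg_stop("cg_format_error", "unterminated GML block")
        advance()
        kv[[length(kv) + 1]] <- list(key = key, value = sub, block = TRUE)
      } else {
        advance()
        v <- if (startsWith(val, '"')) gsub('^"|"$', "", val) else as.numeric(val)
        kv[[length(kv) + 1]] <- list(key = key, value = v, block = FALSE)
      }
    }
    kv
  }
  if (!identical(advance(), "graph") || !identical(advance(), "[")) {
    cg_stop("cg_format_error", "not a GML graph file: %s", path)
  }
  top <- parse_block()
  keys <- vapply(top, `[[`, character(1), "key")
  getv <- function(kv, key) {
    hit <- which(vapply(kv, `[[`, character(1), "key") == key)
    if (length(hit) == 0) NULL else kv[[hit[1]]]$value
  }
  class_label <- getv(top, "classLabel")
  if (is.null(class_label)) {
    cg_stop("cg_format_error", "GML file lacks classLabel: %s", path)
  }
  prov <- list(kind = getv(top, "provenance") %||% "original")
  if (!is.null(getv(top, "seed"))) prov$seed <- as.integer(getv(top, "seed"))
  if (!is.null(getv(top, "threshold"))) prov$u <- getv(top, "threshold")
  node_blocks <- top[keys == "node"]
  edge_blocks <- top[keys == "edge"]
  if (length(node_blocks) == 0) {
    cg_stop("cg_format_error", "GML file has no nodes: %s", path)
  }
  nodes <- do.call(rbind, lapply(node_blocks, function(b) {
    kv <- b$value
    vals <- vapply(gml_key_map, function(k) {
      v <- getv(kv, k)
      if (is.null(v)) cg_stop("cg_format_error", "node lacks attribute %s", k)
      v
    }, numeric(1))
    id <- getv(kv, "id")
    if (is.null(id)) cg_stop("cg_format_error", "node lacks id")
    c(node_id = id, stats::setNames(vals, names(gml_key_map)))
  }))
  nodes <- as.data.frame(nodes)
  id_index <- stats::setNames(seq_len(nrow(nodes)), nodes$node_id)
  edges <- if (length(edge_blocks) > 0) {
    do.call(rbind, lapply(edge_blocks, function(b) {
      kv <- b$value
      s <- getv(kv, "source"); t <- getv(kv, "target"); w <- getv(kv, "weight")
      if (is.null(w)) cg_stop("cg_format_error", "edge lacks weight attribute")
      ii <- id_index[[as.character(s)]]
      jj <- id_index[[as.character(t)]]
      data.frame(i = min(ii, jj), j = max(ii, jj), weight = w)
    }))
  } else {
    data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  }
  lesion_graph(nodes, edges, class_label, prov)
}
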