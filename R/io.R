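# Writing analysis products: CSV tables (0-based (y, x) pixel coordinates,
# physical units in microns/nm), GraphML, TIFF overlays and the run
# configuration as JSON.

zero_base <- function(df, cols = intersect(c("y", "x", "centroid_y",
                                             "centroid_x"), names(df))) {
  for (cl in cols) df[[cl]] <- df[[cl]] - 1
  df
}

#' Write analysis results to a directory
#'
#' Writes per-edge, per-node, per-cisterna and per-polygon CSV tables with
#' stable column names, the network graph as GraphML, label/overlay images
#' as 16-bit TIFF, and the run configuration as JSON. Output is
#' deterministic for identical inputs.
#'
#' @param graph An `er_graph` (may be empty).
#' @param cisternae An `er_cisternae` or `NULL`.
#' @param polygons An `er_polygons` or `NULL`.
#' @param flow_summaries Data frame of per-element flow summaries or `NULL`.
#' @param persistency_nodes Data frame from [persistent_nodes] or `NULL`.
#' @param config An `er_config` (or list) echoed to `config.json`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(graph, cisternae = NULL, polygons = NULL,
                          flow_summaries = NULL, persistency_nodes = NULL,
                          config = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_results: cannot create output directory ", out_dir)
  }
  probe <- file.path(out_dir, ".write_test")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("write_results: output directory not writable: ", out_dir)
  unlink(probe)
  files <- character(0)
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    files <<- c(files, path)
  }
  nd <- graph$nodes
  if (!is.null(nd$branch_angles_deg))
    nd$branch_angles_deg <- vapply(nd$branch_angles_deg, paste,
                                   character(1), collapse = ";")
  wcsv(zero_base(nd), "nodes.csv")
  wcsv(graph$edges, "edges.csv")
  wcsv(zero_base(if (!is.null(cisternae)) cisternae$table
                 else cisterna_table_schema()), "cisternae.csv")
  poly_schema <- cisterna_table_schema()[, c("id", "area_um2", "centroid_y",
                                             "centroid_x", "perimeter_um",
                                             "major_um", "minor_um", "solidity",
                                             "elongation", "circularity",
                                             "roughness")]
  wcsv(zero_base(if (!is.null(polygons)) polygons$table else poly_schema),
       "polygons.csv")
  if (!is.null(flow_summaries)) wcsv(flow_summaries, "flow_summary.csv")
  if (!is.null(persistency_nodes))
    wcsv(zero_base(persistency_nodes), "persistent_nodes.csv")
  gml <- file.path(out_dir, "graph.graphml")
  igraph::write_graph(as_igraph(graph), gml, format = "graphml")
  files <- c(files, gml)
  if (!is.null(cisternae)) {
    tf <- file.path(out_dir, "cisterna_labels.tif")
    tiff::writeTIFF(cisternae$labels / max(max(cisternae$labels), 1), tf,
                    bits.per.sample = 16L)
    files <- c(files, tf)
  }
  if (!is.null(config)) {
    cf <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, cf)
  }
  invisible(files)
}

#' Read a GraphML file back as an igraph object
#'
#' @param path GraphML file written by [write_results].
#' @return An igraph object.
#' @export
read_graphml <- function(path) igraph::read_graph(path, format = "graphml")
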