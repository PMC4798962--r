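# File formats: masks (TIFF/PNG), cell tables and records (CSV), graphs
# (JSON, versioned schema), flow solutions (CSV), scenes (directory),
# analysis configuration (YAML/JSON) and the statistics report (JSON).

GRAPH_SCHEMA <- "vesselpol-graph-1"

#' Read a binary lumen mask
#'
#' Reads a TIFF or PNG image and binarizes it (nonzero = foreground), with
#' a warning if the image holds more than two distinct values.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @param pixel_size um per pixel to attach to the mask.
#' @return Integer 0/1 matrix of class `vessel_mask`.
#' @export
read_mask <- function(path, pixel_size = 1) {
  stop_if_not(file.exists(path), "mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported mask format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- unique(as.vector(img))
  if (length(vals) > 2)
    warning(sprintf("mask has %d distinct values; binarizing nonzero -> 1",
                    length(vals)))
  m <- matrix(as.integer(img > 0), nrow(img), ncol(img))
  structure(m, pixel_size = pixel_size, class = c("vessel_mask", "matrix"))
}

#' Write a binary mask as 8-bit single-channel TIFF
#'
#' @param mask Binary matrix (nonzero = foreground).
#' @param path Output path (.tif/.tiff).
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(ifelse(mask > 0, 1, 0), nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' Read a cell table (nucleus/Golgi centroids)
#'
#' @param path CSV with columns `nucleus_x_um`, `nucleus_y_um`,
#'   `golgi_x_um`, `golgi_y_um` (optional `bed` and others preserved).
#' @param strict If TRUE (default), malformed rows raise an error listing
#'   row numbers; if FALSE they are kept for downstream reporting.
#' @return Data frame.
#' @export
read_cells <- function(path, strict = TRUE) {
  stop_if_not(file.exists(path), "cell table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("nucleus_x_um", "nucleus_y_um", "golgi_x_um", "golgi_y_um")
  missing_cols <- setdiff(req, names(df))
  stop_if_not(length(missing_cols) == 0,
              "cell table lacks columns: ", paste(missing_cols, collapse = ", "))
  for (cl in req) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  bad <- which(!apply(is.finite(as.matrix(df[, req])), 1, all))
  if (length(bad) && strict)
    stop("malformed cell rows (non-numeric or missing): rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Write polarity records to CSV
#'
#' @param records A `polarity_records` data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Write a vessel graph to JSON
#'
#' Versioned schema: nodes (id, x_um, y_um), edges (id, node_a, node_b,
#' polyline, radii_um, bed), plus domain and roots. Full numeric precision.
#'
#' @param g A `vessel_graph`.
#' @param path Output .json path.
#' @return The path, invisibly.
#' @export
write_graph <- function(g, path) {
  obj <- list(
    schema = GRAPH_SCHEMA,
    domain_um = g$domain,
    roots = g$roots,
    nodes = data.frame(id = g$nodes$id, x_um = g$nodes$x, y_um = g$nodes$y),
    edges = lapply(g$edges, function(e) list(
      id = e$id, node_a = e$node_a, node_b = e$node_b,
      polyline = unname(e$polyline), radii_um = e$radii, bed = e$bed)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a vessel graph from JSON
#'
#' @param path JSON file written by [write_graph()].
#' @return A `vessel_graph`.
#' @export
read_graph <- function(path) {
  stop_if_not(file.exists(path), "graph file not found: ", path)
  obj <- jsonlite::read_json(path)     # explicit parsing, no simplification
  stop_if_not(identical(obj$schema, GRAPH_SCHEMA),
              "unknown graph schema version: ",
              as.character(obj$schema %||% "<missing>"))
  nodes <- data.frame(
    id = vapply(obj$nodes, function(n) as.integer(n$id), integer(1)),
    x = vapply(obj$nodes, function(n) as.numeric(n$x_um), numeric(1)),
    y = vapply(obj$nodes, function(n) as.numeric(n$y_um), numeric(1)))
  edges <- lapply(obj$edges, function(e) list(
    id = as.integer(e$id), node_a = as.integer(e$node_a),
    node_b = as.integer(e$node_b),
    polyline = matrix(unlist(e$polyline), ncol = 2, byrow = TRUE),
    radii = as.numeric(unlist(e$radii_um)), bed = e$bed))
  roots <- if (!is.null(obj$roots)) lapply(obj$roots, as.integer) else NULL
  vessel_graph(nodes, edges, domain = as.numeric(unlist(obj$domain_um)),
               roots = roots)
}

#' Write a flow solution to CSV
#'
#' Writes `<prefix>_edges.csv` (edge_id, flow_um3_s, wss_pa,
#' direction_reversed) and `<prefix>_nodes.csv` (node_id, pressure_pa).
#'
#' @param flow A `flow_solution`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_flow <- function(flow, prefix) {
  pe <- paste0(prefix, "_edges.csv")
  pn <- paste0(prefix, "_nodes.csv")
  utils::write.csv(data.frame(edge_id = flow$edges$id,
                              flow_um3_s = flow$edges$flow_um3_s,
                              wss_pa = flow$edges$wss_pa,
                              direction_reversed = flow$edges$reversed),
                   pe, row.names = FALSE)
  utils::write.csv(data.frame(node_id = as.integer(names(flow$node_pressure)),
                              pressure_pa = unname(flow$node_pressure)),
                   pn, row.names = FALSE)
  invisible(c(pe, pn))
}

#' Read a flow solution written by [write_flow()]
#'
#' Rebuilding a full `flow_solution` additionally needs the graph (for
#' conductances and rheology the CSVs do not carry); viscosity defaults to
#' the package default unless given.
#'
#' @param prefix Path prefix used in [write_flow()].
#' @param viscosity_pa_s Viscosity to attach.
#' @param model Rheology model to attach.
#' @return A `flow_solution` (without `boundary`).
#' @export
read_flow <- function(prefix, viscosity_pa_s = 3.5e-3, model = "constant") {
  ed <- utils::read.csv(paste0(prefix, "_edges.csv"))
  nd <- utils::read.csv(paste0(prefix, "_nodes.csv"))
  structure(list(
    node_pressure = stats::setNames(nd$pressure_pa, as.character(nd$node_id)),
    edges = data.frame(id = ed$edge_id, conductance = NA_real_,
                       flow_um3_s = ed$flow_um3_s, wss_pa = ed$wss_pa,
                       reversed = as.logical(ed$direction_reversed)),
    viscosity_pa_s = viscosity_pa_s, model = model),
    class = "flow_solution")
}

#' Serialize a synthetic scene to a directory
#'
#' Writes `mask.tif`, `cells.csv`, `graph.json`, `flow_edges.csv`,
#' `flow_nodes.csv` and `params.json` (parameter echo). Output is
#' byte-stable for a fixed scene.
#'
#' @param scene A `scene` from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mask(scene$mask, file.path(dir, "mask.tif"))
  utils::write.csv(scene$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write_graph(scene$graph, file.path(dir, "graph.json"))
  write_flow(scene$flow, file.path(dir, "flow"))
  pars <- scene$params
  pars$plexus <- unclass(pars$plexus)
  pars$response <- unclass(pars$response)
  jsonlite::write_json(pars, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scene directory back
#'
#' @param dir Directory written by [write_scene()].
#' @return List with `graph`, `mask`, `flow`, `cells`, `params` (flow lacks
#'   conductances; regenerate with [generate_scene()] for exact state).
#' @export
read_scene <- function(dir) {
  pars <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  list(graph = read_graph(file.path(dir, "graph.json")),
       mask = read_mask(file.path(dir, "mask.tif"),
                        pixel_size = pars$plexus$pixel_size %||% 1),
       flow = read_flow(file.path(dir, "flow"),
                        viscosity_pa_s = pars$hemo$viscosity_pa_s %||% 3.5e-3,
                        model = pars$hemo$model %||% "constant"),
       cells = utils::read.csv(file.path(dir, "cells.csv")),
       params = pars)
}

#' Analysis configuration
#'
#' Central configuration for the pipeline; CLI flags override these keys.
#'
#' @param pixel_size_um um per pixel of input masks.
#' @param viscosity_pa_s Blood viscosity, Pa s.
#' @param viscosity_model `"constant"` or `"pries"`.
#' @param inlet_pressure_pa Arterial inlet pressure above venous 0, Pa.
#' @param max_sampling_dist_um Nucleus-to-centreline sampling distance.
#' @param window_deg Anti-alignment half-window, degrees.
#' @param n_bins WSS quantile bins.
#' @param wss_breaks Optional fixed WSS bin edges (overrides `n_bins`).
#' @param n_perm Kuiper permutation count.
#' @param target_fraction Threshold-shear target anti-aligned fraction.
#' @param seed Integer seed for every stochastic stage.
#' @return Object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(pixel_size_um = 1, viscosity_pa_s = 3.5e-3,
                            viscosity_model = "constant",
                            inlet_pressure_pa = 2500,
                            max_sampling_dist_um = 20, window_deg = 45,
                            n_bins = 10, wss_breaks = NULL, n_perm = 9999,
                            target_fraction = 0.6, seed = 1) {
  cfg <- list(pixel_size_um = pixel_size_um, viscosity_pa_s = viscosity_pa_s,
              viscosity_model = viscosity_model,
              inlet_pressure_pa = inlet_pressure_pa,
              max_sampling_dist_um = max_sampling_dist_um,
              window_deg = window_deg, n_bins = n_bins,
              wss_breaks = wss_breaks, n_perm = as.integer(n_perm),
              target_fraction = target_fraction, seed = as.integer(seed))
  stop_if_not(cfg$pixel_size_um > 0 && cfg$viscosity_pa_s > 0 &&
                cfg$inlet_pressure_pa > 0 && cfg$max_sampling_dist_um > 0,
              "physical config quantities must be positive")
  stop_if_not(cfg$viscosity_model %in% c("constant", "pries"),
              "viscosity_model must be 'constant' or 'pries'")
  stop_if_not(cfg$window_deg > 0 && cfg$window_deg < 180,
              "window_deg must lie in (0, 180)")
  stop_if_not(cfg$target_fraction > 0 && cfg$target_fraction < 1,
              "target_fraction must lie in (0, 1)")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path .yaml/.yml or .json file of config keys.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  stop_if_not(file.exists(path), "config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  keys <- switch(ext,
                 yaml = , yml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 stop("unsupported config format: .", ext, call. = FALSE))
  do.call(analysis_config, keys[names(keys) %in% names(formals(analysis_config))])
}

#' Write an analysis configuration
#'
#' @param cfg An `analysis_config`.
#' @param path Output .yaml or .json path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  obj <- unclass(cfg)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  switch(ext,
         yaml = , yml = yaml::write_yaml(obj, path),
         json = jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stop("unsupported config format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write the statistics report to JSON
#'
#' @param report Report list from [polarity_statistics()] /
#'   [run_pipeline()].
#' @param path Output .json path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
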