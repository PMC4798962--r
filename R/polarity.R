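# Per-cell polarity records: nucleus-to-Golgi axial polarity joined to the
# local flow field (WSS magnitude and direction), the angle between polarity
# and flow, the scalar product, and a vascular-bed assignment.

#' Axial polarity vector of a cell
#'
#' The nucleus-to-Golgi vector, the standard proxy for an endothelial
#' cell's migration orientation.
#'
#' @param nucleus,golgi c(x, y) positions in um.
#' @return List with `vec` (2-vector, um) and `magnitude` (um).
#' @export
axial_polarity_vector <- function(nucleus, golgi) {
  v <- c(golgi[1] - nucleus[1], golgi[2] - nucleus[2])
  m <- vec_norm(v)
  if (m == 0)
    stop("nucleus and Golgi coincide: degenerate cell", call. = FALSE)
  list(vec = v, magnitude = m)
}

#' Angle between polarity and flow
#'
#' Counter-clockwise signed angle from the flow direction to the polarity
#' vector, folded to \[0, 360): 0 = polarized with flow, 180 = against flow.
#'
#' @param polarity_vec 2-vector (um).
#' @param flow_dir 2-vector (any nonzero length).
#' @return Angle in degrees on \[0, 360).
#' @export
angle_to_flow <- function(polarity_vec, flow_dir) {
  stop_if_not(vec_norm(polarity_vec) > 0 && vec_norm(flow_dir) > 0,
              "zero vector has no direction")
  fold_angle(rad2deg(atan2(polarity_vec[2], polarity_vec[1]) -
                       atan2(flow_dir[2], flow_dir[1])))
}

#' Scalar product of polarity and WSS
#'
#' s = |polarity| * tau * cos(angle); negative values mean the cell is
#' polarized against the flow.
#'
#' @param polarity_len_um Polarity magnitude, um.
#' @param wss_pa WSS magnitude, Pa.
#' @param angle_deg Angle to flow, degrees.
#' @return Scalar product in um Pa.
#' @export
cell_scalar_product <- function(polarity_len_um, wss_pa, angle_deg) {
  polarity_len_um * wss_pa * cospi(angle_deg / 180)
}

#' Assign a cell to a vascular bed
#'
#' Bed label of the nearest vessel edge within the sampling distance;
#' `unassigned` if no vessel is near enough.
#'
#' @param nucleus c(x, y) in um.
#' @param g A `vessel_graph` whose edges carry bed labels.
#' @param max_dist Maximum distance to a centreline, um.
#' @param index Optional prebuilt [polyline_index()].
#' @return Bed label string.
#' @export
assign_vascular_bed <- function(nucleus, g, max_dist = 20, index = NULL) {
  if (is.null(index)) index <- polyline_index(g)
  hit <- nearest_polyline_point(g, nucleus, max_dist, index)
  if (is.null(hit)) "unassigned" else hit$edge$bed
}

#' Build the per-cell polarity dataset
#'
#' Joins a cell table (nucleus and Golgi centroids) to a vessel graph and
#' its flow solution: computes each cell's polarity vector, samples the WSS
#' vector at the nucleus, derives the angle to flow and the scalar product,
#' and assigns a vascular bed from the matched edge. Cells with no vessel
#' within `max_dist` keep their polarity fields but have missing flow
#' fields; degenerate rows (coincident nucleus/Golgi or non-finite
#' coordinates) are dropped and reported via attributes.
#'
#' @param cells Data frame with columns `nucleus_x_um`, `nucleus_y_um`,
#'   `golgi_x_um`, `golgi_y_um` (extra columns are preserved).
#' @param g A `vessel_graph`.
#' @param flow A `flow_solution` solved on `g`.
#' @param max_dist Maximum nucleus-to-centreline sampling distance, um.
#' @return Data frame of class `polarity_records`, one row per valid input
#'   row: positions, `polarity_x_um`, `polarity_y_um`, `polarity_len_um`,
#'   `wss_pa`, `flow_dir_x`, `flow_dir_y`, `angle_deg`, `scalar_product`,
#'   `bed`, `flow_found`. Attributes `n_dropped` and `dropped_rows` report
#'   excluded input rows.
#' @export
build_polarity_dataset <- function(cells, g, flow, max_dist = 20) {
  req <- c("nucleus_x_um", "nucleus_y_um", "golgi_x_um", "golgi_y_um")
  missing_cols <- setdiff(req, names(cells))
  stop_if_not(length(missing_cols) == 0,
              "cell table lacks columns: ", paste(missing_cols, collapse = ", "))
  stop_if_not(nrow(cells) > 0, "cell table is empty")
  xy <- as.matrix(cells[, req])
  storage.mode(xy) <- "double"
  finite <- apply(is.finite(xy), 1, all)
  degen <- finite & (xy[, 1] == xy[, 3]) & (xy[, 2] == xy[, 4])
  valid <- finite & !degen
  if (!any(valid))
    stop("no valid cell rows (all degenerate or malformed)", call. = FALSE)
  dropped <- which(!valid)
  if (length(dropped))
    warning(sprintf("dropped %d cell row(s): %s", length(dropped),
                    paste(utils::head(dropped, 20), collapse = ", ")))
  xy <- xy[valid, , drop = FALSE]
  n <- nrow(xy)
  px <- xy[, 3] - xy[, 1]
  py <- xy[, 4] - xy[, 2]
  plen <- sqrt(px^2 + py^2)
  idx <- polyline_index(g)
  wss <- rep(NA_real_, n)
  fdx <- rep(NA_real_, n); fdy <- rep(NA_real_, n)
  bed <- rep("unassigned", n)
  found <- logical(n)
  for (i in seq_len(n)) {
    hit <- wss_vector_at_point(flow, g, xy[i, 1:2], max_dist, index = idx)
    if (is.null(hit)) next
    wss[i] <- hit$wss_pa
    fdx[i] <- hit$flow_dir[1]; fdy[i] <- hit$flow_dir[2]
    bed[i] <- hit$bed
    found[i] <- TRUE
  }
  ang <- ifelse(found,
                fold_angle(rad2deg(atan2(py, px) - atan2(fdy, fdx))),
                NA_real_)
  out <- data.frame(nucleus_x_um = xy[, 1], nucleus_y_um = xy[, 2],
                    golgi_x_um = xy[, 3], golgi_y_um = xy[, 4],
                    polarity_x_um = px, polarity_y_um = py,
                    polarity_len_um = plen,
                    wss_pa = wss, flow_dir_x = fdx, flow_dir_y = fdy,
                    angle_deg = ang,
                    scalar_product = plen * wss * cospi(ang / 180),
                    bed = bed, flow_found = found)
  extra <- setdiff(names(cells), names(out))
  for (cl in extra) out[[cl]] <- cells[[cl]][valid]
  structure(out, n_dropped = length(dropped), dropped_rows = dropped,
            class = c("polarity_records", "data.frame"))
}

#' @export
print.polarity_records <- function(x, ...) {
  cat(sprintf("polarity_records: %d cells (%d with flow, %d dropped rows)\n",
              nrow(x), sum(x$flow_found), attr(x, "n_dropped") %||% 0))
  beds <- table(x$bed)
  cat("  beds:", paste(sprintf("%s=%d", names(beds), beds), collapse = ", "),
      "\n")
  if (any(x$flow_found))
    cat(sprintf("  anti-aligned (180 +/- 45 deg): %.1f%%\n",
                100 * antialigned_fraction(x$angle_deg[x$flow_found])))
  invisible(x)
}
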