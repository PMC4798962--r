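# Pipeline composition and the command-line interface.

#' Circular-statistics report for a polarity dataset
#'
#' Per-bed angular summaries, Kuiper comparisons of every bed against a
#' uniform reference (and between beds when requested), the WSS-binned
#' anti-alignment table with threshold-crossing shear, and the
#' scalar-product regressions.
#'
#' @param records A `polarity_records` data frame.
#' @param cfg An `analysis_config`.
#' @param bed_pairs Optional list of 2-vectors of bed names to compare.
#' @return List of class `polarity_report`.
#' @export
polarity_statistics <- function(records, cfg = analysis_config(),
                                bed_pairs = NULL) {
  fl <- records[records$flow_found & is.finite(records$angle_deg), ]
  if (nrow(fl) == 0)
    stop(sprintf(
      "no cells matched to flow within max_sampling_dist_um = %g um",
      cfg$max_sampling_dist_um), call. = FALSE)
  beds <- intersect(VESSEL_BEDS, unique(fl$bed))
  summaries <- list()
  kuiper_uniform <- list()
  for (b in beds) {
    a <- fl$angle_deg[fl$bed == b]
    if (length(a) >= 2)
      summaries[[b]] <- unclass(circular_mean_ci(a))
    if (length(a) >= 5) {
      # deterministic uniform reference grid of matched size
      ref <- (seq_along(a) - 0.5) / length(a) * 360
      kt <- kuiper_two_sample(a, ref, n_perm = cfg$n_perm, seed = cfg$seed)
      kuiper_uniform[[b]] <- kt[c("statistic", "p_value", "n_a", "n_b")]
    }
  }
  kuiper_pairs <- list()
  for (pr in bed_pairs %||% list()) {
    a <- fl$angle_deg[fl$bed == pr[1]]
    b <- fl$angle_deg[fl$bed == pr[2]]
    if (length(a) >= 5 && length(b) >= 5) {
      kt <- kuiper_two_sample(a, b, n_perm = cfg$n_perm, seed = cfg$seed)
      kuiper_pairs[[paste(pr, collapse = "_vs_")]] <-
        kt[c("statistic", "p_value", "n_a", "n_b")]
    }
  }
  binned <- bin_by_wss(fl, breaks = cfg$wss_breaks, n_bins = cfg$n_bins,
                       window_deg = cfg$window_deg)
  thr <- suppressWarnings(
    polarization_threshold_shear(binned, cfg$target_fraction))
  reg <- scalar_product_regression(fl)
  rose <- lapply(stats::setNames(beds, beds), function(b)
    angle_histogram(fl$angle_deg[fl$bed == b]))
  structure(list(
    n_cells = nrow(records), n_with_flow = nrow(fl),
    n_excluded_no_flow = nrow(records) - nrow(fl),
    overall = unclass(circular_mean_ci(fl$angle_deg)),
    antialigned_fraction = antialigned_fraction(fl$angle_deg, cfg$window_deg),
    by_bed = summaries,
    kuiper_vs_uniform = kuiper_uniform,
    kuiper_between_beds = kuiper_pairs,
    binned = as.data.frame(binned),
    threshold_shear_pa = thr,
    target_fraction = cfg$target_fraction,
    scalar_regression = as.data.frame(reg),
    rose_histograms = rose),
    class = "polarity_report")
}

#' @export
print.polarity_report <- function(x, ...) {
  cat(sprintf("polarity_report: %d cells (%d with flow)\n",
              x$n_cells, x$n_with_flow))
  cat(sprintf("  anti-aligned fraction: %.3f\n", x$antialigned_fraction))
  cat(sprintf("  threshold shear (target %.0f%%): %s\n",
              100 * x$target_fraction,
              if (is.na(x$threshold_shear_pa)) "not reached"
              else sprintf("%.2f Pa", x$threshold_shear_pa)))
  neg <- x$scalar_regression[x$scalar_regression$subset == "negative", ]
  if (isTRUE(neg$available))
    cat(sprintf("  negative-subset gradient: %.3f um (r = %.3f, n = %d)\n",
                neg$gradient, neg$r_value, neg$n))
  invisible(x)
}

provenance_block <- function(cfg) {
  list(package = "vesselpol",
       version = as.character(utils::packageVersion("vesselpol")),
       solver = paste("1D Poiseuille/Kirchhoff network solver",
                      "(replaces 3D lattice-Boltzmann CFD; per-segment mean",
                      "WSS and flow direction only)"),
       skeletonization = "Guo-Hall topological thinning",
       config = {
         obj <- unclass(cfg); obj[!vapply(obj, is.null, logical(1))]
       })
}

#' Run the full analysis pipeline
#'
#' Either simulates a synthetic scene (when `scene` parameters are given)
#' or reads a mask + cell table, then extracts the network, solves flow,
#' builds polarity records and computes the statistics report, writing all
#' outputs (records CSV, graph JSON, morphometrics and report JSON with a
#' provenance block) into `out_dir`.
#'
#' @param cfg An `analysis_config`.
#' @param out_dir Output directory.
#' @param mask_path,cells_path Input mask image and cell CSV (measured mode).
#' @param scene A `scene` (synthetic mode; bypasses extraction inputs).
#' @param use_true_graph In synthetic mode, analyse on the ground-truth
#'   graph (TRUE) or re-extract from the rasterized mask (FALSE).
#' @return The `polarity_report`, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, mask_path = NULL, cells_path = NULL,
                         scene = NULL, use_true_graph = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(scene)) {
    cells <- scene$cells
    if (use_true_graph) {
      g <- scene$graph; flow <- scene$flow
      mask <- scene$mask
    } else {
      mask <- scene$mask
      g <- extract_network(mask, attr(mask, "pixel_size"))
      g <- transfer_bed_labels(g, scene$graph)
      g$roots <- list(
        artery = nearest_node(g, unlist(
          scene$graph$nodes[scene$graph$nodes$id == scene$graph$roots$artery,
                            c("x", "y")])),
        vein = nearest_node(g, unlist(
          scene$graph$nodes[scene$graph$nodes$id == scene$graph$roots$vein,
                            c("x", "y")])))
      flow <- solve_flow(g, viscosity_pa_s = cfg$viscosity_pa_s,
                         inlet_pressure_pa = cfg$inlet_pressure_pa,
                         model = cfg$viscosity_model)
    }
  } else {
    stop_if_not(!is.null(mask_path) && !is.null(cells_path),
                "need mask_path and cells_path (or a scene)")
    mask <- read_mask(mask_path, cfg$pixel_size_um)
    cells <- read_cells(cells_path, strict = FALSE)
    g <- extract_network(mask, cfg$pixel_size_um)
    flow <- solve_flow(g, viscosity_pa_s = cfg$viscosity_pa_s,
                       inlet_pressure_pa = cfg$inlet_pressure_pa,
                       model = cfg$viscosity_model)
  }
  records <- build_polarity_dataset(cells, g, flow,
                                    max_dist = cfg$max_sampling_dist_um)
  report <- polarity_statistics(records, cfg)
  write_records(records, file.path(out_dir, "records.csv"))
  write_graph(g, file.path(out_dir, "graph.json"))
  write_flow(flow, file.path(out_dir, "flow"))
  area_mm2 <- prod(dim(mask)) * (attr(mask, "pixel_size") %||%
                                   cfg$pixel_size_um)^2 / 1e6
  morpho <- data.frame(vessel_area_fraction = vessel_area_fraction(mask),
                       branchpoint_density_mm2 = branchpoint_density(g, area_mm2))
  utils::write.csv(morpho, file.path(out_dir, "morphometrics.csv"),
                   row.names = FALSE)
  full <- c(report, list(morphometrics = morpho,
                         provenance = provenance_block(cfg)))
  write_report(full, file.path(out_dir, "report.json"))
  invisible(report)
}

#' Transfer bed labels from a reference graph
#'
#' Labels each edge of an extracted graph with the bed of the nearest
#' reference-graph edge, by majority vote over its polyline points.
#'
#' @param g Graph to label (beds overwritten).
#' @param reference Graph carrying trusted bed labels.
#' @param max_dist Matching distance, um.
#' @return `g` with beds filled in.
#' @export
transfer_bed_labels <- function(g, reference, max_dist = 30) {
  idx <- polyline_index(reference)
  g$edges <- lapply(g$edges, function(e) {
    n <- nrow(e$polyline)
    take <- unique(round(seq(1, n, length.out = min(n, 7))))
    votes <- vapply(take, function(i) {
      hit <- nearest_polyline_point(reference, e$polyline[i, ], max_dist, idx)
      if (is.null(hit)) "unassigned" else hit$edge$bed
    }, "")
    tab <- table(votes)
    e$bed <- names(tab)[which.max(tab)]
    e
  })
  g
}

# --- command-line interface --------------------------------------------------

cli_usage <- function() {
  cat("usage: vesselpol <subcommand> [options]\n",
      "subcommands:\n",
      "  simulate --out DIR [--config FILE] [--seed N] [--tau0 PA]\n",
      "  extract  --mask FILE --out GRAPH.json [--pixel-size UM]\n",
      "           [--morphometrics FILE.csv]\n",
      "  flow     --graph FILE --out PREFIX [--viscosity PA_S]\n",
      "           [--inlet-pressure PA]\n",
      "  polarity --graph FILE --flow PREFIX --cells FILE --out FILE.csv\n",
      "           [--max-dist UM]\n",
      "  stats    --records FILE --out REPORT.json [--config FILE]\n",
      "  run-all  --out DIR [--config FILE] [--mask FILE --cells FILE]\n",
      sep = "")
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    stop_if_not(i < length(args), "missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_config(opts$config)
  else analysis_config()
  num_keys <- c(pixel_size = "pixel_size_um", viscosity = "viscosity_pa_s",
                inlet_pressure = "inlet_pressure_pa",
                max_dist = "max_sampling_dist_um", window = "window_deg",
                n_perm = "n_perm", seed = "seed")
  for (k in names(num_keys))
    if (!is.null(opts[[k]])) cfg[[num_keys[[k]]]] <- as.numeric(opts[[k]])
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/vesselpol` script. Subcommands:
#' `simulate`, `extract`, `flow`, `polarity`, `stats`, `run-all`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    stop_if_not(length(args) >= 1, "no subcommand given")
    sub <- args[1]
    opts <- parse_cli_args(args[-1])
    cfg <- cli_config(opts)
    switch(sub,
      simulate = {
        stop_if_not(!is.null(opts$out), "simulate needs --out DIR")
        resp <- polarity_response_params(
          tau0 = as.numeric(opts$tau0 %||% 4), seed = cfg$seed)
        scene <- generate_scene(
          plexus = plexus_params(pixel_size = cfg$pixel_size_um,
                                 seed = cfg$seed),
          response = resp, viscosity_pa_s = cfg$viscosity_pa_s,
          inlet_pressure_pa = cfg$inlet_pressure_pa,
          model = cfg$viscosity_model)
        write_scene(scene, opts$out)
      },
      extract = {
        stop_if_not(!is.null(opts$mask) && !is.null(opts$out),
                    "extract needs --mask and --out")
        mask <- read_mask(opts$mask, cfg$pixel_size_um)
        g <- extract_network(mask, cfg$pixel_size_um)
        write_graph(g, opts$out)
        if (!is.null(opts$morphometrics)) {
          area_mm2 <- prod(dim(mask)) * cfg$pixel_size_um^2 / 1e6
          utils::write.csv(
            data.frame(vessel_area_fraction = vessel_area_fraction(mask),
                       branchpoint_density_mm2 =
                         branchpoint_density(g, area_mm2)),
            opts$morphometrics, row.names = FALSE)
        }
      },
      flow = {
        stop_if_not(!is.null(opts$graph) && !is.null(opts$out),
                    "flow needs --graph and --out")
        g <- read_graph(opts$graph)
        if (!is.null(opts$artery_root))
          g$roots$artery <- as.integer(opts$artery_root)
        if (!is.null(opts$vein_root))
          g$roots$vein <- as.integer(opts$vein_root)
        fl <- solve_flow(g, viscosity_pa_s = cfg$viscosity_pa_s,
                         inlet_pressure_pa = cfg$inlet_pressure_pa,
                         model = cfg$viscosity_model)
        write_flow(fl, opts$out)
      },
      polarity = {
        stop_if_not(!is.null(opts$graph) && !is.null(opts$flow) &&
                      !is.null(opts$cells) && !is.null(opts$out),
                    "polarity needs --graph, --flow, --cells, --out")
        g <- read_graph(opts$graph)
        fl <- read_flow(opts$flow, viscosity_pa_s = cfg$viscosity_pa_s,
                        model = cfg$viscosity_model)
        cells <- read_cells(opts$cells, strict = FALSE)
        rec <- build_polarity_dataset(cells, g, fl,
                                      max_dist = cfg$max_sampling_dist_um)
        write_records(rec, opts$out)
      },
      stats = {
        stop_if_not(!is.null(opts$records) && !is.null(opts$out),
                    "stats needs --records and --out")
        rec <- utils::read.csv(opts$records)
        rec$flow_found <- as.logical(rec$flow_found)
        report <- polarity_statistics(rec, cfg)
        write_report(c(unclass(report),
                       list(provenance = provenance_block(cfg))), opts$out)
      },
      "run-all" = {
        stop_if_not(!is.null(opts$out), "run-all needs --out DIR")
        if (!is.null(opts$mask)) {
          run_pipeline(cfg, opts$out, mask_path = opts$mask,
                       cells_path = opts$cells)
        } else {
          scene <- generate_scene(
            plexus = plexus_params(pixel_size = cfg$pixel_size_um,
                                   seed = cfg$seed),
            response = polarity_response_params(seed = cfg$seed),
            viscosity_pa_s = cfg$viscosity_pa_s,
            inlet_pressure_pa = cfg$inlet_pressure_pa,
            model = cfg$viscosity_model)
          run_pipeline(cfg, opts$out, scene = scene)
        }
      },
      {
        cli_usage()
        stop("unknown subcommand: ", sub, call. = FALSE)
      })
    0L
  }, error = function(e) {
    message("vesselpol error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
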