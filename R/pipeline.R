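default_config <- function() {
  list(
    head = list(layer_radii = c(85, 88, 91, 92),
                layer_conductivities = c(0.2, 1.65, 0.01, 0.465),
                grid_spacing = 8),
    layout = list(n_rings = 2, n_per_ring = 8, reference_label = "E0",
                  electrode_radius = 6),
    protocol = list(frequencies = c(10, 12), phases = c(0, pi),
                    duration = 1, sample_rate = NULL),
    target = c(-16, 10, 2),
    off_target = c(40, -35, 2),
    direction = "radial_in",
    optimization = list(mode = "pairs", budget = 2, per_electrode_max = 1,
                        lambda = 1, seed = 1, n_starts = 8),
    animate = FALSE,
    fps = 25,
    output_dir = "tistim_run"
  )
}

# Required dotted fields; schema violations name the offending field.
validate_config <- function(config) {
  need <- c("head.layer_radii", "head.layer_conductivities",
            "head.grid_spacing", "layout.n_rings", "layout.n_per_ring",
            "layout.reference_label", "protocol.frequencies",
            "protocol.duration", "target", "off_target", "direction",
            "optimization.mode", "optimization.budget", "optimization.seed",
            "output_dir")
  for (field in need) {
    parts <- strsplit(field, ".", fixed = TRUE)[[1]]
    x <- config
    for (p in parts) {
      x <- x[[p]]
      if (is.null(x)) stop("config schema error: missing field '", field, "'")
    }
  }
  if (length(config$protocol$frequencies) != 2)
    stop("config schema error: 'protocol.frequencies' must have 2 entries")
  if (!config$optimization$mode %in% c("pairs", "arrays"))
    stop("config schema error: 'optimization.mode' must be pairs or arrays")
  invisible(config)
}

# Fill unset fields from the defaults, recursively.
merge_config <- function(config, defaults = default_config()) {
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      config[[nm]] <- merge_config(config[[nm]], defaults[[nm]])
    }
  }
  config
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; unset fields fall back to the package defaults
#'   (demo-scale phantom, 10/12 Hz, pair search).
#' @return validated config list.
#' @export
read_config <- function(path) {
  validate_config(merge_config(yaml::read_yaml(path)))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full modeling pipeline from one configuration
#'
#' Builds (or loads) the phantom lead field, optimizes a montage for the
#' target, simulates the two-frequency protocol, writes the report tables and
#' optionally the animation frames, and records a manifest with checksums of
#' every artifact. Deterministic given the configured seed.
#'
#' @param config a config list (see [read_config()] / the package defaults),
#'   or a path to a YAML file.
#' @param verbose print stage progress.
#' @return the manifest list, invisibly; also written as `manifest.json` in
#'   the output directory.
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  if (is.character(config)) config <- merge_config(yaml::read_yaml(config))
  config <- validate_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  log <- list()

  say("stage leadfield")
  lf <- run_stage("leadfield", {
    if (!is.null(config$leadfield_path)) {
      read_leadfield(config$leadfield_path)
    } else {
      head <- sphere_head_model(config$head$layer_radii,
                                config$head$layer_conductivities,
                                grid_spacing = config$head$grid_spacing)
      layout <- place_electrodes(head, config$layout$n_rings,
                                 config$layout$n_per_ring,
                                 reference_label = config$layout$reference_label,
                                 electrode_radius = config$layout$electrode_radius)
      build_leadfield(head, layout, verbose = verbose)
    }
  })
  run_stage("leadfield", write_leadfield(lf, file.path(out, "leadfield")))

  say("stage optimize")
  opt <- run_stage("optimize", {
    tgt <- target_spec(config$target, direction = config$direction)
    pairs_res <- search_pairs(lf, tgt,
                              total_current_mA = config$optimization$budget,
                              frequencies = config$protocol$frequencies,
                              phases = config$protocol$phases)
    if (config$optimization$mode == "arrays") {
      optimize_arrays(lf, tgt,
                      per_electrode_max_mA = config$optimization$per_electrode_max,
                      total_budget_mA = config$optimization$budget,
                      init = pairs_res,
                      seed = config$optimization$seed,
                      lambda = config$optimization$lambda,
                      n_starts = config$optimization$n_starts,
                      frequencies = config$protocol$frequencies,
                      phases = config$protocol$phases)
    } else pairs_res
  })
  write_montages(list(opt$montage_a, opt$montage_b),
                 file.path(out, "montage.csv"))
  log$optimizer <- opt$diagnostics
  log$md_target <- opt$md_target
  log$focality_cm <- opt$focality

  say("stage simulate")
  sim <- run_stage("simulate", {
    proto <- stim_protocol(opt$montage_a, opt$montage_b,
                           duration = config$protocol$duration,
                           sample_rate = config$protocol$sample_rate)
    off_node <- snap_target(lf, target_spec(config$off_target))$node
    report <- md_report(lf, proto, opt$target_node, off_node)
    utils::write.csv(report, file.path(out, "report.csv"), row.names = FALSE)
    md_r <- md_map(lf, opt$montage_a, opt$montage_b, "radial_in")
    hs <- hotspots(md_r)
    jsonlite::write_json(hs, file.path(out, "hotspots.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    field <- total_field(lf, proto, nodes = c(opt$target_node, off_node))
    sf <- project_field(field, direction_field(field$coords, config$direction))
    write_timeseries(sf, 1, file.path(out, "target_timeseries.csv"))
    write_timeseries(envelope(sf), 1, file.path(out, "target_envelope.csv"))
    list(proto = proto, off_node = off_node)
  })

  if (isTRUE(config$animate)) {
    say("stage animate")
    run_stage("animate",
              animate(lf, sim$proto, opt$target_node, sim$off_node,
                      out = file.path(out, "frames"), fps = config$fps,
                      direction = config$direction))
  }

  say("stage manifest")
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("tistim")),
    seed = config$optimization$seed,
    config = config,
    log = log,
    artifacts = lapply(files, function(f) list(
      path = f, md5 = unname(tools::md5sum(file.path(out, f))))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `tistim` script (`run`, `leadfield`,
#' `optimize`, `simulate`, `report`, `animate`); each is a thin wrapper over
#' the package functions, driven by `--config` and per-command flags.
#'
#' @param args character vector, as from `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
tistim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tistim <command> [--config cfg.yaml] [--out dir] [options]",
    "commands:",
    "  run        full pipeline (leadfield -> optimize -> simulate -> report)",
    "  leadfield  build and save the phantom lead field",
    "  optimize   montage optimization (--mode pairs|arrays, --target x,y,z)",
    "  simulate   simulate a montage CSV (--leadfield dir --montages m.csv)",
    "  report     target/off-target summary (--target x,y,z --off-target x,y,z)",
    "  animate    write animation frames",
    sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest)) {
    if (!startsWith(rest[1], "--")) stop("unexpected argument: ", rest[1])
    key <- sub("^--", "", rest[1])
    opts[[key]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  config <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
  if (!is.null(opts$out)) config$output_dir <- opts$out
  parse_xyz <- function(s) as.numeric(strsplit(s, ",")[[1]])
  if (!is.null(opts$target)) config$target <- parse_xyz(opts$target)
  if (!is.null(opts[["off-target"]]))
    config$off_target <- parse_xyz(opts[["off-target"]])
  if (!is.null(opts$mode)) config$optimization$mode <- opts$mode
  if (!is.null(opts$budget))
    config$optimization$budget <- as.numeric(opts$budget)
  if (!is.null(opts$seed)) config$optimization$seed <- as.integer(opts$seed)
  if (!is.null(opts$direction)) config$direction <- opts$direction
  if (!is.null(opts$leadfield)) config$leadfield_path <- opts$leadfield
  config <- merge_config(config)

  switch(cmd,
    run = run_pipeline(config, verbose = TRUE),
    leadfield = {
      config$optimization <- NULL
      head <- sphere_head_model(config$head$layer_radii,
                                config$head$layer_conductivities,
                                grid_spacing = config$head$grid_spacing)
      layout <- place_electrodes(head, config$layout$n_rings,
                                 config$layout$n_per_ring,
                                 reference_label = config$layout$reference_label)
      lf <- build_leadfield(head, layout, verbose = TRUE)
      write_leadfield(lf, config$output_dir)
      message("lead field written to ", config$output_dir)
    },
    optimize = {
      lf <- if (!is.null(config$leadfield_path))
        read_leadfield(config$leadfield_path) else
        stop("optimize needs --leadfield <container dir>")
      tgt <- target_spec(config$target, direction = config$direction)
      res <- if (config$optimization$mode == "arrays")
        optimize_arrays(lf, tgt,
                        per_electrode_max_mA = config$optimization$per_electrode_max,
                        total_budget_mA = config$optimization$budget,
                        seed = config$optimization$seed,
                        lambda = config$optimization$lambda)
      else search_pairs(lf, tgt, total_current_mA = config$optimization$budget,
                        frequencies = config$protocol$frequencies)
      print(res)
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      write_montages(list(res$montage_a, res$montage_b),
                     file.path(config$output_dir, "montage.csv"))
    },
    simulate = ,
    report = {
      lf <- if (!is.null(config$leadfield_path))
        read_leadfield(config$leadfield_path) else
        stop(cmd, " needs --leadfield <container dir>")
      ms <- if (!is.null(opts$montages)) read_montages(opts$montages) else
        stop(cmd, " needs --montages <csv>")
      proto <- stim_protocol(ms[[1]], ms[[2]],
                             duration = config$protocol$duration)
      tgt <- snap_target(lf, target_spec(config$target))$node
      off <- snap_target(lf, target_spec(config$off_target))$node
      rep <- md_report(lf, proto, tgt, off)
      print(rep)
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(rep, file.path(config$output_dir, "report.csv"),
                       row.names = FALSE)
    },
    animate = {
      lf <- if (!is.null(config$leadfield_path))
        read_leadfield(config$leadfield_path) else
        stop("animate needs --leadfield <container dir>")
      ms <- if (!is.null(opts$montages)) read_montages(opts$montages) else
        stop("animate needs --montages <csv>")
      proto <- stim_protocol(ms[[1]], ms[[2]],
                             duration = config$protocol$duration)
      tgt <- snap_target(lf, target_spec(config$target))$node
      off <- snap_target(lf, target_spec(config$off_target))$node
      animate(lf, proto, tgt, off, out = config$output_dir,
              fps = config$fps, direction = config$direction)
      message("frames written to ", config$output_dir)
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}
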