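## Readers/writers for the XYZ, CSV, TSV and YAML artifacts shared by the
## modules, plus the staged pipeline driver and its run manifest.
## All writes are atomic: write to a temporary file, then rename.

.atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("atomic write failed for ", path)
  invisible(path)
}

#' Write 2D configurations as extended XYZ snapshots
#'
#' One XYZ block per configuration: particle count, then a comment line
#' `box=Lx,Ly periodic=... eta=... sigma=... step=...`, then `P x y 0` rows
#' (z = 0 for the quasi-2D system).  The metadata line is sufficient for
#' bit-exact round-tripping.
#'
#' @param configs a [configuration2d()] or list of them.
#' @param path output file.
#' @param eta,sigma optional metadata recorded in the comment line.
#' @param steps optional per-snapshot sweep indices.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(configs, path, eta = NA, sigma = NA, steps = NULL) {
  if (inherits(configs, "configuration2d")) configs <- list(configs)
  .atomic_write(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (k in seq_along(configs)) {
      cfg <- configs[[k]]
      step <- if (is.null(steps)) k else steps[k]
      writeLines(as.character(nrow(cfg$positions)), con)
      writeLines(sprintf(
        "box=%.17g,%.17g periodic=%d eta=%g sigma=%g step=%d",
        cfg$box[1], cfg$box[2], as.integer(cfg$periodic), eta, sigma, step), con)
      writeLines(sprintf("P %.17g %.17g 0", cfg$positions[, 1],
                         cfg$positions[, 2]), con)
    }
  }, path)
}

#' Read configurations from an XYZ snapshot file or a coordinate CSV
#'
#' XYZ files must carry the `box=Lx,Ly` metadata on each comment line;
#' non-zero z coordinates are dropped with a warning (2D contract).  CSV
#' files need columns `x`, `y` (and optionally `frame` to split into several
#' configurations) plus box sides passed via `box`.
#'
#' @param path input file (`.xyz` or `.csv`, sniffed from content when the
#'   extension is ambiguous).
#' @param box side lengths, required for CSV input.
#' @param periodic periodicity flag for CSV input.
#' @return list of [configuration2d()].
#' @export
read_configuration <- function(path, box = NULL, periodic = TRUE) {
  if (!file.exists(path)) stop("read_configuration(): no such file: ", path)
  first <- readLines(path, n = 1)
  is_xyz <- grepl("^\\s*[0-9]+\\s*$", first)
  if (is_xyz) return(.read_xyz(path))
  .read_coord_csv(path, box = box, periodic = periodic)
}

.read_xyz <- function(path) {
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[i]))
      stop(sprintf("read_configuration(): malformed XYZ header at line %d", i))
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    m <- regmatches(comment, regexec("box=([-0-9.eE+]+),([-0-9.eE+]+)", comment))[[1]]
    if (length(m) != 3)
      stop(sprintf("read_configuration(): missing box metadata at line %d", i + 1))
    box <- as.numeric(m[2:3])
    per <- regmatches(comment, regexec("periodic=([01])", comment))[[1]]
    periodic <- if (length(per) == 2) per[2] == "1" else TRUE
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4)
    if (length(bad))
      stop(sprintf("read_configuration(): malformed atom line %d", i + 1 + bad[1]))
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(xyz)))
      stop(sprintf("read_configuration(): NaN/NA coordinate near line %d", i + 2))
    if (any(xyz[, 3] != 0))
      warning("read_configuration(): non-zero z coordinates dropped (2D data)")
    configs[[length(configs) + 1L]] <-
      configuration2d(xyz[, 1:2, drop = FALSE], box, periodic = periodic)
    i <- i + 2L + n
  }
  configs
}

.read_coord_csv <- function(path, box, periodic) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    stop("read_configuration(): CSV must have columns x and y")
  if (is.null(box))
    stop("read_configuration(): CSV input requires an explicit box")
  if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
    stop("read_configuration(): non-finite coordinates in CSV")
  if ("frame" %in% names(d)) {
    lapply(split(d, d$frame), function(s)
      configuration2d(cbind(s$x, s$y), box, periodic = periodic))
  } else {
    list(configuration2d(cbind(d$x, d$y), box, periodic = periodic))
  }
}

#' Read / write particle tracks as CSV
#'
#' Schema: `frame,id,x,y`, the native output of particle-tracking software.
#'
#' @param path CSV file.
#' @param frame_interval seconds per frame for the returned [track_set()].
#' @return [read_tracks_csv()]: a [track_set()].
#' @export
read_tracks_csv <- function(path, frame_interval = 1 / 15) {
  d <- utils::read.csv(path)
  need <- c("frame", "id", "x", "y")
  if (!all(need %in% names(d)))
    stop("read_tracks_csv(): CSV must have columns frame, id, x, y")
  track_set(d, frame_interval = frame_interval)
}

#' @rdname read_tracks_csv
#' @param ts a [track_set()].
#' @export
write_tracks_csv <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  .atomic_write(function(tmp)
    utils::write.csv(ts$tracks, tmp, row.names = FALSE), path)
}

#' Read a brush geometry from a YAML config
#'
#' Expected keys (units in comments of the template): `f`, `N`, `R_PS_nm`,
#' `b_nm`, and optionally `R_m_nm`, `d_nm`, `T_K`, `eps_r`.
#'
#' @param path YAML file.
#' @return a [brush_geometry()].
#' @export
read_geometry_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `N` as a boolean; map it back
  names(cfg)[names(cfg) %in% c("FALSE", "no")] <- "N"
  need <- c("f", "N", "R_PS_nm", "b_nm")
  if (!all(need %in% names(cfg)))
    stop("read_geometry_yaml(): missing keys: ",
         paste(setdiff(need, names(cfg)), collapse = ", "))
  brush_geometry(f = cfg$f, N = cfg$N, R_PS = cfg$R_PS_nm, b = cfg$b_nm,
                 R_m = cfg$R_m_nm %||% 1, d = cfg$d_nm %||% 0.7,
                 T = cfg$T_K %||% 298, eps_r = cfg$eps_r %||% 78.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tab-separated table atomically
#'
#' @param df data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  .atomic_write(function(tmp)
    utils::write.table(df, tmp, sep = "\t", row.names = FALSE,
                       quote = FALSE), path)
}

#' Run the staged analysis pipeline
#'
#' Executes, in order, the requested stages: `"cell"` (theory shrinking
#' curve), `"mc"` (Monte Carlo runs at each state point, wired to the theory
#' sigma(eta) curve), `"structure"` (order metrics per state point) and
#' `"dynamics"` (MSD of synthetic Brownian benchmark tracks).  Every run
#' directory receives a `manifest.json` recording the configuration, seeds
#' and outputs; rerunning with the same seed reproduces the outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param stages character subset of `c("cell", "mc", "structure",
#'   "dynamics")`.
#' @param eta_grid packing fractions for the cell/mc/structure stages.
#' @param seed base RNG seed; stage s at state point k uses `seed + k`.
#' @param n_steps MC sweeps per state point (`NULL` = per-eta defaults).
#' @param geom a [brush_geometry()].
#' @return invisible list with the per-stage results.
#' @export
pipeline_run <- function(out_dir, stages = c("cell", "mc", "structure"),
                         eta_grid = paper_state_points()$eta, seed = 1,
                         n_steps = NULL,
                         geom = experimental_brush_params()) {
  stages <- match.arg(stages, c("cell", "mc", "structure", "dynamics"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if ("cell" %in% stages) {
    curve <- size_vs_packing(geom, eta_grid)
    write_tsv(curve, file.path(out_dir, "theory_curve.tsv"))
    results$cell <- curve
  }

  if ("mc" %in% stages) {
    trajs <- list()
    for (k in seq_along(eta_grid)) {
      eta <- eta_grid[k]
      cfg <- sim_config(seed = seed + k, n_steps = n_steps)
      tr <- run_state_point(eta, config = cfg, geom = geom)
      write_xyz(tr$snapshots,
                file.path(out_dir, sprintf("snapshots_eta%.2f.xyz", eta)),
                eta = eta, sigma = tr$sigma, steps = tr$snapshot_sweeps)
      write_tsv(data.frame(sweep = seq_along(tr$energy),
                           energy = tr$energy, acceptance = tr$acceptance),
                file.path(out_dir, sprintf("energy_eta%.2f.tsv", eta)))
      trajs[[k]] <- tr
    }
    results$mc <- trajs
  }

  if ("structure" %in% stages) {
    if (is.null(results$mc))
      stop("pipeline_run(): structure stage requires the mc stage")
    rows <- lapply(results$mc, function(tr) {
      om <- order_metrics(tr$snapshots, sigma = tr$sigma)
      data.frame(eta = tr$eta, sigma = tr$sigma, r_p = om$r_p, g_p = om$g_p,
                 neighbor_cutoff = om$neighbor_cutoff,
                 mean_psi6 = om$mean_psi6, mean_neighbors = om$mean_neighbors)
    })
    metrics <- do.call(rbind, rows)
    write_tsv(metrics, file.path(out_dir, "structure_metrics.tsv"))
    results$structure <- metrics
  }

  if ("dynamics" %in% stages) {
    ts <- gen_brownian_tracks(50, D = 0.01, n_frames = 400, seed = seed)
    curve <- msd(drift_correct(ts))
    write_tsv(data.frame(lag_time = curve$lag_times, msd = curve$msd,
                         n_pairs = curve$n_pairs),
              file.path(out_dir, "msd.tsv"))
    results$dynamics <- curve
  }

  manifest <- list(
    command = "pipeline_run",
    stages = stages, seed = seed, eta_grid = eta_grid,
    package_version = as.character(utils::packageVersion("brushpack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list.files(out_dir))
  .atomic_write(function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE),
    file.path(out_dir, "manifest.json"))
  invisible(results)
}
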