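#' Write a 2-D map as a 32-bit float TIFF with a JSON sidecar
#'
#' The TIFF stores values scaled into `[0, 1]`; the scale factor, pixel
#' size and any extra metadata go into `<path>.json` so the map round-trips
#' losslessly (to float32 precision) through [read_map_tiff()].
#'
#' @param m numeric matrix (speed map, density map, light pattern ...).
#' @param path output TIFF path.
#' @param pixel_size pixel edge (µm).
#' @param meta named list of extra metadata for the sidecar.
#' @export
write_map_tiff <- function(m, path, pixel_size = 2, meta = list()) {
  m <- as.matrix(m)
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  side <- c(list(offset = lo, scale = scale, pixel_size_um = pixel_size),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a map written by [write_map_tiff()]
#'
#' @param path TIFF path (the `.json` sidecar must sit next to it).
#' @return numeric matrix with attribute `pixel_size`.
#' @export
read_map_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * side$scale + side$offset
  attr(m, "pixel_size") <- side$pixel_size_um
  m
}

#' Read an 8-bit grayscale PNG as a light pattern
#'
#' @param path PNG path.
#' @return matrix of 8-bit levels (0-255).
#' @export
read_light_pattern <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]   # first channel of RGB(A)
  round(img * 255)
}

#' Write a light pattern as an 8-bit grayscale PNG
#'
#' @param pattern matrix of levels in `[0, 255]`.
#' @param path PNG path.
#' @export
write_light_pattern <- function(pattern, path) {
  png::writePNG(pmin(pmax(as.matrix(pattern), 0), 255) / 255, path)
  invisible(path)
}

# default configuration tree; load_config() fills and validates against it
default_config <- function() {
  list(
    seed = 1L,
    pixel_size_um = 2,
    level_to_power = NA_real_,   # calibration: 8-bit level -> mW/mm^2
    response = list(v_dark = 2, v_sat = 8, I_half = 50, r_sigma = 0.45),
    memory = list(beta = 0.44, tau_m = 35),
    sim = list(n_agents = 20000, dt = 0.05, alpha_motile = 0.5,
               tau_rot = 20, tau_run = NA, mean_sat_speed = 8, Z = 4,
               D_brownian = 0.3, boundary = "periodic"),
    ddm = list(q_min = 0.45, q_max = 1.2, frame_interval = 0.25),
    imaging = list(psf_sigma = 2, counts_per_agent = 30,
                   stray_background = 5, flatfield_sigma = 100),
    feedback = list(gain = 60, period = 20, bounds = c(0, 255),
                    quantize = TRUE, snapshot_every = 2, smooth_sigma = 4),
    estimates = list(l = 1000, v = 5, tau_run = 1, tau_rot = 20,
                     mu = 50, a = 1, temperature_K = 298))
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults)) {
      stop("unknown configuration key: ", path, k)
    }
    if (is.list(defaults[[k]]) && !is.null(defaults[[k]]) &&
        is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial) YAML configuration, fills unset entries with
#' package defaults, and rejects unknown keys. An empty or missing-section
#' file yields the full default configuration. The tree has sections
#' `response`, `memory`, `sim`, `ddm`, `imaging`, `feedback`, `estimates`
#' plus the global `seed`, `pixel_size_um` and the `level_to_power`
#' calibration scalar (8-bit projector level to mW/mm²). In the `sim`
#' section `tau_run: NA` (the default) disables tumbling; pass `NULL` for
#' `tau_run` when forwarding to [sim_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg$memory, memory_params(beta, tau_m))
  with(cfg$response, intensity_response(v_dark, v_sat, I_half))
  # dt must keep the fastest plausible agent under one pixel per step
  v_max <- cfg$response$v_sat * 3      # ~3x the mean saturation speed
  if (v_max * cfg$sim$dt > cfg$pixel_size_um) {
    stop(sprintf(
      "sim.dt = %g violates v_max * dt <= pixel (%g * %g > %g um)",
      cfg$sim$dt, v_max, cfg$sim$dt, cfg$pixel_size_um))
  }
  invisible(cfg)
}

#' Save a run configuration to YAML
#'
#' @param cfg configuration list (as from [load_config()]).
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the resolved configuration, the seed and the package version
#' next to a run's outputs so that any artifact can be regenerated.
#'
#' @param path output JSON path.
#' @param cfg resolved configuration list.
#' @param seed seed actually used.
#' @param extra named list of additional entries.
#' @export
write_manifest <- function(path, cfg, seed, extra = list()) {
  man <- c(list(package = "photokin",
                version = as.character(utils::packageVersion("photokin")),
                timestamp = format(Sys.time(), tz = "UTC",
                                   "%Y-%m-%dT%H:%M:%SZ"),
                seed = seed, config = cfg), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Derive deterministic child seeds from one global seed
#'
#' A single run seed spawns one sub-seed per pipeline stage so that stages
#' can be re-run independently yet reproducibly.
#'
#' @param seed global integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n` (all below 2^31).
#' @export
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
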