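CONFIG_SCHEMA_VERSION <- 1L

#' Save / load a model configuration
#'
#' Round-trips a \code{\link{model_config}} through a human-readable YAML
#' file with an explicit schema version.  Loading validates every module
#' invariant (geometry, wiring probabilities, dynamics) and fills
#' defaults; errors name the offending key.
#'
#' @param cfg a \code{model_config}.
#' @param path file path.
#' @return \code{save_config}: the path, invisibly; \code{load_config}:
#'   the validated \code{model_config}.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  payload <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    model = cfg$model,
    geometry = list(
      grid = as.integer(cfg$geometry$grid),
      minicolumns_per_hypercolumn = cfg$geometry$minicolumns_per_hypercolumn,
      pyramidal = cfg$geometry$pyramidal_full,
      basket = cfg$geometry$basket_full,
      rsnp = cfg$geometry$rsnp_full,
      relays = cfg$geometry$relays_full,
      scale = cfg$geometry$scale
    ),
    wiring = unclass(cfg$wiring)[setdiff(names(cfg$wiring), "model")],
    protocol = cfg$protocol,
    dynamics = list(
      adaptation_tau = cfg$dynamics$cells$pyramidal$ca_tau,
      depression_U = cfg$dynamics$cells$pyramidal$U,
      depression_tau = cfg$dynamics$cells$pyramidal$tau_rec,
      background_rate = cfg$dynamics$background$rate
    ),
    feedback = cfg$feedback
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  p <- yaml::read_yaml(path)
  if (is.null(p$schema_version) || p$schema_version != CONFIG_SCHEMA_VERSION) {
    stop("schema_version: unsupported or missing (expected ", CONFIG_SCHEMA_VERSION, ")")
  }
  g <- p$geometry
  if (is.null(g$scale) || g$scale <= 0) stop("geometry$scale: must be positive")
  cfg <- model_config(p$model, scale = g$scale,
                      mask_points = p$protocol$mask_points,
                      mask_distance = p$protocol$mask_distance,
                      feedback = isTRUE(p$feedback))
  cfg$geometry <- geometry_config(p$model, grid = g$grid,
                                  minicolumns_per_hypercolumn = g$minicolumns_per_hypercolumn,
                                  pyramidal = g$pyramidal, basket = g$basket,
                                  rsnp = g$rsnp, relays = g$relays, scale = g$scale)
  wc <- cfg$wiring
  for (k in names(p$wiring)) {
    if (!k %in% names(wc)) stop("wiring$", k, ": unknown key")
    wc[[k]] <- p$wiring[[k]]
  }
  if (any(wc$lateral_profile < 0 | wc$lateral_profile > 1)) {
    stop("wiring$lateral_profile: probabilities must lie in [0,1]")
  }
  for (k in grep("^p_", names(wc), value = TRUE)) {
    if (wc[[k]] < 0 || wc[[k]] > 1) stop("wiring$", k, ": probability out of [0,1]")
  }
  cfg$wiring <- wc
  for (k in names(p$protocol)) cfg$protocol[[k]] <- p$protocol[[k]]
  d <- p$dynamics
  cfg$dynamics <- dynamics_config(adaptation_tau = d$adaptation_tau,
                                  depression_U = d$depression_U,
                                  depression_tau = d$depression_tau,
                                  background_rate = d$background_rate)
  validate_dynamics(cfg$dynamics)
  cfg
}

#' Serialize geometry and patterns to JSON
#'
#' Writes a versioned JSON document with the hypercolumn grid, cell
#' counts and (optionally) the stored pattern sets.  Minicolumn and
#' pattern ids are written 0-based in the file; the in-memory
#' representation is 1-based.
#'
#' @param geom a \code{network_geometry}.
#' @param path output path.
#' @param v1_patterns,v2_patterns optional \code{pattern_set}s.
#' @return the path, invisibly.
#' @export
write_geometry_json <- function(geom, path, v1_patterns = NULL, v2_patterns = NULL) {
  pat_payload <- function(ps) {
    if (is.null(ps)) return(NULL)
    list(area = ps$area, kind = ps$kind,
         minicolumns = lapply(ps$patterns, function(p) as.integer(p - 1L)))
  }
  payload <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    model = geom$config$model,
    grid = as.integer(geom$grid),
    minicolumns_per_hypercolumn = geom$mc_per_hc,
    counts = as.list(geom$counts),
    lgn_locations = geom$lgn_locations,
    total_cells = geom$n_cells,
    v1_patterns = pat_payload(v1_patterns),
    v2_patterns = pat_payload(v2_patterns)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Pre-assembled miniature fixture networks
#'
#' Small presets used throughout the integration tests: they build in a
#' few seconds and exercise every wiring stage.
#' \itemize{
#'   \item \code{tiny_model1}: 2 x 2 hypercolumns, 4 minicolumns each,
#'     4/1/1 cells per minicolumn per layer, 3 relays per location, with
#'     2 random patterns of 3 minicolumns.
#'   \item \code{tiny_model2}: 3 x 3 hypercolumns, 2 minicolumns each
#'     (6 vertical-line patterns of 3 minicolumns), same cell complement.
#' }
#'
#' @param preset \code{"tiny_model1"} or \code{"tiny_model2"}.
#' @param individual_seed wiring seed.
#' @param feedback wire feedback projections?
#' @param ... overrides forwarded to \code{\link{wiring_config}}.
#' @return A \code{cortical_network}.
#' @export
fixture_network <- function(preset = c("tiny_model1", "tiny_model2"),
                            individual_seed = 1L, feedback = TRUE, ...) {
  preset <- match.arg(preset)
  if (preset == "tiny_model1") {
    gc <- geometry_config("model1", grid = c(2, 2),
                          minicolumns_per_hypercolumn = 4L,
                          pyramidal = 4L, basket = 1L, rsnp = 1L, relays = 3L)
    geom <- build_geometry(gc)
    v1 <- generate_patterns_random(geom, 2L, 3L, seed = individual_seed * 2L + 1L)
    v2 <- generate_patterns_random(geom, 2L, 3L, seed = individual_seed * 2L + 2L,
                                   area = "V2")
    wc <- wiring_config("model1", ...)
  } else {
    gc <- geometry_config("model2", grid = c(3, 3),
                          minicolumns_per_hypercolumn = 2L,
                          pyramidal = 4L, basket = 1L, rsnp = 1L, relays = 3L)
    geom <- build_geometry(gc)
    v1 <- generate_patterns_lines(geom)
    v2 <- generate_patterns_lines(geom, area = "V2")
    wc <- wiring_config("model2", ...)
  }
  assemble_network(geom, v1, v2, link_patterns(v1, v2), wc,
                   individual_seed = individual_seed,
                   feedback_enabled = feedback)
}

#' Run manifest
#'
#' Records the provenance of a set of output files: a hash of the
#' configuration, the seeds used, the package version, and a checksum
#' per output file.  Reruns of deterministic stages with equal manifest
#' inputs yield equal checksums.
#'
#' @param cfg the \code{model_config} used.
#' @param seeds named list/vector of seeds.
#' @param files character vector of output file paths.
#' @param path optional path to write the manifest as JSON.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(cfg, seeds, files = character(0), path = NULL) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  save_config(cfg, tf)
  manifest <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("attractormask")),
    config_hash = unname(tools::md5sum(tf)),
    seeds = as.list(seeds),
    files = if (length(files)) {
      lapply(stats::setNames(files, basename(files)),
             function(f) list(path = f, md5 = unname(tools::md5sum(f))))
    } else list()
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }
  manifest
}
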