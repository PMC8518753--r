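#' Read a run configuration
#'
#' YAML configuration with unit-bearing keys, grouped in blocks:
#' `kinetics` (rate constants `k1_per_mM_s` .. `k5_per_mM_s`,
#' `k6_per_s`), `tube` (`propargyl0_mM`, `catalyst0_mM`,
#' `hydrogen_clamp_mM`, `schedule_s`), `synth` (`noise_sd_mM`, `seed`),
#' `chip` (geometry overrides in mm, `h_pdms_mM`, `D_m2_s`), and `sweep`
#' (`flow_uL_min` grid, `scenario`). All blocks are optional; missing values
#' take the package defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed config: top level must be a mapping")
  known <- c("kinetics", "tube", "synth", "chip", "sweep", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Rate constants from a config kinetics block
#'
#' @param cfg Config list from [read_run_config()].
#' @return Named `k1`..`k6` vector; package defaults where unspecified.
#' @export
config_rate_constants <- function(cfg) {
  ks <- calibrated_rate_constants()
  blk <- cfg$kinetics
  if (!is.null(blk)) {
    for (i in 1:5) {
      key <- sprintf("k%d_per_mM_s", i)
      if (!is.null(blk[[key]])) ks[[i]] <- as.numeric(blk[[key]])
    }
    if (!is.null(blk$k6_per_s)) ks[["k6"]] <- as.numeric(blk$k6_per_s)
  }
  ks
}

#' Build the chip geometry and transport config from a config chip block
#'
#' The `chip` block carries unit-bearing keys: geometry overrides in mm
#' (`channel_length_mm`, `channel_width_mm`, `membrane_length_mm`,
#' `membrane_thickness_mm`, `membrane_start_mm`, `chamber_length_mm`,
#' `chamber_width_mm`, `chamber_start_mm`, `chamber_shift_mm`, `depth_mm`,
#' `dx_mm`), plus `flow_uL_min`, `D_m2_s`, `h_pdms_mM` and `inlet_mM` (a
#' mapping from species id to mM) for the transport configuration.
#'
#' @param cfg Config list from [read_run_config()] (or a bare chip block).
#' @param flow_uL_min Flow rate override; required if the block has none.
#' @return List with `geometry` (a `chip_geometry`) and `config`
#'   (a `chip_config`).
#' @export
config_chip <- function(cfg, flow_uL_min = NULL) {
  blk <- if (!is.null(cfg$chip)) cfg$chip else cfg
  geo_keys <- c("channel_length_mm", "channel_width_mm",
                "membrane_length_mm", "membrane_thickness_mm",
                "membrane_start_mm", "chamber_length_mm", "chamber_width_mm",
                "chamber_start_mm", "chamber_shift_mm", "depth_mm", "dx_mm")
  geo_args <- blk[intersect(names(blk), geo_keys)]
  geometry <- do.call(build_geometry, lapply(geo_args, as.numeric))
  q <- if (!is.null(flow_uL_min)) flow_uL_min else blk$flow_uL_min
  if (is.null(q)) stop("no flow_uL_min in the chip block or arguments")
  cfg_args <- list(flow_uL_min = as.numeric(q))
  if (!is.null(blk$D_m2_s)) cfg_args$D_m2_s <- as.numeric(blk$D_m2_s)
  if (!is.null(blk$h_pdms_mM)) cfg_args$h_pdms_mM <- as.numeric(blk$h_pdms_mM)
  if (!is.null(blk$inlet_mM)) cfg_args$inlet_mM <- unlist(blk$inlet_mM)
  list(geometry = geometry, config = do.call(chip_config, cfg_args))
}

#' Write a provenance log for an analysis run
#'
#' Records what produced the artifacts in an output directory: the digest of
#' the configuration used, the seed, package and R versions, and a
#' timestamp.
#'
#' @param dir Output directory (created if needed).
#' @param config Configuration list (or `NULL`).
#' @param seed Seed used for any randomness (or `NULL`).
#' @param extra Optional named list of extra fields.
#' @return The provenance list, invisibly.
#' @export
write_provenance <- function(dir, config = NULL, seed = NULL, extra = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(list(
    config_digest = if (is.null(config)) NA_character_ else
      paste0(format(sum(utf8ToInt(yaml::as.yaml(config)) *
                          seq_along(utf8ToInt(yaml::as.yaml(config)))) %%
                      .Machine$integer.max)),
    seed = if (is.null(seed)) NA else seed,
    package_version = as.character(utils::packageVersion("phipflow")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), extra)
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(prov)
}
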