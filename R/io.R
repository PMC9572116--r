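#' Write a radar cube as raw interleaved int16
#'
#' Dialect: frame-major, then sample-major within each frame, I before Q,
#' little-endian int16. Floating-point samples are scaled by `scale`
#' (default: 32000 / max|sample|) before quantisation; the scale, the radar
#' configuration and any ground truth go into a JSON sidecar at
#' `<path>.json` so the file is self-describing.
#'
#' @param cube An [iq_cube()].
#' @param path Output file path.
#' @param scale Optional quantisation scale.
#' @return `path`, invisibly.
#' @export
write_raw_cube <- function(cube, path, scale = NULL) {
  stopifnot(inherits(cube, "iq_cube"))
  I <- Re(cube$data); Q <- Im(cube$data)
  peak <- max(abs(c(I, Q)), 1e-300)
  scale <- scale %||% (32000 / peak)
  # interleave I,Q per sample, frames consecutive (column-major matches frame-major)
  inter <- rbind(as.vector(I), as.vector(Q)) * scale
  stor <- as.integer(pmin(pmax(round(inter), -32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(stor, con, size = 2L, endian = "little")
  sidecar <- list(
    format = "interleaved-int16-iq", scale = scale,
    n_samples = cube$config$n_samples, n_frames = cube$config$n_frames,
    config = unclass(cube$config)[c("fc", "Tc", "slope", "Fs", "Ts",
                                    "n_samples", "n_frames")],
    truth = if (!is.null(cube$truth)) unclass(cube$truth) else NULL
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a raw interleaved int16 cube
#'
#' Inverse of [write_raw_cube()]. When `config` is `NULL` the JSON sidecar at
#' `<path>.json` is consulted for the dimensions, scale and configuration.
#'
#' @param path Raw file path.
#' @param config Optional [radar_config()]; overrides the sidecar.
#' @param scale Quantisation scale to undo; sidecar value when `NULL`, else 1.
#' @return An [iq_cube()].
#' @export
read_raw_cube <- function(path, config = NULL, scale = NULL) {
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  if (is.null(config)) {
    if (is.null(sidecar)) stop("no config given and no sidecar found at ", sidecar_path)
    cf <- sidecar$config
    config <- radar_config(fc = cf$fc, Tc = cf$Tc, slope = cf$slope, Fs = cf$Fs,
                           Ts = cf$Ts, n_samples = cf$n_samples,
                           n_frames = cf$n_frames)
  }
  scale <- scale %||% sidecar$scale %||% 1
  expected <- config$n_samples * config$n_frames * 2L * 2L
  actual <- file.size(path)
  if (is.na(actual) || actual != expected) {
    stop(sprintf("file size mismatch: expected %d bytes for %d x %d I/Q int16, found %s",
                 expected, config$n_samples, config$n_frames, actual))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw16 <- readBin(con, integer(), n = expected / 2L, size = 2L,
                   endian = "little", signed = TRUE)
  I <- raw16[c(TRUE, FALSE)] / scale
  Q <- raw16[c(FALSE, TRUE)] / scale
  iq_cube(matrix(complex(real = I, imaginary = Q),
                 config$n_samples, config$n_frames), config)
}

#' Pipeline configuration object
#'
#' Bundles every tunable the command-line pipeline uses into one
#' serialisable record: radar timing, denoiser constants, VMD solver
#' settings, decision thresholds and the master seed.
#'
#' @param radar,wit,vmd Parameter objects (defaults as documented in
#'   [radar_config()], [wit_params()], [vmd_params()]).
#' @param conf_threshold,diff_threshold,decisive_conf Heart-decision
#'   thresholds (see [decide_heart_rate()]).
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(radar = radar_config(), wit = wit_params(),
                            vmd = vmd_params(), conf_threshold = 0.3,
                            diff_threshold = 0.15, decisive_conf = 1.0,
                            seed = 1L) {
  structure(list(radar = radar, wit = wit, vmd = vmd,
                 conf_threshold = conf_threshold,
                 diff_threshold = diff_threshold,
                 decisive_conf = decisive_conf,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_config_keys <- list(
  radar = c("fc", "Tc", "slope", "Fs", "Ts", "n_samples", "n_frames"),
  wit = c("C", "beta", "rho", "A", "wavelet", "levels", "k_range",
          "noise_mode", "seed"),
  vmd = c("K", "alpha", "tau_admm", "eps", "max_iter"),
  top = c("radar", "wit", "vmd", "conf_threshold", "diff_threshold",
          "decisive_conf", "seed")
)

#' Write a pipeline configuration to YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- list(
    radar = unclass(cfg$radar)[pipeline_config_keys$radar],
    wit = unclass(cfg$wit)[pipeline_config_keys$wit],
    vmd = unclass(cfg$vmd)[pipeline_config_keys$vmd],
    conf_threshold = cfg$conf_threshold,
    diff_threshold = cfg$diff_threshold,
    decisive_conf = cfg$decisive_conf,
    seed = cfg$seed
  )
  writeLines(yaml::as.yaml(x, precision = 17), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys anywhere in the file are rejected, so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  check_keys <- function(got, allowed, where) {
    bad <- setdiff(names(got), allowed)
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in %s: %s", where, paste(bad, collapse = ", ")))
    }
  }
  check_keys(x, pipeline_config_keys$top, "config")
  check_keys(x$radar, pipeline_config_keys$radar, "radar block")
  check_keys(x$wit, pipeline_config_keys$wit, "wit block")
  check_keys(x$vmd, pipeline_config_keys$vmd, "vmd block")
  radar <- do.call(radar_config, x$radar %||% list())
  wit <- do.call(wit_params, x$wit %||% list())
  vmd <- do.call(vmd_params, x$vmd %||% list())
  pipeline_config(radar = radar, wit = wit, vmd = vmd,
                  conf_threshold = x$conf_threshold %||% 0.3,
                  diff_threshold = x$diff_threshold %||% 0.15,
                  decisive_conf = x$decisive_conf %||% 1.0,
                  seed = x$seed %||% 1L)
}

#' Serialise a vitals report to JSON
#'
#' @param report A `vitals_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$heart_decision <- unclass(x$heart_decision)
  x$denoise_diagnostics$thresholds <- NULL # bulky; K values and counts suffice
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
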