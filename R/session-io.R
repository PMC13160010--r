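SESSION_FORMAT_VERSION <- "1.0"

#' Write a session to disk
#'
#' Serializes a session into a directory: `session.json` (format version,
#' configuration, tuning model, trial table and run settings) plus
#' delimited-text arrays `counts.csv`, `rates.csv` and `kinematics.csv`
#' (the per-bin table, including labels when present). All files are plain
#' text and readable by [read_session()].
#'
#' @param session A [generate_session()] session.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- unclass(session$config)
  tun <- list(
    baseline = session$tuning$baseline,
    preferred_direction = session$tuning$preferred_direction,
    depth = session$tuning$depth,
    error_loading = session$tuning$error_loading
  )
  meta <- list(
    format_version = SESSION_FORMAT_VERSION,
    config = cfg, tuning = tun,
    trials = session$trials,
    bias_direction = session$bias_direction,
    policy = unclass(session$policy),
    seed = session$seed, cursor_mode = session$cursor_mode,
    attenuation = session$attenuation
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(session$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(session$rates, file.path(dir, "rates.csv"),
                   row.names = FALSE)
  utils::write.csv(session$bins, file.path(dir, "kinematics.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a session from disk
#'
#' Reads a directory written by [write_session()] and rebuilds the
#' `bci_session` object, checking the format-version field.
#'
#' @param dir Session directory.
#' @return A `bci_session`.
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path)) abort("Not a session directory (no session.json).")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$format_version)) abort("Missing format-version field.")
  if (package_version(meta$format_version) > package_version(SESSION_FORMAT_VERSION)) {
    abort(sprintf("Session format %s is newer than supported (%s).",
                  meta$format_version, SESSION_FORMAT_VERSION))
  }
  cfg <- meta$config
  cfg$n_channels <- as.integer(cfg$n_channels)
  cfg$n_targets <- as.integer(cfg$n_targets)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$bias_direction) && length(cfg$bias_direction) == 0L) {
    cfg$bias_direction <- NULL
  }
  class(cfg) <- "sim_config"
  tuning <- structure(
    list(baseline = meta$tuning$baseline,
         preferred_direction = matrix(unlist(meta$tuning$preferred_direction),
                                      ncol = 2),
         depth = meta$tuning$depth,
         error_loading = matrix(unlist(meta$tuning$error_loading), ncol = 2),
         n_channels = cfg$n_channels),
    class = "bci_tuning"
  )
  counts <- unname(as.matrix(utils::read.csv(file.path(dir, "counts.csv"))))
  storage.mode(counts) <- "integer"
  rates <- unname(as.matrix(utils::read.csv(file.path(dir, "rates.csv"))))
  bins <- as_tibble(utils::read.csv(file.path(dir, "kinematics.csv")))
  structure(
    list(config = validate_sim_config(cfg), tuning = tuning,
         trials = as_tibble(meta$trials), bins = bins,
         counts = counts, rates = rates,
         bias_direction = meta$bias_direction,
         policy = structure(meta$policy, class = "modulation_policy"),
         seed = meta$seed, cursor_mode = meta$cursor_mode,
         attenuation = meta$attenuation),
    class = "bci_session"
  )
}
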