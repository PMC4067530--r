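#' Load a simulation configuration from YAML or JSON
#'
#' Unspecified keys take the package defaults (see [sim_config()]); unknown
#' keys are a hard error so typos cannot silently revert a parameter to its
#' default.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   [sim_config()] argument names.
#' @return A validated `sim_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "relay_config.yaml",
#'                                package = "dnarelay"))
#' cfg$k_cat
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  values <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  if (is.null(values)) values <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, values)
}

#' Validate a spot-tracking table
#'
#' Schema and invariant checks for the tables consumed by the trajectory
#' analysis: required columns, strictly increasing frames per cell, at most
#' two spots per cell per frame, and (when cell geometry is supplied)
#' positions within the cell bounds. Errors cite the offending cell.
#'
#' @param spots Data frame or path to a TSV with columns `cell_id`, `frame`,
#'   `t_s`, `x_um`, `y_um`.
#' @param meta Optional per-cell metadata (data frame with `cell_id`,
#'   `length_um`, `width_um`).
#' @return The parsed table, invisibly.
#' @export
validate_spot_table <- function(spots, meta = NULL) {
  if (is.character(spots)) spots <- read.delim(spots)
  req <- c("cell_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(spots))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (cell in unique(spots$cell_id)) {
    s <- spots[spots$cell_id == cell, ]
    counts <- table(s$frame)
    if (any(counts > 2))
      stop("cell ", cell, ": more than 2 spots in a frame (frames ",
           paste(names(counts)[counts > 2], collapse = ", "),
           "); at most two partition complexes are expected", call. = FALSE)
    fr <- unique(s$frame)
    if (is.unsorted(fr, strictly = FALSE))
      stop("cell ", cell, ": frame column is not non-decreasing",
           call. = FALSE)
    if (!is.null(meta)) {
      g <- meta[meta$cell_id == cell, ]
      if (nrow(g) == 1 &&
          (any(s$x_um < 0 | s$x_um > g$length_um) ||
           any(abs(s$y_um) > g$width_um / 2)))
        stop("cell ", cell, ": spot positions outside the cell bounds",
             call. = FALSE)
    }
  }
  invisible(spots)
}

#' Write per-run trajectories as TSV
#'
#' @param trajectories A `bd_trajectory` or list of them.
#' @param path Output file; columns `run`, `t_s`, `x_um`, `y_um`, `n_bound`.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectories, path) {
  if (inherits(trajectories, "bd_trajectory"))
    trajectories <- list(trajectories)
  tab <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    data.frame(run = i, t_s = tr$t_s, x_um = tr$x_um, y_um = tr$y_um,
               n_bound = tr$n_bound)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble summary as CSV
#'
#' @param ensemble A `bd_ensemble`.
#' @param path Output file; columns `t_s`, `mean_x_um`,
#'   `completion_fraction`.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "bd_ensemble"))
  write.csv(data.frame(t_s = ensemble$times, mean_x_um = ensemble$mean_x,
                       completion_fraction = ensemble$completion_fraction),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records everything needed to re-execute a run: the resolved
#' configuration, seed(s), package version and input/output file digests.
#'
#' @param path Output JSON file.
#' @param config The resolved configuration (list or `sim_config`).
#' @param seed Seed(s) used.
#' @param files Optional character vector of associated files to digest.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, files = character(0),
                               extra = list()) {
  digests <- vapply(files, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- c(list(
    package = "dnarelay",
    version = as.character(utils::packageVersion("dnarelay")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    file_digests = as.list(digests)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
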