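# Trial-record CSV format, run configuration and run manifests.
#
# Angles are stored raw (unoriented, degrees); orientation and baseline
# subtraction are analysis steps, never baked into files. Time fields are
# milliseconds. `clamp_deg` is empty exactly on no-feedback (probe) trials.

trial_record_cols <- c(participant_id = "character", design = "character",
                       platform = "character", clamp_dir = "character",
                       phase = "character", trial = "integer",
                       cs = "character", clamp_deg = "numeric",
                       hand_angle_deg = "numeric", angle_50ms_deg = "numeric",
                       rt_ms = "numeric", mt_ms = "numeric")

#' Write trial records to CSV
#'
#' @param cohort Long tibble of trial records (one or more participants).
#' @param path Output CSV path.
#' @export
write_trials <- function(cohort, path) {
  missing <- setdiff(names(trial_record_cols), names(cohort))
  if (length(missing))
    stop("cohort lacks columns: ", paste(missing, collapse = ", "))
  utils::write.csv(cohort[, names(trial_record_cols)], path,
                   row.names = FALSE, na = "")
}

#' Read trial records from CSV
#'
#' Header-keyed (column order is free); validates the schema and the
#' structural invariants: contiguous 1-based trial indices per participant,
#' `clamp_deg` present exactly on feedback trials, angle/time fields numeric.
#'
#' @param path CSV path.
#' @return A typed tibble of trial records.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(names(trial_record_cols), names(raw))
  extra <- setdiff(names(raw), names(trial_record_cols))
  if (length(missing) || length(extra))
    stop("trial-record schema mismatch; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  out <- tibble::as_tibble(raw[, names(trial_record_cols)])
  for (col in names(trial_record_cols)) {
    type <- trial_record_cols[[col]]
    if (type == "numeric") {
      v <- suppressWarnings(as.numeric(ifelse(out[[col]] == "", NA,
                                              out[[col]])))
      bad <- which(!is.na(out[[col]]) & out[[col]] != "" & is.na(v))
      if (length(bad))
        stop("unparseable numeric in column '", col, "' at data row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      out[[col]] <- v
    } else if (type == "integer") {
      out[[col]] <- as.integer(out[[col]])
    }
  }
  for (pid in unique(out$participant_id)) {
    tr <- out$trial[out$participant_id == pid]
    if (!identical(tr, seq_along(tr)))
      stop("trial indices for participant ", pid,
           " are not contiguous and 1-based")
  }
  probe_with_clamp <- out$phase == "probe" & !is.na(out$clamp_deg)
  acq_without <- out$phase == "acquisition" & is.na(out$clamp_deg)
  if (any(probe_with_clamp) || any(acq_without))
    stop("clamp_deg must be empty exactly on no-feedback (probe) trials")
  out
}

#' Read a run configuration
#'
#' A YAML file with sections `design`, `model`, `synthetic`, `analysis`,
#' `seed`, `out_dir`; missing entries take package defaults. The fully
#' resolved configuration is what [write_run_manifest()] stores next to a
#' run's outputs.
#'
#' @param path YAML file path.
#' @return A named list with all fields resolved.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(design = "exp1_differential", model = "rw",
                   n_participants = 16, seed = 1L, out_dir = ".",
                   synthetic = list(), analysis = list(bin_width = 50,
                                                       statistic = "mean"))
  out <- utils::modifyList(defaults, cfg)
  if (!out$design %in% DESIGNS)
    stop("unknown design: ", out$design)
  out
}

#' Write a run manifest beside a run's outputs
#'
#' Records the resolved configuration, master seed, package version and R
#' version, so that a run's outputs are reproducible from the manifest
#' alone.
#'
#' @param config Resolved configuration list.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- c(config,
                list(package_version =
                       as.character(utils::packageVersion("adaptcond")),
                     r_version = R.version.string))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
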