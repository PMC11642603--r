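#' Read and write trial designs as CSV
#'
#' @param design Trial table from [generate_design()].
#' @param path File path.
#' @return `read_design` returns the validated trial `data.frame`.
#' @export
write_design <- function(design, path) {
  write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "context", "block", "combination", "own_shape",
            "partner_shape", "cue_pair", "is_catch", "congruency",
            "start_time", "partner_duration", "drawing_duration",
            "delta_time", "catch_response")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file ", path, " missing columns: ",
         paste(miss, collapse = ", "))
  d
}

#' Read and write trajectories as long-format CSV
#'
#' One row per pen sample, keyed by trial id: columns `trial_id`,
#' `sample_idx`, `x`, `y`, `t`.
#'
#' @param trajectories List of trajectories ([generate_trajectories()]
#'   format).
#' @param path File path.
#' @return `read_trajectories` returns the list of trajectories.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    data.frame(trial_id = tr$trial_id,
               sample_idx = seq_len(nrow(tr$samples)),
               x = tr$samples[, "x"], y = tr$samples[, "y"],
               t = tr$samples[, "t"])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  d <- read.csv(path)
  miss <- setdiff(c("trial_id", "sample_idx", "x", "y", "t"), names(d))
  if (length(miss))
    stop("trajectory file ", path, " missing columns: ",
         paste(miss, collapse = ", "))
  lapply(split(d, d$trial_id), function(g) {
    g <- g[order(g$sample_idx), ]
    list(trial_id = g$trial_id[1],
         samples = cbind(x = g$x, y = g$y, t = g$t))
  })
}

#' Read and write epoch sets as HDF5
#'
#' The container holds the dataset `data` (trials x channels x time), the
#' scalars `sfreq` and `tmin`, `channel_names`, `channel_pos`, and the
#' per-trial condition labels as the compound dataset `events`.  Reading
#' validates the schema and refuses containers whose label count does not
#' match the trial dimension.
#'
#' @param epochs An [epoch_set()].
#' @param path File path (`.h5`).
#' @return `read_epochs` returns the [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$sfreq, path, "sfreq")
  rhdf5::h5write(epochs$times[1], path, "tmin")
  rhdf5::h5write(epochs$channel_names, path, "channel_names")
  if (!is.null(epochs$channel_pos))
    rhdf5::h5write(epochs$channel_pos, path, "channel_pos")
  ev <- epochs$labels
  for (cl in names(ev)) if (is.logical(ev[[cl]])) ev[[cl]] <-
      as.integer(ev[[cl]])
  rhdf5::h5write(ev, path, "events")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  have <- rhdf5::h5ls(path)$name
  for (ds in c("data", "sfreq", "channel_names", "events"))
    if (!ds %in% have)
      stop("epochs container ", path, " is missing dataset '", ds, "'")
  dat <- rhdf5::h5read(path, "data")
  sfreq <- as.numeric(rhdf5::h5read(path, "sfreq"))
  tmin <- if ("tmin" %in% have) as.numeric(rhdf5::h5read(path, "tmin")) else 0
  ch <- as.character(rhdf5::h5read(path, "channel_names"))
  pos <- if ("channel_pos" %in% have) rhdf5::h5read(path, "channel_pos")
    else NULL
  ev <- as.data.frame(rhdf5::h5read(path, "events"))
  ev[] <- lapply(ev, as.vector)
  rhdf5::h5closeAll()
  for (cl in c("is_catch", "catch_response")) if (cl %in% names(ev))
    ev[[cl]] <- as.logical(ev[[cl]])
  epoch_set(dat, sfreq, ev, channel_names = ch, channel_pos = pos,
            tmin = tmin)
}

#' Write an analysis report as JSON
#'
#' @param report Named list (nested lists / data.frames allowed).
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}
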