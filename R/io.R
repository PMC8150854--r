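## Tabular output is TSV (tab-separated, header row, '.' decimal) for
## locale safety; run metadata goes in a JSON sidecar with sorted keys so
## reruns diff cleanly.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a trajectory as TSV with a JSON sidecar
#'
#' The TSV has columns `time, nR, nA, nAR, nARA`; the sidecar
#' (`<path>.json`) records the parameters, seed and package version so a
#' run can be reproduced.
#'
#' @param traj a `trajectory` object.
#' @param path output TSV path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  write_tsv(as.data.frame(traj), path)
  meta <- list(kind = "trajectory",
               params = traj$params[order(names(traj$params))],
               seed = traj$seed, absorbed = traj$absorbed,
               end_time = traj$end_time,
               package_version = as.character(utils::packageVersion("stochfr")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  params <- do.call(model_params,
                    meta$params[names(meta$params) %in%
                                  names(formals(model_params))])
  structure(list(times = df$time,
                 states = as.matrix(df[, STATE_VARS]),
                 absorbed = isTRUE(meta$absorbed),
                 end_time = meta$end_time, seed = meta$seed,
                 params = params),
            class = "trajectory")
}

#' Write / read a chemostatic feeding record
#'
#' TSV columns `time, event, nA, cumulative_n`; sidecar as for
#' [write_trajectory()].
#'
#' @param record a `feeding_record`.
#' @param path output TSV path.
#' @export
write_feeding_record <- function(record, path) {
  write_tsv(as.data.frame(record), path)
  meta <- record[c("mode", "hill_order", "alpha", "nu", "chi", "eta",
                   "nR0", "nA0", "N", "seed", "end_time", "theta")]
  meta$kind <- "feeding_record"
  meta$package_version <- as.character(utils::packageVersion("stochfr"))
  meta <- meta[order(names(meta))]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feeding_record
#' @export
read_feeding_record <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(list(event_times = df$time,
                 event = factor(df$event,
                                levels = c("feed", "pair_release",
                                           "triplet_formation",
                                           "triplet_release")),
                 nA_path = df$nA, cumulative_n = df$cumulative_n,
                 end_time = meta$end_time, theta = meta$theta,
                 mode = meta$mode, hill_order = meta$hill_order,
                 alpha = meta$alpha, nu = meta$nu, chi = meta$chi,
                 eta = meta$eta, nR0 = meta$nR0, nA0 = meta$nA0,
                 N = meta$N, seed = meta$seed),
            class = "feeding_record")
}
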