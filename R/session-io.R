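# On-disk session container: a directory of plain-text files
#   meta.json    sfreq, channel labels, positions
#   data.tsv     channels x samples sensor matrix (one row per channel)
#   aux.tsv      auxiliary traces, one column per trace
#   trials.csv   trial table, one row per trial
#   ground_truth.json  planted oracle (optional)

#' Write / read a session directory
#'
#' Serializes a simulated (or assembled) session to a directory of
#' plain-text files: JSON metadata, TSV signal matrices, a CSV trial table
#' and a JSON ground-truth record.
#'
#' @param session list with `recording`, `trials` and optionally
#'   `groundTruth`, as returned by [simulateSession()].
#' @param dir target directory (created if needed).
#' @return `writeSession` returns `dir` invisibly; `readSession` returns a
#'   session list (`recording`, `trials`, `groundTruth` or NULL).
#' @examples
#' ses <- simulateSession(simulationConfig(seed = 5, sfreq = 250,
#'                                         nChannels = 6,
#'                                         nTrialsPerCondition = 2))
#' d <- file.path(tempdir(), "ses")
#' writeSession(ses, d)
#' back <- readSession(d)
#' @export
writeSession <- function(session, dir) {
  rec <- session$recording
  stopifnot(is(rec, "Recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sfreq = sfreq(rec),
               channel_labels = channelLabels(rec),
               channel_positions = apply(channelPositions(rec), 1,
                                         as.list, simplify = FALSE),
               position_columns = colnames(channelPositions(rec)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(sensorData(rec), file.path(dir, "data.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  aux <- rec@aux
  if (length(aux))
    utils::write.table(as.data.frame(aux), file.path(dir, "aux.tsv"),
                       sep = "\t", row.names = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(session$groundTruth)) {
    gt <- session$groundTruth
    jsonlite::write_json(
      list(r_times = gt@rTimes, t_times = gt@tTimes,
           effect_sensors = gt@effectSensors,
           effect_window = gt@effectWindow,
           blink_intervals = gt@blinkIntervals),
      file.path(dir, "ground_truth.json"), digits = NA)
  }
  invisible(dir)
}

#' @rdname writeSession
#' @export
readSession <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  labels <- as.character(meta$channel_labels)
  nCh <- length(labels)
  pos <- if (nCh) {
    p <- do.call(rbind, lapply(meta$channel_positions, function(r)
      unlist(r[meta$position_columns])))
    colnames(p) <- meta$position_columns
    rownames(p) <- labels
    p
  } else matrix(numeric(0), 0, 5)
  dataPath <- file.path(dir, "data.tsv")
  dat <- if (nCh && file.exists(dataPath) && file.size(dataPath) > 0) {
    as.matrix(utils::read.table(dataPath, sep = "\t"))
  } else matrix(numeric(0), nrow = 0, ncol = 0)
  dimnames(dat) <- NULL
  auxPath <- file.path(dir, "aux.tsv")
  aux <- if (file.exists(auxPath)) {
    df <- utils::read.table(auxPath, sep = "\t", header = TRUE,
                            check.names = FALSE)
    lapply(as.list(df), as.numeric)
  } else list()
  if (nrow(dat) == 0 && length(aux))
    dat <- matrix(numeric(0), nrow = 0, ncol = length(aux[[1]]))
  rec <- new("Recording", data = dat, sfreq = meta$sfreq,
             channelLabels = labels, channelPositions = pos, aux = aux)
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  gtPath <- file.path(dir, "ground_truth.json")
  gt <- NULL
  if (file.exists(gtPath)) {
    g <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
    bi <- g$blink_intervals
    bi <- if (length(bi)) matrix(as.numeric(unlist(bi)), ncol = 2)
          else matrix(numeric(0), ncol = 2)
    gt <- new("GroundTruth", rTimes = as.numeric(g$r_times),
              tTimes = as.numeric(g$t_times),
              effectSensors = as.character(unlist(g$effect_sensors)),
              effectWindow = as.numeric(g$effect_window),
              blinkIntervals = bi)
  }
  list(recording = rec, trials = trials, groundTruth = gt)
}

#' Write a cardiac-events peak table as CSV
#'
#' @param events a [CardiacEvents-class] object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(events, path) {
  df <- data.frame(beat = seq_along(rTimes(events)),
                   r_time = rTimes(events), t_time = tTimes(events),
                   valid = validBeats(events),
                   reason = exclusionReasons(events))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
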