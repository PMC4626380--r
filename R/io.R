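#' Plain-text cohort interchange format
#'
#' A cohort on disk is a directory with, per subject, a pressure waveform
#' CSV (`<id>_pressure.csv`), an optional flow waveform CSV
#' (`<id>_flow.csv`) — both two columns `t_s,value`, one beat per file —
#' and a metadata JSON (`<id>.json`) with keys `id`, `age`, `sex`,
#' `height_cm`, `bmi`, `map_mmHg`, `dbp_mmHg` and optionally `cfpwv_ms`
#' and `ed_s`. A `manifest.csv` links ids to files, and
#' `ground_truth.csv` (written for simulated cohorts) carries the
#' generator truth. Values are written with 10 significant digits.
#'
#' @param beat a beat object.
#' @param path file path.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_waveform_csv <- function(beat, path) {
  df <- data.frame(t_s = sprintf("%.10g", beat_time(beat)),
                   value = sprintf("%.10g", beat$samples))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @param type `"pressure"` or `"flow"`; decides the beat class.
#' @param ed optional ejection duration (s) to attach.
#' @export
read_waveform_csv <- function(path, type = c("pressure", "flow"), ed = NULL) {
  type <- match.arg(type)
  df <- utils::read.csv(path)
  if (!all(c("t_s", "value") %in% names(df)))
    validation_error(sprintf("%s: expected columns t_s,value", path))
  dts <- diff(df$t_s)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1])
    validation_error(sprintf("%s: sampling is not uniform", path))
  if (type == "pressure") pressure_beat(df$value, dts[1], ed = ed)
  else flow_beat(df$value, dts[1], ed = ed)
}

#' @rdname cohort_io
#' @param cohort a `cohort` object from [simulate_cohort()].
#' @param dir directory to write into (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    pf <- paste0(s$id, "_pressure.csv")
    qf <- if (!is.null(s$flow)) paste0(s$id, "_flow.csv") else NA_character_
    mf <- paste0(s$id, ".json")
    write_waveform_csv(s$pressure, file.path(dir, pf))
    if (!is.na(qf)) write_waveform_csv(s$flow, file.path(dir, qf))
    meta <- list(id = s$id, age = s$age, sex = s$sex,
                 height_cm = s$height_cm, bmi = s$bmi,
                 map_mmHg = s$map_mmHg, dbp_mmHg = s$dbp_mmHg,
                 hr_bpm = s$hr_bpm, cfpwv_ms = s$cfpwv_ms)
    if (!is.null(s$flow) && !is.null(s$flow$ed)) meta$ed_s <- s$flow$ed
    jsonlite::write_json(meta, file.path(dir, mf),
                         auto_unbox = TRUE, digits = NA)
    data.frame(id = s$id, pressure_file = pf, flow_file = qf,
               metadata_file = mf, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path))
    validation_error(sprintf("no manifest.csv under %s", dir))
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    meta <- jsonlite::read_json(file.path(dir, man$metadata_file[i]),
                                simplifyVector = TRUE)
    ed <- meta$ed_s
    s <- list(
      id = meta$id, age = meta$age, sex = meta$sex,
      height_cm = meta$height_cm, bmi = meta$bmi,
      map_mmHg = meta$map_mmHg, dbp_mmHg = meta$dbp_mmHg,
      hr_bpm = meta$hr_bpm, cfpwv_ms = meta$cfpwv_ms,
      pressure = read_waveform_csv(file.path(dir, man$pressure_file[i]),
                                   "pressure"),
      flow = if (!is.na(man$flow_file[i]))
        read_waveform_csv(file.path(dir, man$flow_file[i]), "flow", ed = ed)
    )
    class(s) <- "subject_record"
    s
  })
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt_path))
    truth <- utils::read.csv(gt_path, stringsAsFactors = FALSE)
  structure(list(subjects = subjects, truth = truth, config = NULL),
            class = "cohort")
}
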