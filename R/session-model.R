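# Session data model: containers, validation, and on-disk round-trip.
#
# A session bundles everything one behavioral imaging experiment produces:
# the trial event table, the lick raster, per-channel ROI fluorescence with
# frame timestamps, an optional passive-stimulus log, and an optional pupil
# landmark table. All analysis stages consume this container.

PUPIL_MARKERS <- c(
  "eye_medial", "eye_lateral", "eye_superior", "eye_inferior",
  paste0("pupil_", 1:8)
)

TRIAL_COLUMNS <- c(
  "trial_id", "trial_type", "side", "contrast", "tone_time", "stim_on",
  "stim_off", "response", "correct", "reward_time", "airpuff_time"
)

#' Construct a fluorescence set
#'
#' An ROI-by-frame matrix of raw fluorescence or \eqn{\Delta F/F} with its
#' frame timestamps, acquisition channel and per-ROI pixel counts.
#'
#' @param values numeric matrix, ROI x frame.
#' @param frame_times numeric vector of frame timestamps (s), strictly
#'   increasing, one per column of `values`.
#' @param channel `"green"` or `"red"`.
#' @param roi_pixels integer vector of pixels per ROI (used as merge
#'   weights); recycled if length 1.
#' @param kind `"raw_F"` or `"dff"`.
#' @return An object of class `fluorescence_set`.
#' @export
fluorescence_set <- function(values, frame_times,
                             channel = c("green", "red"),
                             roi_pixels = 1L,
                             kind = c("raw_F", "dff")) {
  channel <- match.arg(channel)
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (length(roi_pixels) == 1L) roi_pixels <- rep(roi_pixels, nrow(values))
  structure(
    list(
      values = values,
      frame_times = as.numeric(frame_times),
      channel = channel,
      roi_pixels = as.integer(roi_pixels),
      kind = kind
    ),
    class = "fluorescence_set"
  )
}

#' @export
print.fluorescence_set <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_set> %d ROI x %d frames, channel=%s, kind=%s\n",
    nrow(x$values), ncol(x$values), x$channel, x$kind
  ))
  invisible(x)
}

#' Construct a session record
#'
#' @param trials data.frame with columns `trial_id, trial_type, side,
#'   contrast, tone_time, stim_on, stim_off, response, correct, reward_time,
#'   airpuff_time` (reward/airpuff times `NA` where absent).
#' @param licks numeric vector of lick timestamps (s), sorted ascending.
#' @param fluorescence named list of [fluorescence_set()] objects keyed by
#'   channel (`green`, optionally `red`).
#' @param stimuli optional passive-stimulus log: data.frame with columns
#'   `onset, direction, position_index`.
#' @param pupil optional per-frame pupil landmark table (see
#'   [save_session()] for the column layout).
#' @param duration session length in seconds; inferred from the data when
#'   `NULL`.
#' @return An object of class `session_record`.
#' @export
session_record <- function(trials, licks, fluorescence,
                           stimuli = NULL, pupil = NULL, duration = NULL) {
  trials <- as.data.frame(trials)
  if (is.null(duration)) {
    cand <- c(
      trials$stim_off, licks,
      vapply(fluorescence, function(f) max(f$frame_times), numeric(1)),
      if (!is.null(stimuli)) stimuli$onset + 1 else numeric(0)
    )
    duration <- if (length(cand)) max(cand, na.rm = TRUE) else 0
  }
  structure(
    list(
      trials = trials,
      licks = as.numeric(licks),
      fluorescence = fluorescence,
      stimuli = stimuli,
      pupil = pupil,
      duration = duration
    ),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> %d trials, %d licks, %.1f s, channels: %s\n",
    nrow(x$trials), length(x$licks), x$duration,
    paste(names(x$fluorescence), collapse = ", ")
  ))
  invisible(x)
}

#' Validate a session record
#'
#' Checks every structural invariant of the data model and returns the list
#' of violations (empty for a valid session). Reporting only; never throws.
#'
#' Invariants checked: per-trial event ordering (tone < stim_on < stim_off),
#' time-ordered non-overlapping trials, reward time present iff the trial is
#' a correct go, airpuff time present iff it is an incorrect no-go, contrast
#' in (0, 1], strictly increasing lick times within the session, strictly
#' increasing approximately uniform frame clocks, positive ROI pixel counts,
#' consistent matrix dimensions, and sorted stimulus onsets.
#'
#' @param session a `session_record`.
#' @return character vector of violation messages, `character(0)` if valid.
#' @export
validate_session <- function(session) {
  v <- character(0)
  tr <- session$trials

  missing_cols <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing_cols)) {
    return(sprintf(
      "TrialTable: missing column(s) %s",
      paste(missing_cols, collapse = ", ")
    ))
  }

  bad <- which(!(tr$tone_time < tr$stim_on & tr$stim_on < tr$stim_off))
  for (i in bad) {
    v <- c(v, sprintf(
      "TrialTable: trial_id %s violates tone_time < stim_on < stim_off",
      tr$trial_id[i]
    ))
  }
  if (nrow(tr) > 1L) {
    ov <- which(tr$tone_time[-1L] < tr$stim_off[-nrow(tr)])
    for (i in ov) {
      v <- c(v, sprintf(
        "TrialTable: trial_id %s overlaps trial_id %s",
        tr$trial_id[i], tr$trial_id[i + 1L]
      ))
    }
    if (is.unsorted(tr$tone_time, strictly = TRUE)) {
      v <- c(v, "TrialTable: trials not time-ordered")
    }
  }
  is_go <- tr$trial_type == "go"
  want_reward <- is_go & tr$correct
  bad <- which(want_reward != !is.na(tr$reward_time))
  for (i in bad) {
    v <- c(v, sprintf(
      "TrialTable: trial_id %s: reward_time must be present iff go & correct",
      tr$trial_id[i]
    ))
  }
  want_puff <- !is_go & !tr$correct
  bad <- which(want_puff != !is.na(tr$airpuff_time))
  for (i in bad) {
    v <- c(v, sprintf(
      "TrialTable: trial_id %s: airpuff_time must be present iff nogo & incorrect",
      tr$trial_id[i]
    ))
  }
  bad <- which(!(tr$contrast > 0 & tr$contrast <= 1))
  for (i in bad) {
    v <- c(v, sprintf(
      "TrialTable: trial_id %s: contrast outside (0,1]", tr$trial_id[i]
    ))
  }
  if (!all(tr$trial_type %in% c("go", "nogo"))) {
    v <- c(v, "TrialTable: trial_type outside {go, nogo}")
  }
  if (!all(tr$response %in% c("lick", "no_lick"))) {
    v <- c(v, "TrialTable: response outside {lick, no_lick}")
  }

  lk <- session$licks
  if (length(lk) > 1L && is.unsorted(lk, strictly = TRUE)) {
    v <- c(v, "LickRaster: lick_times not strictly increasing")
  }
  if (length(lk) && (min(lk) < 0 || max(lk) > session$duration)) {
    v <- c(v, "LickRaster: lick outside session duration")
  }

  for (ch in names(session$fluorescence)) {
    f <- session$fluorescence[[ch]]
    lab <- sprintf("FluorescenceSet[%s]", ch)
    if (ncol(f$values) != length(f$frame_times)) {
      v <- c(v, sprintf("%s: values/frame_times dimension mismatch", lab))
      next
    }
    if (nrow(f$values) != length(f$roi_pixels)) {
      v <- c(v, sprintf("%s: values/roi_pixels dimension mismatch", lab))
    }
    if (length(f$frame_times) > 1L) {
      d <- diff(f$frame_times)
      if (any(d <= 0)) {
        v <- c(v, sprintf("%s: frame_times not strictly increasing", lab))
      } else if (max(d) > 2 * stats::median(d)) {
        v <- c(v, sprintf("%s: frame clock not approximately uniform", lab))
      }
    }
    if (any(f$roi_pixels < 1L)) {
      v <- c(v, sprintf("%s: roi_pixels < 1", lab))
    }
    if (!f$kind %in% c("raw_F", "dff")) {
      v <- c(v, sprintf("%s: unknown kind '%s'", lab, f$kind))
    }
  }

  st <- session$stimuli
  if (!is.null(st)) {
    if (is.unsorted(st$onset)) v <- c(v, "StimulusLog: onsets not sorted")
    if (any(st$direction < 0 | st$direction >= 360)) {
      v <- c(v, "StimulusLog: direction outside [0,360)")
    }
  }

  v
}

.stop_if_invalid <- function(session) {
  v <- validate_session(session)
  if (length(v)) {
    stop("invalid session:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(session)
}

#' Save a session to disk
#'
#' Writes `trials.csv`, `licks.csv`, optionally `stimuli.csv` and
#' `pupil.csv`, and an HDF5 container `traces.h5` with one group per
#' channel (`/green`, `/red`), each holding datasets `values` (ROI x
#' frame), `frame_times` and `roi_pixels` plus a `kind` attribute. Missing
#' values are written as empty CSV fields. [load_session()] inverts the
#' write bit-for-bit for integers and strings and to double precision for
#' floats.
#'
#' @param session a valid `session_record`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named character vector of files written.
#' @export
save_session <- function(session, out_dir) {
  .stop_if_invalid(session)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  files <- c(
    trials = file.path(out_dir, "trials.csv"),
    licks = file.path(out_dir, "licks.csv"),
    traces = file.path(out_dir, "traces.h5")
  )
  # doubles are written with 17 significant digits so the CSV round-trip is
  # bit-exact; missing values become empty fields
  fmt <- function(df) {
    for (col in names(df)) {
      if (is.double(df[[col]])) {
        df[[col]] <- ifelse(is.na(df[[col]]), NA, sprintf("%.17g", df[[col]]))
      }
    }
    df
  }
  utils::write.csv(fmt(session$trials[TRIAL_COLUMNS]), files[["trials"]],
    row.names = FALSE, na = ""
  )
  utils::write.csv(fmt(data.frame(lick_time = session$licks)),
    files[["licks"]],
    row.names = FALSE
  )
  if (!is.null(session$stimuli)) {
    files[["stimuli"]] <- file.path(out_dir, "stimuli.csv")
    utils::write.csv(
      fmt(session$stimuli[c("onset", "direction", "position_index")]),
      files[["stimuli"]],
      row.names = FALSE, na = ""
    )
  }
  if (!is.null(session$pupil)) {
    files[["pupil"]] <- file.path(out_dir, "pupil.csv")
    utils::write.csv(fmt(session$pupil), files[["pupil"]],
      row.names = FALSE, na = ""
    )
  }

  h5 <- files[["traces"]]
  if (file.exists(h5)) file.remove(h5)
  rhdf5::h5createFile(h5)
  for (ch in names(session$fluorescence)) {
    f <- session$fluorescence[[ch]]
    grp <- paste0("/", ch)
    rhdf5::h5createGroup(h5, grp)
    rhdf5::h5write(f$values, h5, paste0(grp, "/values"))
    rhdf5::h5write(f$frame_times, h5, paste0(grp, "/frame_times"))
    rhdf5::h5write(f$roi_pixels, h5, paste0(grp, "/roi_pixels"))
    fid <- rhdf5::H5Fopen(h5)
    gid <- rhdf5::H5Gopen(fid, grp)
    rhdf5::h5writeAttribute(f$kind, gid, "kind")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  invisible(files)
}

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf(
      "%s (%s): missing column(s) %s",
      what, basename(path), paste(missing_cols, collapse = ", ")
    ))
  }
  df
}

#' Load a session from disk
#'
#' Reads the files written by [save_session()] from a directory and returns
#' a validated `session_record`. A schema mismatch raises an error naming
#' the offending column; an invariant violation raises an error naming the
#' offending trial or component.
#'
#' @param dir directory containing `trials.csv`, `licks.csv`, `traces.h5`
#'   and optionally `stimuli.csv` / `pupil.csv`.
#' @return a validated `session_record`.
#' @export
load_session <- function(dir) {
  trials <- .read_csv_checked(
    file.path(dir, "trials.csv"), TRIAL_COLUMNS, "trial table"
  )
  trials$correct <- as.logical(trials$correct)
  for (col in c("reward_time", "airpuff_time")) {
    trials[[col]] <- as.numeric(trials[[col]])
  }
  licks <- .read_csv_checked(
    file.path(dir, "licks.csv"), "lick_time", "lick raster"
  )$lick_time

  h5 <- file.path(dir, "traces.h5")
  if (!file.exists(h5)) stop("missing file: ", h5)
  ls <- rhdf5::h5ls(h5)
  groups <- ls$name[ls$otype == "H5I_GROUP" & ls$group == "/"]
  fl <- list()
  for (ch in intersect(c("green", "red"), groups)) {
    grp <- paste0("/", ch)
    values <- as.matrix(rhdf5::h5read(h5, paste0(grp, "/values")))
    attrs <- rhdf5::h5readAttributes(h5, grp)
    fl[[ch]] <- fluorescence_set(
      values = values,
      frame_times = as.numeric(rhdf5::h5read(h5, paste0(grp, "/frame_times"))),
      channel = ch,
      roi_pixels = as.integer(rhdf5::h5read(h5, paste0(grp, "/roi_pixels"))),
      kind = as.character(attrs$kind)
    )
  }
  rhdf5::h5closeAll()

  stimuli <- NULL
  if (file.exists(file.path(dir, "stimuli.csv"))) {
    stimuli <- .read_csv_checked(
      file.path(dir, "stimuli.csv"),
      c("onset", "direction", "position_index"), "stimulus log"
    )
  }
  pupil <- NULL
  if (file.exists(file.path(dir, "pupil.csv"))) {
    pupil <- .read_csv_checked(
      file.path(dir, "pupil.csv"), "frame_time", "pupil landmark table"
    )
  }

  session <- session_record(
    trials = trials, licks = licks, fluorescence = fl,
    stimuli = stimuli, pupil = pupil
  )
  .stop_if_invalid(session)
  session
}
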