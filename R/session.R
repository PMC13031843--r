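#' Cortical region vocabulary
#'
#' The eight simultaneously imaged dorsal-cortex regions: anterior lateral
#' motor cortex (ALM), anterior/posterior primary motor cortex (M1a, M1p),
#' secondary motor cortex (M2), forelimb and vibrissal primary somatosensory
#' cortex (S1fl, vS1), retrosplenial cortex (RSC) and posterior parietal
#' cortex (PPC).
#'
#' @export
CORTEX_REGIONS <- c("ALM", "M1a", "M1p", "M2", "S1fl", "vS1", "RSC", "PPC")

DISTRACTOR_LEVELS <- c("none", "early", "middle", "late")
SIDE_LEVELS <- c("left", "right")
OUTCOME_LEVELS <- c("correct", "incorrect", "no_response")
EPOCH_NAMES <- c("stimulus", "delay", "early_delay", "late_delay", "action",
                 "iti_window", "trial_window")

#' Construct a trial table
#'
#' One row per trial. `onset_frame` is the 0-based frame index of stimulus
#' onset. Distractors, when present, occur 1 s (early), 2 s (middle) or 3 s
#' (late) after delay onset. A `no_response` outcome implies `choice_side ==
#' "none"`.
#'
#' @param onset_frame integer vector, strictly increasing, 0-based.
#' @param stimulus_side "left" or "right".
#' @param choice_side "left", "right" or "none".
#' @param outcome "correct", "incorrect" or "no_response".
#' @param distractor "none", "early", "middle" or "late".
#' @return data.frame with the five validated columns.
#' @export
trial_table <- function(onset_frame, stimulus_side, choice_side, outcome,
                        distractor) {
  tr <- data.frame(onset_frame = as.integer(onset_frame),
                   stimulus_side = as.character(stimulus_side),
                   choice_side = as.character(choice_side),
                   outcome = as.character(outcome),
                   distractor = as.character(distractor),
                   stringsAsFactors = FALSE)
  validate_trials(tr)
  tr
}

validate_trials <- function(tr) {
  stopifnot(is.data.frame(tr))
  need <- c("onset_frame", "stimulus_side", "choice_side", "outcome",
            "distractor")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tr) > 1 && any(diff(tr$onset_frame) <= 0))
    stop("trial onset frames must be strictly increasing")
  bad <- function(col, levels)
    if (!all(tr[[col]] %in% levels))
      stop("invalid value in trial column '", col, "': ",
           paste(unique(setdiff(tr[[col]], levels)), collapse = ", "))
  bad("stimulus_side", SIDE_LEVELS)
  bad("choice_side", c(SIDE_LEVELS, "none"))
  bad("outcome", OUTCOME_LEVELS)
  bad("distractor", DISTRACTOR_LEVELS)
  nr <- tr$outcome == "no_response"
  if (any(tr$choice_side[nr] != "none"))
    stop("no_response trials must have choice_side == 'none'")
  invisible(tr)
}

#' Construct a recording session
#'
#' The universal container for one imaging session: a neurons-by-frames
#' activity matrix (z-scored deconvolved event amplitudes), a region label
#' per neuron, the frame rate and the trial table.
#'
#' @param activity numeric matrix, neurons x frames; all values finite.
#' @param region character/factor of length `nrow(activity)` with values in
#'   [CORTEX_REGIONS].
#' @param frame_rate_hz acquisition rate in Hz (~9.35 for the emulated rig).
#' @param trials trial table (see [trial_table()]).
#' @param cohort_tag "control", "reduced_connectivity" or "other".
#' @param check if `TRUE`, verify that the recording spans at least
#'   \[−5 s, +9 s\] around every trial onset.
#' @return object of class `cortex_session`.
#' @export
session <- function(activity, region, frame_rate_hz, trials,
                    cohort_tag = "other", check = TRUE) {
  activity <- as.matrix(activity)
  if (nrow(activity) > 0 && !all(is.finite(activity)))
    stop("activity contains non-finite values")
  region <- as.character(region)
  if (length(region) != nrow(activity))
    stop("need exactly one region label per neuron")
  if (!all(region %in% CORTEX_REGIONS))
    stop("unknown region label(s): ",
         paste(unique(setdiff(region, CORTEX_REGIONS)), collapse = ", "))
  stopifnot(is.numeric(frame_rate_hz), frame_rate_hz > 0)
  validate_trials(trials)
  if (!cohort_tag %in% c("control", "reduced_connectivity", "other"))
    stop("cohort_tag must be control, reduced_connectivity or other")
  s <- structure(list(activity = activity, region = region,
                      frame_rate_hz = frame_rate_hz, trials = trials,
                      cohort_tag = cohort_tag),
                 class = "cortex_session")
  if (check && nrow(trials) > 0) {
    lo <- sec_to_frame(-5, frame_rate_hz) + trials$onset_frame[1]
    hi <- sec_to_frame(9, frame_rate_hz) + trials$onset_frame[nrow(trials)]
    if (lo < 0 || hi > ncol(activity))
      stop("recording does not span [-5 s, +9 s] around every trial onset")
  }
  s
}

#' @export
print.cortex_session <- function(x, ...) {
  cat(sprintf("<cortex_session> %d neurons x %d frames @ %.2f Hz, %d trials, cohort=%s\n",
              nrow(x$activity), ncol(x$activity), x$frame_rate_hz,
              nrow(x$trials), x$cohort_tag))
  invisible(x)
}

# floor-based second -> frame-offset conversion (0-based frames)
sec_to_frame <- function(t_sec, rate) as.integer(floor(t_sec * rate))

#' Frame interval of a task epoch
#'
#' Converts an epoch name into a 0-based, half-open `[start, end)` frame
#' interval for one trial. Time origin t = 0 is stimulus onset; the epochs
#' are stimulus \[0,1) s, delay \[1,5) s (early \[1,3), late \[3,5)), action
#' \[5,9) s, the inter-trial window \[−5,−1) s and the trial window \[−1,7) s.
#' Frames are computed as `floor(t * frame_rate) + onset_frame`.
#'
#' @param session a `cortex_session`.
#' @param trial trial row index, or a one-row trial data.frame.
#' @param epoch one of `r paste(EPOCH_NAMES, collapse=", ")`.
#' @return integer vector `c(start, end)`, half-open.
#' @export
epoch_frames <- function(session, trial, epoch) {
  epoch <- match.arg(epoch, EPOCH_NAMES)
  onset <- if (is.data.frame(trial)) trial$onset_frame[1]
           else session$trials$onset_frame[trial]
  lim <- switch(epoch,
                stimulus     = c(0, 1),
                delay        = c(1, 5),
                early_delay  = c(1, 3),
                late_delay   = c(3, 5),
                action       = c(5, 9),
                iti_window   = c(-5, -1),
                trial_window = c(-1, 7))
  iv <- sec_to_frame(lim, session$frame_rate_hz) + onset
  if (iv[1] < 0 || iv[2] > ncol(session$activity))
    stop("epoch interval [", iv[1], ",", iv[2], ") exceeds recording bounds")
  iv
}

#' Frames of an epoch concatenated over trials
#'
#' @param session a `cortex_session`.
#' @param epoch epoch name (see [epoch_frames()]).
#' @param trials trial row indices (default all).
#' @return 1-based frame indices into the activity matrix, concatenated in
#'   trial order.
#' @export
epoch_frames_all <- function(session, epoch, trials = seq_len(nrow(session$trials))) {
  unlist(lapply(trials, function(i) {
    iv <- epoch_frames(session, i, epoch)
    seq.int(iv[1] + 1L, iv[2])
  }), use.names = FALSE)
}

#' Write a session to an HDF5 container
#'
#' Stores `/activity`, `/region_of`, `/frame_rate` and the trial table
#' (group `/trials`) in one HDF5 file, with the cohort tag as a root
#' attribute; the trial table is additionally mirrored as a sibling CSV
#' (`<path>.trials.csv`).
#'
#' @param session a `cortex_session`.
#' @param path output file path (`.h5`).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "cortex_session"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(session$activity, path, "activity")
  rhdf5::h5write(session$region, path, "region_of")
  rhdf5::h5write(session$frame_rate_hz, path, "frame_rate")
  rhdf5::h5createGroup(path, "trials")
  for (col in names(session$trials))
    rhdf5::h5write(session$trials[[col]], path, paste0("trials/", col))
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(session$cohort_tag, fid, "cohort_tag")
  rhdf5::H5Fclose(fid)
  utils::write.csv(session$trials, paste0(path, ".trials.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a session from an HDF5 container
#'
#' Inverse of [write_session()]: `read_session(write_session(s, p))` is the
#' identity on all fields. Rejects containers with missing datasets, region
#' labels outside the eight-name vocabulary, non-finite activity, or invalid
#' trial fields (each with a named-field error).
#'
#' @param path HDF5 file written by [write_session()].
#' @return a `cortex_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  have <- file.path(ifelse(ls$group == "/", "", ls$group), ls$name)
  have <- sub("^/", "", sub("^//", "", have))
  for (need in c("activity", "region_of", "frame_rate"))
    if (!need %in% have) stop("missing dataset '", need, "' in ", path)
  act <- rhdf5::h5read(path, "activity")
  if (length(act) == 0) act <- matrix(numeric(0), nrow = 0, ncol = ncol(act))
  reg <- as.character(rhdf5::h5read(path, "region_of"))
  rate <- as.numeric(rhdf5::h5read(path, "frame_rate"))
  tr <- as.data.frame(lapply(
    c("onset_frame", "stimulus_side", "choice_side", "outcome", "distractor"),
    function(col) {
      v <- rhdf5::h5read(path, paste0("trials/", col))
      if (col == "onset_frame") as.integer(v) else as.character(v)
    }))
  names(tr) <- c("onset_frame", "stimulus_side", "choice_side", "outcome",
                 "distractor")
  fid <- rhdf5::H5Fopen(path)
  tag <- rhdf5::h5readAttributes(fid, "/")$cohort_tag
  rhdf5::H5Fclose(fid)
  if (is.null(tag)) tag <- "other"
  session(act, reg, rate, tr, cohort_tag = as.character(tag), check = FALSE)
}

#' Read a trial table from CSV
#'
#' Validates fields on load; an unknown tag (e.g. a distractor label outside
#' none/early/middle/late) raises an error naming the offending column.
#'
#' @param path CSV with columns onset_frame, stimulus_side, choice_side,
#'   outcome, distractor.
#' @return validated trial data.frame.
#' @export
read_trial_table <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(tr)
  tr
}
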