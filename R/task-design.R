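#' Trial condition labels
#'
#' The five discrete trial types of the control task.  The `cognitive`
#' condition is an eye-movement trial in the eye-movement variant and a
#' working-memory trial in the working-memory variant; `null` trials are
#' fixation-only and serve as the implicit GLM baseline.
#'
#' @param active If `TRUE`, return only the four active (non-null)
#'   conditions.
#' @return Character vector of condition labels.
#' @examples
#' trialConditions()
#' trialConditions(active = TRUE)
#' @export
trialConditions <- function(active = FALSE) {
  conds <- c("auditory", "visual", "motor", "cognitive", "null")
  if (active) conds[conds != "null"] else conds
}

#' Stimulus-parameter metadata for the control task
#'
#' Immutable description of the audiovisual stimuli used by each trial
#' type: the six pure tones of the auditory trials (musical pitches C4,
#' D4, E4, F4, A4, B4), the drifting sine-wave grating of the visual
#' trials, the three button-press cues of the motor trials, and the two
#' cognitive variants (six-position saccade targets on an 8.75 degree
#' circle, or a 4-letter working-memory probe with 50% match rate).
#' These values are presentation metadata only; no stimulus rendering is
#' performed by this package.
#'
#' @return A named list of stimulus parameters.
#' @examples
#' stimulusParams()$tone_frequencies_hz
#' @export
stimulusParams <- function() {
  list(
    tone_frequencies_hz = c(261.63, 293.66, 329.63, 349.23, 440, 493.88),
    tone_duration_s = 0.5,
    grating_spatial_freq_cpd = 1.2,
    grating_drift_cps = 6,
    grating_reversal_s = 0.5,
    motor_cue_count = 3L,
    motor_cue_duration_s = 1,
    eye_target_radius_deg = 8.75,
    eye_target_count = 6L,
    eye_target_duration_s = 0.5,
    wm_string_length = 4L,
    wm_match_proportion = 0.5
  )
}

# Canonical pseudo-random condition sequence shared by both variants.
# The original task's standardized order is not recoverable, so one
# canonical permutation is generated from a fixed seed under the
# constraint that no condition occurs more than 3 times in a row, and
# shipped as the standardized forward order.
canonicalEnv <- new.env(parent = emptyenv())

canonicalSequence <- function() {
  if (is.null(canonicalEnv$seq)) {
    canonicalEnv$seq <- withSeed(1103L, {
      repeat {
        s <- sample(rep(trialConditions(), each = 20L))
        if (max(rle(s)$lengths) <= 3L) break
      }
      s
    })
  }
  canonicalEnv$seq
}

#' Generate a task-variant trial schedule
#'
#' Builds the trial schedule for one run: 100 back-to-back 3 s trials
#' (20 per condition, null included) in a standardized pseudo-random
#' order, followed by a 10 s buffer (310 s total).  The forward order is a
#' fixed canonical permutation (identical across calls); the reversed
#' order is its exact reversal.  Both variants share the same sequence;
#' they differ only in what the `cognitive` trials contain.
#'
#' @param variant `"eye-movement"` or `"working-memory"`.
#' @param order `"forward"` or `"reversed"`.
#' @return An [EventSchedule-class] object.
#' @examples
#' sch <- generateSchedule("eye-movement", "forward")
#' table(trials(sch)$condition)
#' runDuration(sch)
#' @export
generateSchedule <- function(variant = c("eye-movement", "working-memory"),
                             order = c("forward", "reversed")) {
  variant <- match.arg(variant)
  order <- match.arg(order)
  conds <- canonicalSequence()
  if (order == "reversed") conds <- rev(conds)
  new("EventSchedule", variant = variant, order = order,
      trials = data.frame(onset = seq(0, 297, by = 3), duration = 3,
                          condition = conds, stringsAsFactors = FALSE),
      buffer = 10)
}

#' Serialize a trial schedule to event files
#'
#' Writes a schedule either as a single BIDS `events.tsv` (columns
#' `onset`, `duration`, `trial_type`) or as FSL 3-column EV text files,
#' one per active condition (onset, duration, weight 1).  Null trials are
#' never written as a regressor file: they form the implicit baseline.
#'
#' @param schedule An [EventSchedule-class].
#' @param dir Output directory (created if absent).
#' @param dialect `"bids_events_tsv"` or `"fsl_ev3col"`.
#' @return Character vector of written file paths, invisibly.
#' @seealso [readEvents()] for the BIDS round-trip.
#' @examples
#' d <- tempfile(); sch <- generateSchedule()
#' writeEvents(sch, d, "fsl_ev3col")
#' list.files(d)
#' @export
writeEvents <- function(schedule, dir,
                        dialect = c("bids_events_tsv", "fsl_ev3col")) {
  stopifnot(is(schedule, "EventSchedule"))
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("task-%s_dir-%s",
                  sub("-", "", schedule@variant), schedule@order)
  tr <- trials(schedule)
  if (dialect == "bids_events_tsv") {
    path <- file.path(dir, paste0(stem, "_events.tsv"))
    writeTsv(data.frame(onset = tr$onset, duration = tr$duration,
                        trial_type = tr$condition), path)
    paths <- path
  } else {
    paths <- vapply(trialConditions(active = TRUE), function(cond) {
      ev <- tr[tr$condition == cond, , drop = FALSE]
      path <- file.path(dir, sprintf("%s_ev-%s.txt", stem, cond))
      utils::write.table(cbind(ev$onset, ev$duration, 1),
                         path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      path
    }, character(1))
  }
  invisible(paths)
}

#' Read a BIDS events.tsv back into a trial table
#'
#' @param path Path to a tab-separated events file with columns `onset`,
#'   `duration` and `trial_type`.
#' @return A `data.frame` with columns `onset`, `duration`, `condition`.
#' @export
readEvents <- function(path) {
  ev <- readTsv(path)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(ev)))
  data.frame(onset = ev$onset, duration = ev$duration,
             condition = ev$trial_type, stringsAsFactors = FALSE)
}

#' Write the stimulus-parameter sidecar
#'
#' Serializes [stimulusParams()] as a JSON sidecar next to the event
#' files.
#'
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeStimulusParams <- function(path) {
  jsonlite::write_json(stimulusParams(), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
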