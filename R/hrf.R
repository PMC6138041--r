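#' Number of volumes covering a schedule
#'
#' Smallest number of volumes at repetition time `tr` whose total span
#' covers the schedule's duration (trials plus buffer).  The canonical
#' 310 s run at TR 2 s needs 155 volumes.
#'
#' @param schedule An [EventSchedule-class], or a single numeric duration
#'   in seconds.
#' @param tr Repetition time in seconds (> 0).
#' @return Integer volume count.
#' @examples
#' nVolumesFor(generateSchedule(), 2)   # 155
#' @export
nVolumesFor <- function(schedule, tr) {
  stopifnot(tr > 0)
  dur <- if (is(schedule, "EventSchedule")) runDuration(schedule)
         else if (is.data.frame(schedule))
           max(schedule$onset + schedule$duration)
         else as.numeric(schedule)
  as.integer(ceiling(dur / tr))
}

# Accept either an EventSchedule or a bare trial table.
scheduleTrials <- function(x) {
  if (is(x, "EventSchedule")) return(trials(x))
  stopifnot(is.data.frame(x),
            all(c("onset", "duration", "condition") %in% names(x)))
  x
}

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak near 5 s, undershoot
#' near 15 s, undershoot ratio 1/6), sampled at `dt` over `duration`
#' seconds and scaled to peak amplitude 1.  This is the field-standard
#' canonical HRF used to convolve trial boxcars into BOLD regressors.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param peakDelay,undershootDelay Gamma shape parameters (s; rate 1).
#' @param ratio Undershoot-to-peak amplitude ratio.
#' @param duration Kernel support in seconds (>= 32 recommended).
#' @return Numeric kernel with attribute `"times"` (sampling times in s).
#' @examples
#' h <- doubleGammaHrf(0.1)
#' attr(h, "times")[which.max(h)]   # peak near 5 s
#' @export
doubleGammaHrf <- function(dt, peakDelay = 6, undershootDelay = 16,
                           ratio = 1 / 6, duration = 32) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peakDelay, rate = 1) -
    ratio * stats::dgamma(t, shape = undershootDelay, rate = 1)
  h <- h / max(h)
  structure(h, times = t)
}

#' HRF-convolved condition regressor
#'
#' Builds the BOLD regressor for one active condition: a unit boxcar over
#' the condition's trials on a fine 0.1 s grid, convolved with the
#' canonical double-gamma HRF and resampled at the volume acquisition
#' times `0, tr, 2*tr, ...`.  Null trials are the implicit baseline and
#' have no regressor.
#'
#' @param schedule An [EventSchedule-class], or a trial `data.frame` with
#'   columns `onset`, `duration`, `condition`.
#' @param condition An active condition label.
#' @param tr Repetition time in seconds.
#' @param nVolumes Number of volumes; defaults to [nVolumesFor()].
#' @param dt Fine-grid step in seconds.
#' @return Numeric vector of length `nVolumes`.
#' @export
conditionRegressor <- function(schedule, condition, tr,
                               nVolumes = nVolumesFor(schedule, tr),
                               dt = 0.1) {
  if (condition == "null")
    stop("null trials are the implicit baseline and have no regressor")
  if (!condition %in% trialConditions(active = TRUE))
    stop("unknown condition '", condition, "'")
  ev <- scheduleTrials(schedule)
  ev <- ev[ev$condition == condition, , drop = FALSE]
  tEnd <- (nVolumes - 1) * tr
  fine <- seq(0, tEnd + dt, by = dt)
  box <- numeric(length(fine))
  for (i in seq_len(nrow(ev))) {
    on <- fine >= ev$onset[i] & fine < ev$onset[i] + ev$duration[i]
    box[on] <- 1
  }
  h <- doubleGammaHrf(dt)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(fine)] * dt
  stats::approx(fine, conv, xout = (seq_len(nVolumes) - 1) * tr,
                rule = 2)$y
}
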