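# Trapezoidal nanosecond pulse trains. A train is a list of phases, each a
# trapezoid (linear rise, flat plateau, linear fall) with a signed amplitude
# in V/m; the electrode voltage is field * electrode_spacing.

#' Single trapezoidal pulse phase
#'
#' @param start_time Time at which the rise begins (s).
#' @param plateau_duration Duration of the flat top (s), >= 0. Note the
#'   conventional "pulse duration" is the full width at half maximum,
#'   `plateau_duration + (rise_time + fall_time)/2`.
#' @param rise_time,fall_time Linear ramp times (s), > 0.
#' @param amplitude Signed plateau field (V/m); the sign encodes polarity.
#' @return An object of class `pulse_phase`.
#' @export
pulse_phase <- function(start_time, plateau_duration, rise_time, fall_time,
                        amplitude) {
  if (rise_time <= 0 || fall_time <= 0) stop("rise and fall times must be > 0")
  if (plateau_duration < 0) stop("plateau_duration must be >= 0")
  structure(list(start_time = start_time,
                 plateau_duration = plateau_duration,
                 rise_time = rise_time, fall_time = fall_time,
                 amplitude = amplitude),
            class = "pulse_phase")
}

phase_end <- function(ph) ph$start_time + ph$rise_time + ph$plateau_duration + ph$fall_time

#' Trapezoidal pulse train
#'
#' @param phases List of [pulse_phase()] objects, time-sorted and
#'   non-overlapping.
#' @param electrode_spacing Distance between the parallel electrodes (m);
#'   electrode voltage is field times this spacing.
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(phases, electrode_spacing = 100e-6) {
  stopifnot(length(phases) >= 1, all(vapply(phases, inherits, TRUE, "pulse_phase")))
  starts <- vapply(phases, `[[`, 0, "start_time")
  ends <- vapply(phases, phase_end, 0)
  o <- order(starts)
  phases <- phases[o]; starts <- starts[o]; ends <- ends[o]
  if (length(phases) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("pulse phases must not overlap in time")
  structure(list(phases = phases, electrode_spacing = electrode_spacing),
            class = "pulse_train")
}

#' Standard nanosecond pulse stimuli
#'
#' The four trapezoidal nsPEF stimuli used throughout the package, all with
#' 1 ns rise and fall times and equal nominal power density
#' (amplitude^2 x duration):
#' \describe{
#'   \item{`p3ns`}{3 ns at 18.3 kV/cm (183 V across 100 um).}
#'   \item{`p10ns`}{10 ns at 10 kV/cm (100 V across 100 um).}
#'   \item{`p5ns_bipolar`}{two 5 ns phases of opposite polarity at 10 kV/cm,
#'     separated by a 6 ns interval.}
#'   \item{`p5ns_unipolar_pair`}{two 5 ns phases of equal polarity at
#'     10 kV/cm, separated by a 6 ns interval.}
#' }
#' Pulse durations are full width at half maximum, so the plateau of an
#' `n`-ns pulse lasts `n - 1` ns. The interval is the gap between the end of
#' one phase's fall and the start of the next phase's rise (`interval`
#' argument exposes the convention).
#'
#' @param name One of `"p3ns"`, `"p10ns"`, `"p5ns_bipolar"`,
#'   `"p5ns_unipolar_pair"`.
#' @param electrode_spacing Electrode spacing (m), default 100 um.
#' @param interval Gap between phases for the two-phase stimuli (s).
#' @return A [pulse_train()].
#' @export
standard_pulse <- function(name = c("p10ns", "p3ns", "p5ns_bipolar",
                                    "p5ns_unipolar_pair"),
                           electrode_spacing = 100e-6,
                           interval = 6e-9) {
  name <- match.arg(name)
  tr <- 1e-9
  trap <- function(t0, dur, amp)
    pulse_phase(t0, plateau_duration = dur - tr, rise_time = tr,
                fall_time = tr, amplitude = amp)
  phases <- switch(name,
    p3ns = list(trap(0, 3e-9, 1.83e6)),
    p10ns = list(trap(0, 10e-9, 1.0e6)),
    p5ns_bipolar = {
      p1 <- trap(0, 5e-9, 1.0e6)
      list(p1, trap(phase_end(p1) + interval, 5e-9, -1.0e6))
    },
    p5ns_unipolar_pair = {
      p1 <- trap(0, 5e-9, 1.0e6)
      list(p1, trap(phase_end(p1) + interval, 5e-9, 1.0e6))
    })
  pulse_train(phases, electrode_spacing)
}

#' Evaluate a pulse train
#'
#' Piecewise-linear evaluation of the applied field and electrode voltage.
#'
#' @param train A [pulse_train()].
#' @param t Time(s) at which to evaluate (s); vectorized.
#' @return A data frame with columns `t`, `field` (V/m) and `voltage` (V).
#' @export
evaluate_pulse <- function(train, t) {
  stopifnot(inherits(train, "pulse_train"), all(is.finite(t)))
  E <- pulse_field(train, t)
  data.frame(t = t, field = E, voltage = E * train$electrode_spacing)
}

#' Applied field of a pulse train at given times
#'
#' @inheritParams evaluate_pulse
#' @return Numeric vector of applied field values (V/m).
#' @export
pulse_field <- function(train, t) {
  E <- numeric(length(t))
  for (ph in train$phases) {
    tl <- t - ph$start_time
    r <- ph$rise_time; p <- ph$plateau_duration; f <- ph$fall_time
    up <- pmin(pmax(tl / r, 0), 1)
    down <- pmin(pmax((tl - r - p) / f, 0), 1)
    E <- E + ph$amplitude * (up - down)
  }
  E
}

#' Nominal duration of a pulse train phase set
#'
#' Sum over phases of |amplitude|^2 x FWHM duration, the nominal power
#' density metric used to match stimuli of different shapes.
#' @param train A [pulse_train()].
#' @return Scalar, (V/m)^2 * s.
#' @export
pulse_energy_metric <- function(train) {
  sum(vapply(train$phases, function(ph)
    ph$amplitude^2 * (ph$plateau_duration + (ph$rise_time + ph$fall_time) / 2),
    0))
}

#' End time of the last phase of a pulse train
#' @param train A [pulse_train()].
#' @return Time (s) at which the last fall completes.
#' @export
pulse_end_time <- function(train) max(vapply(train$phases, phase_end, 0))

#' Default simulation horizon for a pulse train
#'
#' Last phase end plus a 10 ns tail so post-pulse relaxation (for example the
#' polarization peak after the fall) is captured.
#' @param train A [pulse_train()].
#' @return Time (s).
#' @export
pulse_horizon <- function(train) pulse_end_time(train) + 10e-9

#' Export a sampled waveform to delimited text
#'
#' @param train A [pulse_train()].
#' @param path Output file (tab-separated: `t`, `field`, `voltage`).
#' @param dt Sampling step (s).
#' @param t_end End of the sampled window (s); defaults to [pulse_horizon()].
#' @return `path`, invisibly.
#' @export
write_pulse_train <- function(train, path, dt = 0.05e-9,
                              t_end = pulse_horizon(train)) {
  tt <- seq(0, t_end, by = dt)
  utils::write.table(evaluate_pulse(train, tt), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("Pulse train: %d phase(s), electrode spacing %g um\n",
              length(x$phases), x$electrode_spacing * 1e6))
  for (ph in x$phases)
    cat(sprintf("  t0 %6.2f ns  rise %g ns  plateau %g ns  fall %g ns  amp %+.3g kV/cm\n",
                ph$start_time * 1e9, ph$rise_time * 1e9,
                ph$plateau_duration * 1e9, ph$fall_time * 1e9,
                ph$amplitude / 1e5))
  invisible(x)
}
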