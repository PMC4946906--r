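# Behavioural and metabolic metrics: pure table-in / value-out formulas.

#' Pre-pulse inhibition (PPI)
#'
#' `(1 - mean(prepulse response) / mean(startle response)) x 100`, one
#' value per pre-pulse level. Trials are typed by the stimulus: a 120 dB
#' startle pulse alone, or the same pulse preceded by a 74, 78 or 82 dB
#' pre-pulse.
#'
#' @param session data.frame with columns `type` (one of
#'   `"startle_120dB"`, `"prepulse_74dB"`, `"prepulse_78dB"`,
#'   `"prepulse_82dB"`) and `response` (startle magnitude, arbitrary
#'   force units).
#' @param levels pre-pulse levels (dB) to report.
#' @return named numeric vector of percent inhibition, one per level; at
#'   most 100 (complete inhibition), negative when the pre-pulse
#'   facilitates the response.
#' @examples
#' s <- data.frame(type = c("startle_120dB", "startle_120dB", "prepulse_74dB"),
#'                 response = c(100, 100, 50))
#' ppi(s, levels = 74)
#' @export
ppi <- function(session, levels = c(74, 78, 82)) {
  stopifnot(is.data.frame(session),
            all(c("type", "response") %in% names(session)))
  if (!all(is.finite(session$response)))
    stop("responses must be finite", call. = FALSE)
  startle <- session$response[session$type == "startle_120dB"]
  if (length(startle) == 0)
    stop("at least one 'startle_120dB' trial is required", call. = FALSE)
  ms <- mean(startle)
  if (ms == 0)
    stop("mean startle response is 0; PPI undefined", call. = FALSE)
  out <- vapply(levels, function(lv) {
    tp <- sprintf("prepulse_%ddB", lv)
    pp <- session$response[session$type == tp]
    if (length(pp) == 0)
      stop(sprintf("no '%s' trials present", tp), call. = FALSE)
    (1 - mean(pp) / ms) * 100
  }, numeric(1))
  names(out) <- sprintf("%ddB", levels)
  out
}

#' Resting metabolic rate from a fasting calorimetry trace
#'
#' Mean of the two lowest energy-expenditure values whose timestamps fall
#' in the half-open window (4 to 8 hours after fast start by default).
#'
#' @param trace data.frame with columns `time` (hours since fast start,
#'   strictly increasing) and `energy_expenditure` (kcal/h).
#' @param window numeric length-2 half-open window `[from, to)` in hours.
#' @return RMR in kcal/h.
#' @examples
#' tr <- data.frame(time = c(4.5, 5, 6, 7), energy_expenditure = c(5, 4, 6, 3))
#' resting_metabolic_rate(tr)  # mean of 3 and 4
#' @export
resting_metabolic_rate <- function(trace, window = c(4, 8)) {
  stopifnot(is.data.frame(trace),
            all(c("time", "energy_expenditure") %in% names(trace)))
  if (is.unsorted(trace$time, strictly = TRUE))
    stop("'time' must be strictly increasing", call. = FALSE)
  inside <- trace$time >= window[1] & trace$time < window[2]
  vals <- trace$energy_expenditure[inside]
  if (length(vals) < 2)
    stop("need at least 2 samples inside the window", call. = FALSE)
  mean(sort(vals)[1:2])
}

#' Repetitive nose-poke runs in a hole-board sequence
#'
#' Number of maximal runs of identical consecutive hole identifiers with
#' run length >= 2 ("continuously poking the same hole no less than
#' twice"). With `distinct = TRUE` the number of distinct holes that
#' received at least one such run is returned instead.
#'
#' @param seq_holes integer/character vector of hole identifiers in poke
#'   order (1-16 on a standard 16-hole board).
#' @param distinct count distinct holes rather than runs (default FALSE).
#' @param n_holes board size for identifier validation (default 16); set
#'   `NULL` to skip validation (e.g. for labelled holes).
#' @return integer count.
#' @examples
#' repetitive_poke_runs(c(1, 1, 2, 3, 2, 2, 2, 1, 1))  # 3 runs
#' repetitive_poke_runs(c(1, 1, 2, 1, 1), distinct = TRUE)  # hole 1 only
#' @export
repetitive_poke_runs <- function(seq_holes, distinct = FALSE, n_holes = 16) {
  if (length(seq_holes) == 0) return(0L)
  if (!is.null(n_holes) && is.numeric(seq_holes) &&
      any(seq_holes < 1 | seq_holes > n_holes))
    stop(sprintf("hole identifiers must lie in 1..%d", n_holes),
         call. = FALSE)
  r <- rle(as.character(seq_holes))
  rep_holes <- r$values[r$lengths >= 2]
  if (distinct) length(unique(rep_holes)) else length(rep_holes)
}

#' Foot slips normalised to distance travelled
#'
#' @param footfalls number of foot slips observed.
#' @param distance total distance travelled, metres (> 0).
#' @return slips per metre.
#' @export
footslips_per_distance <- function(footfalls, distance) {
  stopifnot_scalar(footfalls, "footfalls", nonneg = TRUE)
  if (!is.numeric(distance) || length(distance) != 1 || distance <= 0)
    stop("'distance' must be > 0", call. = FALSE)
  footfalls / distance
}

#' Synaptic charge transfer over a recording window
#'
#' Trapezoidal integral of the deviation of a clamp current from its
#' baseline over `[0, duration)` seconds; pA x s = pC. Absolute deviation
#' by default so inward/outward conventions do not flip the sign;
#' `signed = TRUE` preserves direction.
#'
#' @param trace data.frame with columns `time` (s, uniform sampling) and
#'   `current` (pA); optional `baseline` column or scalar via the
#'   `baseline` argument (default 0).
#' @param duration integration window in seconds (default 120).
#' @param baseline holding/baseline current in pA when no column present.
#' @param signed integrate the signed deviation (default FALSE).
#' @return charge in pC.
#' @examples
#' tr <- data.frame(time = seq(0, 120, by = 0.1), current = 10)
#' charge_transfer(tr)  # 1200 pC
#' @export
charge_transfer <- function(trace, duration = 120, baseline = 0,
                            signed = FALSE) {
  stopifnot(is.data.frame(trace),
            all(c("time", "current") %in% names(trace)))
  if (max(trace$time) < duration)
    stop(sprintf("trace covers only %.3f s of the %.0f s window",
                 max(trace$time), duration), call. = FALSE)
  if ("baseline" %in% names(trace)) baseline <- trace$baseline
  keep <- trace$time <= duration
  t <- trace$time[keep]
  dev <- trace$current[keep] - if (length(baseline) > 1) baseline[keep] else baseline
  if (!signed) dev <- abs(dev)
  sum(diff(t) * (dev[-1] + dev[-length(dev)]) / 2)
}
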