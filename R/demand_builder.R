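#' Demanded activation for a repeated-sprint test
#'
#' Detects sprint intervals in a 1 Hz energy series and builds the
#' step-function intent signal: during every detected sprint the demand
#' equals the peak energy of the *first* sprint (the athlete keeps trying
#' to match their fresh maximal effort even as later sprints fall short),
#' and zero during recoveries.
#'
#' An interval counts as a sprint when the energy exceeds
#' `threshold_frac` of the session maximum for at least `min_len`
#' consecutive seconds; single-second dips below the threshold inside an
#' effort do not end it (one-bin exit hysteresis). Because the measured
#' energy responds to intent with a one-sample delay (the demand over
#' second `k` shapes the sample at `k + 1`), each detected interval is
#' shifted `intent_lead` bins earlier: the decision to sprint precedes
#' the speed change it causes.
#'
#' @param energy Data frame with columns `t` (1 s grid) and `energy` (J),
#'   e.g. from [speed_to_energy()].
#' @param threshold_frac Sprint detection threshold as a fraction of the
#'   session maximum energy (default 0.4).
#' @param min_len Minimum sprint duration in seconds (default 2).
#' @param intent_lead Bins by which intent precedes the measured response
#'   (default 1).
#' @return A [demand_profile()] on the same grid, unit `"J"`.
#' @export
sprint_test_demand <- function(energy, threshold_frac = 0.4, min_len = 2L,
                               intent_lead = 1L) {
  stopifnot(is.data.frame(energy), all(c("t", "energy") %in% names(energy)))
  e <- energy$energy
  thr <- threshold_frac * max(e)
  above <- e >= thr
  # one-bin hysteresis: bridge single-second dips between above-runs
  n <- length(above)
  if (n >= 3L) {
    dip <- which(!above & c(FALSE, above[-n])[seq_len(n)] &
                   c(above[-1], FALSE))
    above[dip] <- TRUE
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) {
    stop(sprintf(
      "no interval exceeds %.0f%% of the session maximum for >= %d s: no sprint detected",
      100 * threshold_frac, min_len), call. = FALSE)
  }
  starts <- starts[keep]
  ends <- ends[keep]
  plateau <- max(e[starts[1]:ends[1]])
  starts <- pmax(starts - intent_lead, 1L)
  ends <- pmax(ends - intent_lead, starts)
  mad <- numeric(length(e))
  for (j in seq_along(starts)) mad[starts[j]:ends[j]] <- plateau
  demand_profile(mad, times = energy$t, unit = "J")
}

#' Demanded activation for match play
#'
#' Match intent is not observable, so the measured energy series is
#' segmented into alternating monotone runs between tolerance-filtered
#' local extrema, and the demand anticipates each run's destination: on a
#' rising run the demand equals the upcoming local maximum from the run's
#' start, on a falling run the upcoming local minimum. Fluctuations
#' smaller than `tol_frac` of the session's energy range are treated as
#' sensor chatter, not extrema.
#'
#' @param energy Data frame with columns `t` and `energy` on a 1 s grid.
#' @param tol_frac Extremum tolerance as a fraction of the energy range
#'   (default 0.05).
#' @return A [demand_profile()] on the same grid.
#' @examples
#' e <- data.frame(t = 0:6, energy = c(0, 200, 800, 1800, 1800, 800, 200))
#' match_demand(e)$values # 1800 x4, then 200 x3
#' @export
match_demand <- function(energy, tol_frac = 0.05) {
  stopifnot(is.data.frame(energy), all(c("t", "energy") %in% names(energy)))
  v <- energy$energy
  n <- length(v)
  rng <- max(v) - min(v)
  if (n < 2L || rng == 0) {
    return(demand_profile(rep(v[n], n), times = energy$t, unit = "J"))
  }
  tol <- tol_frac * rng
  # first significant departure from the initial value fixes the direction
  i0 <- which(abs(v - v[1]) >= tol)[1]
  if (is.na(i0)) {
    return(demand_profile(rep(v[n], n), times = energy$t, unit = "J"))
  }
  dir <- sign(v[i0] - v[1])
  seg <- v[1:i0]
  ext_i <- if (dir > 0) which.max(seg) else which.min(seg)
  ext_v <- v[ext_i]
  turns <- integer(0)
  for (i in i0:n) {
    if (dir > 0) {
      if (v[i] > ext_v) {
        ext_i <- i; ext_v <- v[i]
      } else if (v[i] <= ext_v - tol) {
        turns <- c(turns, ext_i); dir <- -1; ext_i <- i; ext_v <- v[i]
      }
    } else {
      if (v[i] < ext_v) {
        ext_i <- i; ext_v <- v[i]
      } else if (v[i] >= ext_v + tol) {
        turns <- c(turns, ext_i); dir <- 1; ext_i <- i; ext_v <- v[i]
      }
    }
  }
  mad <- numeric(n)
  lo <- 1L
  for (tp in turns) {
    mad[lo:tp] <- v[tp]
    lo <- tp + 1L
  }
  if (lo <= n) mad[lo:n] <- v[n]
  demand_profile(mad, times = energy$t, unit = "J")
}

#' Constant demand profile
#'
#' Flat intent at a fixed level, the analogue of a sustained maximal
#' contraction (e.g. the hand-grip benchmark) when `level` equals the
#' capacity.
#'
#' @param level Demand level (>= 0) in the working unit.
#' @param duration Duration in whole seconds (> 0); the profile has
#'   `duration + 1` grid points.
#' @param unit Unit label (default `"J"`).
#' @return A [demand_profile()].
#' @export
constant_demand <- function(level, duration, unit = "J") {
  stopifnot(level >= 0, duration > 0)
  demand_profile(rep(level, duration + 1), unit = unit)
}

#' Stepped drill demand profile from segment specifications
#'
#' Builds a square-wave speed-unit profile from a list of drill segments.
#' Each segment must give a `duration` (s) and either a `distance` (m) —
#' in which case the plateau speed is `distance / duration` converted to
#' km/h — or an explicit `speed` (km/h). The default segments reproduce a
#' one-minute soccer drill: three 5 s sprint efforts (21.2 m with changes
#' of direction) separated by 5 s recoveries, then 10 s linear striding
#' (40 m), 10 s slalom (28 m) and 10 s shuttle runs (20 m + 20 m).
#'
#' @param segments List of lists with fields `duration` and one of
#'   `distance`/`speed`. `NULL` selects the default one-minute drill.
#' @param unit Unit label (default `"km/h"`).
#' @return A [demand_profile()].
#' @examples
#' drill_profile(list(list(duration = 10, distance = 40)))$values[1] # 14.4
#' @export
drill_profile <- function(segments = NULL, unit = "km/h") {
  if (is.null(segments)) {
    sprint <- list(duration = 5, distance = 21.2)
    rest <- list(duration = 5, speed = 0)
    segments <- list(sprint, rest, sprint, rest, sprint, rest,
                     list(duration = 10, distance = 40),
                     list(duration = 10, distance = 28),
                     list(duration = 10, distance = 40))
  }
  if (!is.list(segments) || length(segments) == 0L) {
    stop("segment list must be non-empty", call. = FALSE)
  }
  vals <- numeric(0)
  for (sg in segments) {
    if (is.null(sg$duration) || sg$duration <= 0 ||
        abs(sg$duration - round(sg$duration)) > 1e-9) {
      stop("each segment needs a positive whole-second duration",
           call. = FALSE)
    }
    has_d <- !is.null(sg$distance)
    has_s <- !is.null(sg$speed)
    if (has_d == has_s) {
      stop("each segment needs exactly one of distance or speed",
           call. = FALSE)
    }
    sp <- if (has_d) sg$distance / sg$duration * 3.6 else sg$speed
    if (sp < 0) stop("segment speed must be non-negative", call. = FALSE)
    vals <- c(vals, rep(sp, sg$duration))
  }
  demand_profile(c(vals, vals[length(vals)]), unit = unit)
}

#' Read / write demand profiles as CSV
#'
#' The interchange format has header `t,mad,unit`.
#'
#' @param demand A [demand_profile()].
#' @param path File path.
#' @return `write_demand_csv` returns `path` invisibly;
#'   `read_demand_csv` returns a [demand_profile()].
#' @export
write_demand_csv <- function(demand, path) {
  stopifnot(inherits(demand, "demand_profile"))
  write.csv(as.data.frame(demand), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_demand_csv
#' @export
read_demand_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("t", "mad"), names(df))
  if (length(miss)) {
    stop(sprintf("demand CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  unit <- if ("unit" %in% names(df)) df$unit[1] else "J"
  demand_profile(df$mad, times = df$t, unit = unit)
}
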