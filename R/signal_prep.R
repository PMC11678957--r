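#' Read a raw wearable speed trace from CSV
#'
#' Expects the header `timestamp,speed,latitude,longitude`. Timestamps may
#' be numeric seconds or ISO-8601 strings; the format is auto-detected and
#' recorded in the `timestamp_format` attribute. Times are normalised to
#' seconds from session start; latitude/longitude are carried through
#' untouched (they play no role in the model).
#'
#' @param path CSV file path.
#' @return A data frame with columns `t` (s from start), `speed` (m/s),
#'   `latitude`, `longitude`, plus attributes `timestamp_format` and
#'   `nominal_rate`.
#' @export
read_speed_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "speed")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("input CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ts <- suppressWarnings(as.numeric(df$timestamp))
  if (anyNA(ts)) {
    parsed <- as.POSIXct(df$timestamp, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(parsed)) {
      stop("timestamp column is neither numeric seconds nor ISO-8601",
           call. = FALSE)
    }
    ts <- as.numeric(parsed)
    fmt <- "iso8601"
  } else {
    fmt <- "seconds"
  }
  if (is.unsorted(ts)) stop("timestamps must be non-decreasing", call. = FALSE)
  if (any(!is.finite(df$speed)) || any(df$speed < 0)) {
    stop("speed must be finite and non-negative", call. = FALSE)
  }
  out <- data.frame(t = ts - ts[1], speed = df$speed,
                    latitude = if ("latitude" %in% names(df)) df$latitude else NA_real_,
                    longitude = if ("longitude" %in% names(df)) df$longitude else NA_real_)
  attr(out, "timestamp_format") <- fmt
  attr(out, "nominal_rate") <- 18
  out
}

#' Smooth a high-rate speed trace to a 1 Hz grid
#'
#' Averages raw speeds within half-open one-second bins `[k, k + 1)`
#' anchored at the first timestamp. Bins that contain no samples (sensor
#' dropouts) carry the previous bin's value forward and are flagged.
#'
#' @param raw Data frame with columns `t` (seconds from start) and `speed`
#'   (m/s), e.g. from [read_speed_csv()].
#' @return Data frame with columns `t` (0, 1, ... s), `speed` (bin means)
#'   and `gap` (logical fill flag). The number of rows equals the session
#'   duration rounded up to whole seconds.
#' @export
smooth_to_1hz <- function(raw) {
  stopifnot(is.data.frame(raw), all(c("t", "speed") %in% names(raw)))
  if (nrow(raw) == 0L) stop("raw series is empty", call. = FALSE)
  if (any(!is.finite(raw$speed)) || any(raw$speed < 0)) {
    stop("speed must be finite and non-negative", call. = FALSE)
  }
  trel <- raw$t - raw$t[1]
  b <- floor(trel + 1e-9)
  nb <- as.integer(max(b)) + 1L
  cnt <- tabulate(b + 1L, nbins = nb)
  if (cnt[1] == 0L) stop("no samples in the first one-second window",
                         call. = FALSE)
  sums <- numeric(nb)
  agg <- rowsum(raw$speed, group = b, reorder = TRUE)
  sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  speed <- ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_)
  gap <- cnt == 0L
  # carry the previous value across empty windows
  for (i in which(gap)) speed[i] <- speed[i - 1L]
  data.frame(t = seq_len(nb) - 1, speed = speed, gap = gap)
}

#' Convert a speed series to kinetic energy
#'
#' Pointwise \eqn{E = \tfrac{1}{2} m v^2}: the working quantity of the
#' athlete-facing model, making efforts comparable across body masses.
#'
#' @param speed Either a numeric vector of speeds (m/s) or a data frame
#'   with columns `t` and `speed` (e.g. from [smooth_to_1hz()]).
#' @param mass Body mass in kg (> 0).
#' @return If `speed` is a data frame, a data frame with columns `t`,
#'   `energy` (J) and any `gap` column carried through, with attribute
#'   `mass`; otherwise a numeric vector of energies.
#' @examples
#' speed_to_energy(5, mass = 80) # 1000 J
#' @export
speed_to_energy <- function(speed, mass) {
  stopifnot(is.numeric(mass), length(mass) == 1L, is.finite(mass), mass > 0)
  if (is.data.frame(speed)) {
    v <- speed$speed
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("speed must be finite and non-negative", call. = FALSE)
    }
    out <- data.frame(t = speed$t, energy = mass * v^2 / 2)
    if ("gap" %in% names(speed)) out$gap <- speed$gap
    attr(out, "mass") <- mass
    attr(out, "unit") <- "J"
    out
  } else {
    if (any(!is.finite(speed)) || any(speed < 0)) {
      stop("speed must be finite and non-negative", call. = FALSE)
    }
    mass * speed^2 / 2
  }
}

#' Total motor-unit capacity from mass and maximal speed
#'
#' The athlete's maximal energy reservoir. The default convention is peak
#' kinetic energy \eqn{\tfrac{1}{2} m v_{max}^2}, which keeps the capacity
#' on the same scale as the measured energy series; `mv2` drops the 1/2
#' factor.
#'
#' @param mass Body mass, kg (> 0).
#' @param vmax Maximal speed, m/s (>= 0).
#' @param formula `"half_mv2"` (default) or `"mv2"`.
#' @return Capacity in joules.
#' @examples
#' compute_m0(80, 9.14) # about 3342 J
#' @export
compute_m0 <- function(mass, vmax, formula = c("half_mv2", "mv2")) {
  formula <- match.arg(formula)
  stopifnot(mass > 0, vmax >= 0)
  if (formula == "half_mv2") mass * vmax^2 / 2 else mass * vmax^2
}

#' Write a smoothed 1 Hz session to CSV
#'
#' Header `t,speed,energy,gap_flag`.
#'
#' @param smoothed Output of [smooth_to_1hz()].
#' @param mass Body mass in kg used for the energy column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(smoothed, mass, path) {
  en <- speed_to_energy(smoothed, mass)
  write.csv(data.frame(t = smoothed$t, speed = smoothed$speed,
                       energy = en$energy,
                       gap_flag = as.integer(smoothed$gap)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
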