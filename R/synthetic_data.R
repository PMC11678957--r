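#' Generate a synthetic repeated-sprint session with known ground truth
#'
#' Emulates the wearable record of a 10-effort repeated-sprint test:
#' a stepped demanded-activation profile (5 s lead-in rest, then cycles of
#' `work_s` seconds at the demand level and rest to complete each cycle)
#' is forward-simulated with known parameters, the whole-second activation
#' energies are converted back to speed with the athlete's capacity
#' convention, and the speed is emitted at `rate_hz` by zero-order hold
#' with multiplicative Gaussian measurement noise. With zero noise the
#' round trip through smoothing, energy conversion and re-simulation is
#' exact by construction.
#'
#' @param athlete An [athlete_profile()]. Default: 80 kg, 9.14 m/s.
#' @param true_params Generating [model_parameters()]. The defaults
#'   (alpha_a 4e-4, beta_d 1.2e-3, F 1.5e-2, R 1.9e-2, all inside the
#'   calibration bounds) give an athlete who attains the demanded level
#'   within a few seconds of each effort — the near-rectangular energy
#'   plateaus a repeated-sprint test is designed to elicit — while
#'   accumulating enough fatigue that later efforts fall visibly short.
#' @param n_sprints Number of efforts (default 10).
#' @param work_s,rest_s Effort and recovery durations in seconds
#'   (default 15/15, giving a 300 s session).
#' @param demand_level Demand plateau in J; default `0.8 * m0`
#'   (repeated-sprint pacing at about 90\% of maximal speed, sustainable
#'   across ten efforts).
#' @param noise_sd_fraction Relative s.d. of multiplicative speed noise at
#'   the sensor rate (default 0.02).
#' @param noise_type `"multiplicative"` (default) or `"additive"`
#'   (absolute s.d. `noise_sd_fraction * vmax`).
#' @param seed RNG seed.
#' @param rate_hz Sensor rate (default 18).
#' @return A list with `raw` (data frame `timestamp,speed,latitude,`
#'   `longitude`), `demand` (the true [demand_profile()]), `trajectory`
#'   (the generating `fatigue_trajectory`), `athlete`, `true_params`,
#'   `seed`.
#' @export
gen_sprint_session <- function(athlete = athlete_profile(80, 9.14),
                               true_params = model_parameters(
                                 4e-4, 1.2e-3, 1.5e-2, 1.9e-2),
                               n_sprints = 10L, work_s = 15L, rest_s = 15L,
                               demand_level = NULL,
                               noise_sd_fraction = 0.02,
                               noise_type = c("multiplicative", "additive"),
                               seed = 1L, rate_hz = 18L) {
  noise_type <- match.arg(noise_type)
  stopifnot(inherits(athlete, "athlete_profile"),
            inherits(true_params, "model_parameters"),
            n_sprints >= 1L, work_s >= 1L, rest_s >= 1L,
            noise_sd_fraction >= 0)
  if (is.null(demand_level)) demand_level <- 0.8 * athlete$m0
  lead <- min(5L, rest_s) # standing lead-in, borrowed from the first rest
  cycle <- work_s + rest_s
  total <- n_sprints * cycle
  mad <- numeric(total + 1L)
  for (j in seq_len(n_sprints)) {
    on <- (j - 1L) * cycle + lead
    mad[(on + 1L):(on + work_s)] <- demand_level
  }
  demand <- demand_profile(mad, unit = "J")
  traj <- simulate_fatigue(demand, true_params, athlete$m0,
                           init = list(ma = 0, mf = 0))
  ev <- traj$eval_view
  v1 <- ma_to_speed(ev$ma, athlete)
  with_seed(seed, {
    nsec <- length(v1) - 1L
    vv <- rep(v1[seq_len(nsec)], each = rate_hz)
    noise <- switch(noise_type,
      multiplicative = vv * rnorm(length(vv), 0, noise_sd_fraction),
      additive = rnorm(length(vv), 0, noise_sd_fraction * athlete$vmax))
    speed <- pmax(vv + noise, 0)
    raw <- data.frame(
      timestamp = rep(seq_len(nsec) - 1L, each = rate_hz) +
        rep(seq_len(rate_hz) - 1L, nsec) / rate_hz,
      speed = speed, latitude = 45.0, longitude = 14.0)
    list(raw = raw, demand = demand, trajectory = traj, athlete = athlete,
         true_params = true_params, seed = seed)
  })
}

# Invert the capacity convention: speed implied by an activation energy.
ma_to_speed <- function(ma, athlete) {
  if (athlete$capacity == "half_mv2") sqrt(2 * pmax(ma, 0) / athlete$mass)
  else sqrt(pmax(ma, 0) / athlete$mass)
}

#' Generate a synthetic match speed trace
#'
#' A seeded alternating-renewal (semi-Markov) process over locomotor
#' states — standing, walking, jogging, running, sprinting — with
#' state-specific target speeds and duration ranges. Within a segment the
#' speed ramps linearly from its previous value towards the target over
#' roughly two seconds and then holds with small autoregressive jitter.
#' This emulates the intermittent structure of match running; it makes no
#' claim of statistical match realism.
#'
#' @param duration_min Match duration in minutes (default 83).
#' @param athlete An [athlete_profile()] bounding the speed range.
#' @param sprint_weight Relative frequency of sprint segments
#'   (default 0.08; 0 removes sprints entirely).
#' @param seed RNG seed.
#' @param rate_hz Sensor rate (default 18).
#' @return A raw speed data frame (`timestamp,speed,latitude,longitude`).
#' @export
gen_match_session <- function(duration_min = 83, athlete = athlete_profile(80, 9.14),
                              sprint_weight = 0.08, seed = 1L, rate_hz = 18L) {
  stopifnot(duration_min > 0, sprint_weight >= 0)
  states <- data.frame(
    name = c("stand", "walk", "jog", "run", "sprint"),
    speed = c(0, 1.4, 2.9, 4.8, 0.9 * athlete$vmax),
    sd = c(0, 0.1, 0.2, 0.3, 0.3),
    dmin = c(2, 4, 4, 3, 2),
    dmax = c(10, 25, 20, 8, 6),
    w = c(0.22, 0.35, 0.25, 0.10, sprint_weight))
  n_samp <- ceiling(duration_min * 60 * rate_hz)
  dt <- 1 / rate_hz
  with_seed(seed, {
    speed <- numeric(n_samp)
    i <- 1L
    cur <- 0
    prev_state <- 1L
    while (i <= n_samp) {
      repeat {
        st <- sample.int(nrow(states), 1L, prob = states$w)
        if (st != prev_state) break
      }
      prev_state <- st
      dur <- runif(1, states$dmin[st], states$dmax[st])
      nseg <- max(1L, round(dur * rate_hz))
      target <- max(0, rnorm(1, states$speed[st], states$sd[st]))
      ramp_n <- min(nseg, 2L * rate_hz)
      seg <- numeric(nseg)
      if (ramp_n > 0) {
        seg[seq_len(ramp_n)] <- cur + (target - cur) * seq_len(ramp_n) / ramp_n
      }
      if (nseg > ramp_n) {
        jit <- stats::filter(rnorm(nseg - ramp_n, 0, 0.05), 0.8,
                             method = "recursive")
        seg[(ramp_n + 1L):nseg] <- target + as.numeric(jit)
      }
      seg <- pmin(pmax(seg, 0), athlete$vmax * 1.02)
      take <- min(nseg, n_samp - i + 1L)
      speed[i:(i + take - 1L)] <- seg[seq_len(take)]
      cur <- seg[take]
      i <- i + take
    }
    data.frame(timestamp = (seq_len(n_samp) - 1L) * dt, speed = speed,
               latitude = 45.0, longitude = 14.0)
  })
}

#' Canonical literature benchmark demand profiles
#'
#' The three protocols used to contrast the enhanced model with the
#' baseline: a sustained maximal contraction (hand-grip analogue, 60 s
#' constant demand in force units), the one-minute soccer drill square
#' wave ([drill_profile()] defaults, km/h), and a 15-minute intermittent
#' treadmill protocol (repeated 90 s cycles of walking 6 km/h, jogging
#' 12 km/h, cruising 15 km/h, a 10 s sprint at 21 km/h and a standing
#' recovery, km/h).
#'
#' @param handgrip_level Constant demand for the hand-grip analogue
#'   (default 435, force units).
#' @return Named list of [demand_profile()] objects: `handgrip`,
#'   `drill_1min`, `treadmill_15min`.
#' @export
gen_literature_protocols <- function(handgrip_level = 435) {
  cycle <- list(list(duration = 20, speed = 6),
                list(duration = 20, speed = 12),
                list(duration = 15, speed = 15),
                list(duration = 10, speed = 21),
                list(duration = 25, speed = 0))
  tread <- drill_profile(rep(cycle, 10), unit = "km/h")
  list(handgrip = constant_demand(handgrip_level, 60, unit = "N"),
       drill_1min = drill_profile(),
       treadmill_15min = tread)
}

#' Published benchmark parameter sets
#'
#' The model parameter values used for the three literature benchmark
#' protocols, for the baseline and the enhanced model respectively, in
#' each protocol's working unit (force for the hand-grip, km/h for the
#' drills).
#'
#' @return A data frame with one row per protocol/model combination.
#' @export
benchmark_parameters <- function() {
  data.frame(
    protocol = c("handgrip", "handgrip", "drill_1min", "drill_1min",
                 "treadmill_15min", "treadmill_15min"),
    model = rep(c("sns", "enhanced"), 3),
    m0 = c(435, 418.55, 20, 21.67, 27, 25),
    alpha_a = c(NA, 2.10e-2, NA, 9.90e-2, NA, 9.90),
    beta_d = c(NA, 1.04e-2, NA, 8.50e-2, NA, 9.96),
    f = c(2.45e-2, 2.40e-2, 0.05, 4.23e-2, 0.05, 9.99e-2),
    r = c(1.15e-2, 1.19e-2, 0.05, 5.79e-2, 0.05, 1.55e-2))
}

#' Write a raw speed trace to CSV
#'
#' Header `timestamp,speed,latitude,longitude`, the dialect read by
#' [read_speed_csv()].
#'
#' @param raw Data frame as produced by the generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_speed_csv <- function(raw, path) {
  stopifnot(all(c("timestamp", "speed") %in% names(raw)))
  write.csv(raw[, intersect(c("timestamp", "speed", "latitude", "longitude"),
                            names(raw))],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
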