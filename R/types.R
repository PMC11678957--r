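#' Athlete profile with derived energy capacity
#'
#' Bundles an athlete's body mass and maximal running speed and derives the
#' total motor-unit capacity `m0`, interpreted as the athlete's maximal
#' energy reservoir. By default `m0` is the peak kinetic energy
#' \eqn{\tfrac{1}{2} m v_{max}^2}, so that the capacity is directly
#' comparable to the measured kinetic-energy series produced by
#' [speed_to_energy()]; the alternative `mv2` convention (no 1/2 factor)
#' is available as a switch.
#'
#' @param mass Body mass in kg. Must be positive.
#' @param vmax Maximal running speed in m/s. Must be positive.
#' @param capacity Capacity convention, `"half_mv2"` (default) or `"mv2"`.
#' @return An object of class `athlete_profile`: a list with elements
#'   `mass`, `vmax`, `m0` (J) and `capacity`.
#' @examples
#' athlete_profile(80, 9.14) # m0 about 3342 J
#' @export
athlete_profile <- function(mass, vmax, capacity = c("half_mv2", "mv2")) {
  capacity <- match.arg(capacity)
  stopifnot(is.numeric(mass), length(mass) == 1L, is.finite(mass), mass > 0,
            is.numeric(vmax), length(vmax) == 1L, is.finite(vmax), vmax > 0)
  structure(
    list(mass = mass, vmax = vmax,
         m0 = compute_m0(mass, vmax, capacity), capacity = capacity),
    class = "athlete_profile")
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf("<athlete_profile> mass %.1f kg, vmax %.2f m/s, M0 %.1f J (%s)\n",
              x$mass, x$vmax, x$m0, x$capacity))
  invisible(x)
}

#' Rate parameters of the fatigue model
#'
#' The four per-athlete rate coefficients of the enhanced model:
#' `alpha_a` governs activation towards the demanded level while reserve
#' units are available, `beta_d` governs deactivation when demand falls
#' below the current activation, and `f`/`r` are the fatigue and recovery
#' rates (1/s) transferring capacity between the active and fatigued
#' compartments. Numeric values are used exactly as printed in the
#' protocol's working units; rate coefficients are protocol-unit dependent
#' (energy for athletes, force or speed for literature benchmarks).
#'
#' @param alpha_a Activation rate coefficient (> 0).
#' @param beta_d Deactivation rate coefficient (> 0).
#' @param f Fatigue rate, 1/s (> 0).
#' @param r Recovery rate, 1/s (> 0).
#' @return An object of class `model_parameters`.
#' @examples
#' model_parameters(1.5e-4, 1.17e-3, 7.39e-2, 1.91e-2)
#' @export
model_parameters <- function(alpha_a, beta_d, f, r) {
  vals <- c(alpha_a = alpha_a, beta_d = beta_d, f = f, r = r)
  if (!all(is.finite(vals)) || alpha_a <= 0 || beta_d <= 0 || f < 0 || r < 0) {
    stop(paste("activation/deactivation rates must be strictly positive,",
               "fatigue/recovery rates non-negative"), call. = FALSE)
  }
  structure(list(alpha_a = alpha_a, beta_d = beta_d, f = f, r = r),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf(
    "<model_parameters> alpha_a %.3g, beta_d %.3g, F %.3g 1/s, R %.3g 1/s\n",
    x$alpha_a, x$beta_d, x$f, x$r))
  invisible(x)
}

#' Demanded-activation profile on a 1 s grid
#'
#' A step-function intent signal: the level of activation (energy, force or
#' speed, recorded in `unit`) the athlete is trying to attain at each whole
#' second. Values are held constant across each second when the model is
#' integrated on its finer grid.
#'
#' @param values Non-negative demand levels, one per grid second.
#' @param times Optional time grid in seconds; defaults to
#'   `start + 0:(length(values) - 1)`. Must be uniform with 1 s spacing.
#' @param unit Unit label carried as metadata (default `"J"`).
#' @param start Session start time in seconds when `times` is not given.
#' @return An object of class `demand_profile` with elements `times`,
#'   `values` and `unit`.
#' @export
demand_profile <- function(values, times = NULL, unit = "J", start = 0) {
  if (length(values) < 1L) stop("demand profile must be non-empty", call. = FALSE)
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("demand values must be finite and non-negative", call. = FALSE)
  }
  if (is.null(times)) times <- start + seq_along(values) - 1
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) > 1L) {
    sp <- diff(times)
    if (any(abs(sp - 1) > 1e-9)) {
      stop("demand grid spacing must be uniform at 1 s", call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit),
            class = "demand_profile")
}

#' @export
print.demand_profile <- function(x, ...) {
  cat(sprintf("<demand_profile> %d s grid, range [%.3g, %.3g] %s\n",
              length(x$values), min(x$values), max(x$values), x$unit))
  invisible(x)
}

#' @export
length.demand_profile <- function(x) length(x$values)

#' @export
as.data.frame.demand_profile <- function(x, ...) {
  data.frame(t = x$times, mad = x$values, unit = x$unit)
}

#' Parameter bounds for calibration
#'
#' Per-parameter search intervals for the optimization vector
#' (`alpha_a`, `beta_d`, `f`, `r`). The defaults are the bounds used for
#' athlete-energy protocols; literature benchmarks in force or speed units
#' operate on different numeric scales and take their own bounds.
#'
#' @param alpha_a,beta_d,f,r Length-2 numeric `c(low, high)` with
#'   `0 < low < high`.
#' @return An object of class `bounds_spec`.
#' @export
bounds_spec <- function(alpha_a = c(1e-5, 1e-3),
                        beta_d = c(1e-5, 1e-2),
                        f = c(1e-3, 1e-1),
                        r = c(1e-3, 1e-1)) {
  b <- list(alpha_a = alpha_a, beta_d = beta_d, f = f, r = r)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[1] <= 0 || v[1] >= v[2]) {
      stop(sprintf("bound for %s must be c(low, high) with 0 < low < high", nm),
           call. = FALSE)
    }
  }
  structure(b, class = "bounds_spec")
}

#' @export
print.bounds_spec <- function(x, ...) {
  cat("<bounds_spec>\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-8s [%.3g, %.3g]\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}

#' Particle swarm configuration
#'
#' Swarm size and patience follow the calibration protocol (10 particles,
#' early stop after 15 iterations without improvement); the remaining
#' hyperparameters are standard constriction-factor defaults.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param patience Iterations without strict improvement before stopping.
#' @param max_iter Hard iteration cap.
#' @param inertia,cognitive,social PSO velocity-update coefficients.
#' @param seed Integer RNG seed; `NULL` means the caller seeds.
#' @param log_scale Search in log10-transformed parameter space.
#' @param init_positions Optional matrix (swarm_size x n_par) of initial
#'   particle positions, mainly for testing.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 10L, patience = 15L, max_iter = 200L,
                       inertia = 0.7298, cognitive = 1.49618,
                       social = 1.49618, seed = NULL, log_scale = FALSE,
                       init_positions = NULL) {
  stopifnot(swarm_size >= 2L, patience >= 1L, max_iter >= 1L)
  structure(list(swarm_size = as.integer(swarm_size),
                 patience = as.integer(patience),
                 max_iter = as.integer(max_iter),
                 inertia = inertia, cognitive = cognitive, social = social,
                 seed = seed, log_scale = isTRUE(log_scale),
                 init_positions = init_positions),
            class = "pso_config")
}

# Run an expression with a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
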