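#' @useDynLib sprintfatigue, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif lm coef median approx
#' @importFrom utils read.csv write.csv packageVersion
NULL

new_trajectory <- function(times, ma, mf, m0, dt, n_sub, unit, model,
                           demand = NULL, stability_warning = FALSE) {
  mp <- m0 - ma - mf
  eval_idx <- seq(1L, length(times), by = n_sub)
  structure(
    list(times = times, ma = ma, mf = mf, mp = mp, m0 = m0, dt = dt,
         unit = unit, model = model,
         eval_view = data.frame(t = times[eval_idx], ma = ma[eval_idx],
                                mf = mf[eval_idx], mp = mp[eval_idx]),
         demand = demand, stability_warning = stability_warning),
    class = "fatigue_trajectory")
}

#' @export
print.fatigue_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fatigue_trajectory> [%s] %.0f s at dt = %g s, M0 = %.4g %s\n",
    x$model, max(x$times) - min(x$times), x$dt, x$m0, x$unit))
  cat(sprintf("  MA range [%.4g, %.4g], final MF %.4g, min MP %.4g\n",
              min(x$ma), max(x$ma), x$mf[length(x$mf)], min(x$mp)))
  invisible(x)
}

#' @export
as.data.frame.fatigue_trajectory <- function(x, ...) {
  data.frame(t = x$times, ma = x$ma, mf = x$mf, mp = x$mp)
}

check_dt <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive finite scalar", call. = FALSE)
  }
  n_sub <- round(1 / dt)
  if (n_sub < 1L || abs(n_sub - 1 / dt) > 1e-8) {
    stop("dt must divide the 1 s demand grid evenly", call. = FALSE)
  }
  as.integer(n_sub)
}

resolve_init <- function(init, demand, m0) {
  if (is.null(init)) {
    init <- list(ma = min(demand$values[1], m0), mf = 0)
  }
  stopifnot(is.list(init), all(c("ma", "mf") %in% names(init)))
  if (!all(is.finite(c(init$ma, init$mf)))) {
    stop("initial state must be finite", call. = FALSE)
  }
  init
}

#' Single Euler step of the enhanced fatigue model
#'
#' Advances the compartment state `(MA, MF)` by one explicit Euler step of
#' length `dt` under a demanded activation `mad`. The required change
#' \eqn{\Delta M_{AD} = M_{AD} - M_A} drives activation at rate
#' `alpha_a` scaled by the available reserve \eqn{M_P = M_0 - M_A - M_F}
#' when positive, and deactivation at rate `beta_d` scaled by \eqn{M_A}
#' when negative; fatigue transfer follows
#' \eqn{dM_F/dt = M_A F - M_F R}. After the update the reserve constraint
#' \eqn{M_0 - M_A - M_F \ge 0} is enforced (fatigue consumes active units
#' once the reserve is exhausted) and compartments are kept non-negative.
#'
#' A warning of class `sprintfatigue_stability` is raised (computation
#' proceeds) when `dt * MP * alpha_a >= 1` or `dt * MA * beta_d >= 1`,
#' the single-step overshoot bound.
#'
#' @param state List with elements `t`, `ma`, `mf`.
#' @param mad Demanded activation level (>= 0) over this step.
#' @param params A [model_parameters()] object.
#' @param m0 Total capacity in the working unit.
#' @param dt Step length in seconds.
#' @return The state list advanced by `dt`.
#' @examples
#' p <- model_parameters(2.1e-2, 1.04e-2, 2.4e-2, 1.19e-2)
#' fatigue_step(list(t = 0, ma = 0, mf = 0), mad = 418.55,
#'              params = p, m0 = 418.55, dt = 0.1)
#' @export
fatigue_step <- function(state, mad, params, m0, dt = 0.1) {
  vals <- c(state$ma, state$mf, mad, m0, dt,
            params$alpha_a, params$beta_d, params$f, params$r)
  if (!all(is.finite(vals))) stop("non-finite input to fatigue_step",
                                  call. = FALSE)
  if (mad < 0) stop("demanded activation must be non-negative", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  mp <- max(m0 - state$ma - state$mf, 0)
  if (dt * mp * params$alpha_a >= 1 || dt * state$ma * params$beta_d >= 1) {
    warning(warningCondition(
      sprintf("dt = %g is large for the activation rates (overshoot bound)",
              dt),
      class = "sprintfatigue_stability"))
  }
  delta <- mad - state$ma
  dma <- if (delta > 0) delta * mp * params$alpha_a
         else delta * state$ma * params$beta_d
  dmf <- state$ma * params$f - state$mf * params$r
  ma <- state$ma + dt * dma
  mf <- state$mf + dt * dmf
  mf <- min(max(mf, 0), m0)
  ma <- max(ma, 0)
  if (ma + mf > m0) ma <- m0 - mf
  list(t = state$t + dt, ma = ma, mf = mf)
}

#' Simulate the enhanced fatigue model over a demand profile
#'
#' Integrates the two-equation compartment model with explicit Euler steps
#' of length `dt` (default 0.1 s), holding each 1 s demand value constant
#' across its substeps (zero-order hold). The returned trajectory carries
#' the full substep series and an `eval_view` restricted to whole seconds,
#' which is the grid on which all goodness-of-fit metrics are computed.
#'
#' The default initial state activates the first demand value (capped at
#' `m0`) with no accumulated fatigue: standing starts begin at zero while
#' sustained maximal protocols begin at the demanded level.
#'
#' @param demand A [demand_profile()] (at least 2 grid points).
#' @param params A [model_parameters()] object.
#' @param m0 Total capacity in the demand's unit.
#' @param init Optional list `list(ma = , mf = )` initial state.
#' @param dt Euler step in seconds; must divide 1 s evenly.
#' @return A `fatigue_trajectory` object.
#' @examples
#' d <- constant_demand(418.55, 60, unit = "N")
#' p <- model_parameters(2.1e-2, 1.04e-2, 2.4e-2, 1.19e-2)
#' tr <- simulate_fatigue(d, p, m0 = 418.55, init = list(ma = 0, mf = 0))
#' head(tr$eval_view)
#' @export
simulate_fatigue <- function(demand, params, m0, init = NULL, dt = 0.1) {
  stopifnot(inherits(demand, "demand_profile"),
            inherits(params, "model_parameters"))
  if (length(demand$values) < 2L) {
    stop("demand profile must span at least one second", call. = FALSE)
  }
  if (!is.finite(m0) || m0 <= 0) stop("m0 must be positive", call. = FALSE)
  n_sub <- check_dt(dt)
  init <- resolve_init(init, demand, m0)
  res <- .sim_enhanced_cpp(demand$values, m0, params$alpha_a, params$beta_d,
                           params$f, params$r, n_sub, init$ma, init$mf)
  if (isTRUE(res$warn)) {
    warning(warningCondition(
      "dt is large for the activation rates at some step; results may overshoot",
      class = "sprintfatigue_stability"))
  }
  times <- demand$times[1] + dt * (seq_along(res$ma) - 1)
  new_trajectory(times, res$ma, res$mf, m0, dt, n_sub, demand$unit,
                 model = "enhanced", demand = demand,
                 stability_warning = isTRUE(res$warn))
}

#' Simulate the baseline (prior) fatigue model
#'
#' The baseline model ties the activation rate to the finite-difference
#' derivative of the demand profile: while unfatigued units suffice
#' (\eqn{M_{AD} < M_A + M_P}) the active pool tracks demand changes
#' one-for-one; when demand exceeds \eqn{M_0 - M_F} every available unit
#' is recruited. Fatigue transfer is identical to the enhanced model.
#' Activation is deliberately not clipped at zero, so the baseline's
#' documented failure under stepped demand (negative activation, i.e.
#' negative implied speed) is reproducible.
#'
#' @inheritParams simulate_fatigue
#' @param f,r Fatigue and recovery rates, 1/s.
#' @return A `fatigue_trajectory` with `model = "sns"`.
#' @export
simulate_sns <- function(demand, f, r, m0, init = NULL, dt = 0.1) {
  stopifnot(inherits(demand, "demand_profile"))
  if (length(demand$values) < 2L) {
    stop("demand profile must span at least one second", call. = FALSE)
  }
  n_sub <- check_dt(dt)
  init <- resolve_init(init, demand, m0)
  res <- .sim_sns_cpp(demand$values, m0, f, r, n_sub, init$ma, init$mf)
  times <- demand$times[1] + dt * (seq_along(res$ma) - 1)
  new_trajectory(times, res$ma, res$mf, m0, dt, n_sub, demand$unit,
                 model = "sns", demand = demand)
}

#' High-accuracy reference integration of the enhanced model
#'
#' Integrates the same vector field with classical 4th-order Runge-Kutta
#' at a fine step (default 1e-3 s), applying the same per-step constraint
#' projection as the production Euler integrator. Used as an independent
#' accuracy reference for the fixed-step solver.
#'
#' @inheritParams simulate_fatigue
#' @param dt Fine step in seconds (default `1e-3`).
#' @return A `fatigue_trajectory` with `model = "reference"`.
#' @export
simulate_reference <- function(demand, params, m0, init = NULL, dt = 1e-3) {
  stopifnot(inherits(demand, "demand_profile"),
            inherits(params, "model_parameters"))
  if (length(demand$values) < 2L) {
    stop("demand profile must span at least one second", call. = FALSE)
  }
  n_sub <- check_dt(dt)
  init <- resolve_init(init, demand, m0)
  n <- length(demand$values)
  npts <- (n - 1L) * n_sub + 1L
  ma <- numeric(npts)
  mf <- numeric(npts)
  a <- init$ma
  q <- init$mf
  ma[1] <- a
  mf[1] <- q
  deriv <- function(a, q, d) {
    mp <- max(m0 - a - q, 0)
    delta <- d - a
    dma <- if (delta > 0) delta * mp * params$alpha_a
           else delta * a * params$beta_d
    c(dma, a * params$f - q * params$r)
  }
  idx <- 2L
  for (k in seq_len(n - 1L)) {
    d <- demand$values[k]
    for (s in seq_len(n_sub)) {
      k1 <- deriv(a, q, d)
      k2 <- deriv(a + dt / 2 * k1[1], q + dt / 2 * k1[2], d)
      k3 <- deriv(a + dt / 2 * k2[1], q + dt / 2 * k2[2], d)
      k4 <- deriv(a + dt * k3[1], q + dt * k3[2], d)
      a <- a + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      q <- q + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      q <- min(max(q, 0), m0)
      a <- max(a, 0)
      if (a + q > m0) a <- m0 - q
      ma[idx] <- a
      mf[idx] <- q
      idx <- idx + 1L
    }
  }
  times <- demand$times[1] + dt * (seq_len(npts) - 1)
  new_trajectory(times, ma, mf, m0, dt, n_sub, demand$unit,
                 model = "reference", demand = demand)
}

#' Closed-form activation under constant demand without fatigue
#'
#' Analytic solution of \eqn{dM_A/dt = (D - M_A)(M_0 - M_A)\alpha_A}
#' (the activation equation with `F = R = 0` and constant demand
#' `D < M0`), a separable logistic-type ODE. Serves as an independent
#' oracle for the Euler integrator.
#'
#' @param d Constant demand level, with `ma0 <= d < m0`.
#' @param m0 Total capacity.
#' @param alpha_a Activation rate coefficient.
#' @param t Time(s) in seconds (vectorised).
#' @param ma0 Initial activation (default 0).
#' @return Activation at time `t`.
#' @export
closed_form_activation <- function(d, m0, alpha_a, t, ma0 = 0) {
  if (d >= m0) {
    stop("degenerate case d >= m0: the two roots coincide or cross",
         call. = FALSE)
  }
  if (ma0 < 0 || ma0 > d) stop("require 0 <= ma0 <= d", call. = FALSE)
  if (ma0 == d) return(rep(d, length(t)))
  c0 <- (m0 - ma0) / (d - ma0)
  q <- c0 * exp((m0 - d) * alpha_a * t)
  out <- (q * d - m0) / (q - 1)
  out[!is.finite(q)] <- d
  out
}

#' Closed-form deactivation decay to zero demand
#'
#' Solution of \eqn{dM_A/dt = -M_A^2 \beta_D} (the deactivation limb with
#' zero demand and `F = R = 0`):
#' \eqn{M_A(t) = M_A(0) / (1 + M_A(0)\,\beta_D\, t)}.
#'
#' @param ma0 Initial activation (>= 0).
#' @param beta_d Deactivation rate coefficient.
#' @param t Time(s) in seconds (vectorised).
#' @return Activation at time `t`.
#' @export
closed_form_decay <- function(ma0, beta_d, t) {
  stopifnot(ma0 >= 0)
  ma0 / (1 + ma0 * beta_d * t)
}

#' Closed-form fatigue accumulation under constant activation
#'
#' Solution of \eqn{dM_F/dt = A F - M_F R} from `MF(0) = 0` with constant
#' activation `A`: \eqn{M_F(t) = (A F / R)(1 - e^{-R t})}. With `R = 0`
#' the growth is linear, `A F t`.
#'
#' @param a Constant activation level (>= 0).
#' @param f Fatigue rate, 1/s.
#' @param r Recovery rate, 1/s (>= 0).
#' @param t Time(s) in seconds (vectorised).
#' @return Fatigued-compartment size at time `t`.
#' @export
closed_form_fatigue <- function(a, f, r, t) {
  stopifnot(a >= 0, r >= 0)
  if (r == 0) return(a * f * t)
  (a * f / r) * (1 - exp(-r * t))
}

#' Write a trajectory to CSV
#'
#' Writes the whole-second evaluation view with header `t,mad,ma,mf,mp`
#' (seconds, then the working energy/force/speed unit).
#'
#' @param trajectory A `fatigue_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "fatigue_trajectory"))
  ev <- trajectory$eval_view
  mad <- if (!is.null(trajectory$demand)) {
    trajectory$demand$values[seq_len(nrow(ev))]
  } else rep(NA_real_, nrow(ev))
  write.csv(data.frame(t = ev$t, mad = mad, ma = ev$ma, mf = ev$mf,
                       mp = ev$mp),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
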