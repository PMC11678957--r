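#' Time-averaged squared-error cost
#'
#' The calibration cost: the squared error between the model's
#' whole-second activation energies and the measured 1 Hz energies,
#' integrated over the session and divided by its duration — i.e. the
#' mean squared error over 1 s samples. The `per_minute` convention
#' divides the summed squared error by the session length in minutes
#' instead (numerically the per-second value times 60), matching the
#' reporting convention used for match tables.
#'
#' @param simulated A `fatigue_trajectory` (its `eval_view` is used) or a
#'   numeric vector already on the evaluation grid.
#' @param measured Data frame with columns `t` and `energy`, or a numeric
#'   vector of the same length as `simulated`.
#' @param normalization `"per_second"` (default) or `"per_minute"`.
#' @return Non-negative scalar cost in squared working units.
#' @examples
#' cost_epsilon(c(1, 3), c(0, 1)) # 2.5
#' @export
cost_epsilon <- function(simulated, measured,
                         normalization = c("per_second", "per_minute")) {
  normalization <- match.arg(normalization)
  al <- align_eval(simulated, measured)
  sq <- (al$sim - al$meas)^2
  eps <- mean(sq)
  if (normalization == "per_minute") eps <- sum(sq) / (length(sq) / 60)
  eps
}

# Align a simulated trajectory's whole-second view with a measured series.
align_eval <- function(simulated, measured) {
  if (inherits(simulated, "fatigue_trajectory")) {
    ev <- simulated$eval_view
    if (is.data.frame(measured)) {
      idx <- match(round(measured$t, 6), round(ev$t, 6))
      if (anyNA(idx)) {
        stop("measured grid is not a subset of the trajectory's 1 s grid",
             call. = FALSE)
      }
      list(sim = ev$ma[idx], meas = measured$energy)
    } else {
      if (length(measured) != nrow(ev)) {
        stop("measured series length does not match the evaluation grid",
             call. = FALSE)
      }
      list(sim = ev$ma, meas = as.numeric(measured))
    }
  } else {
    meas <- if (is.data.frame(measured)) measured$energy else as.numeric(measured)
    if (length(simulated) != length(meas)) {
      stop("simulated and measured series must have equal length",
           call. = FALSE)
    }
    list(sim = as.numeric(simulated), meas = meas)
  }
}

#' Coefficient of determination on the evaluation grid
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the
#' measured mean. Can be negative when the model underperforms the mean
#' predictor.
#'
#' @inheritParams cost_epsilon
#' @return Dimensionless scalar, at most 1.
#' @examples
#' r_squared(c(0, 1, 2, 5), c(0, 1, 2, 3)) # 0.2
#' @export
r_squared <- function(simulated, measured) {
  al <- align_eval(simulated, measured)
  if (length(al$meas) < 2L) stop("need at least 2 points", call. = FALSE)
  ss_tot <- sum((al$meas - mean(al$meas))^2)
  if (ss_tot == 0) {
    stop("measured series is constant: R^2 is undefined", call. = FALSE)
  }
  1 - sum((al$sim - al$meas)^2) / ss_tot
}

#' Calibrate rate parameters by particle swarm optimization
#'
#' Minimises [cost_epsilon()] between the simulated whole-second
#' activation energies and the measured series over the four rate
#' parameters within `bounds` (optionally also over the capacity, for
#' benchmark protocols where it is fitted rather than derived).
#' Global-best PSO with constriction-factor defaults; particles are
#' clamped to the bounds with the velocity zeroed on the clamped
#' coordinate; the search stops early after `config$patience` iterations
#' without strict improvement of the best cost.
#'
#' @param demand A [demand_profile()] for the session.
#' @param measured Data frame with columns `t`, `energy` on the demand's
#'   1 s grid (subset allowed).
#' @param m0 Capacity in the working unit (fixed unless `fit_m0`).
#' @param bounds A [bounds_spec()].
#' @param config A [pso_config()]; `config$seed` makes the run
#'   reproducible.
#' @param normalization Cost normalisation, see [cost_epsilon()].
#' @param init Optional initial state passed to [simulate_fatigue()].
#' @param fit_m0 Also search the capacity (requires `m0_bounds`).
#' @param m0_bounds Length-2 capacity bounds when `fit_m0 = TRUE`.
#' @param run_index Bookkeeping index recorded in the result.
#' @return An object of class `fit_result`: fitted [model_parameters()],
#'   `m0`, cost `epsilon`, `r2`, evaluation count `n_eval`, iteration
#'   count `n_iter`, `seed` and `run_index`.
#' @export
fit_pso <- function(demand, measured, m0, bounds = bounds_spec(),
                    config = pso_config(),
                    normalization = c("per_second", "per_minute"),
                    init = NULL, fit_m0 = FALSE, m0_bounds = NULL,
                    run_index = 1L) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(demand, "demand_profile"), inherits(bounds, "bounds_spec"),
            inherits(config, "pso_config"))
  n_sub <- 10L
  # pre-align measurement indices on the 1 s evaluation grid
  ev_t <- demand$times
  meas_t <- if (is.data.frame(measured)) measured$t else ev_t
  meas_e <- if (is.data.frame(measured)) measured$energy else as.numeric(measured)
  idx <- match(round(meas_t, 6), round(ev_t, 6))
  if (anyNA(idx)) {
    stop("measured grid is not a subset of the demand grid", call. = FALSE)
  }
  # default initial state: the first measured energy sample, no fatigue
  if (is.null(init)) init <- list(ma = min(meas_e[1], m0), mf = 0)
  init <- resolve_init(init, demand, m0)
  norm_fac <- if (normalization == "per_minute") 60 else 1

  lb <- c(bounds$alpha_a[1], bounds$beta_d[1], bounds$f[1], bounds$r[1])
  ub <- c(bounds$alpha_a[2], bounds$beta_d[2], bounds$f[2], bounds$r[2])
  if (fit_m0) {
    if (is.null(m0_bounds) || length(m0_bounds) != 2L) {
      stop("fit_m0 = TRUE requires m0_bounds = c(low, high)", call. = FALSE)
    }
    lb <- c(lb, m0_bounds[1])
    ub <- c(ub, m0_bounds[2])
  }
  np <- length(lb)
  tf <- if (config$log_scale) log10 else identity
  itf <- if (config$log_scale) function(z) 10^z else identity
  lo <- tf(lb)
  hi <- tf(ub)

  cost_of <- function(z) {
    p <- itf(z)
    cm0 <- if (fit_m0) p[5] else m0
    res <- .sim_enhanced_cpp(demand$values, cm0, p[1], p[2], p[3], p[4],
                             n_sub, min(init$ma, cm0), init$mf)
    sim <- res$ma[1L + (idx - 1L) * n_sub]
    mean((sim - meas_e)^2) * norm_fac
  }

  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  sw <- config$swarm_size
  out <- with_seed(seed, {
    x <- if (!is.null(config$init_positions)) {
      m <- config$init_positions
      stopifnot(is.matrix(m), nrow(m) == sw, ncol(m) == np)
      tf(m)
    } else {
      matrix(runif(sw * np, rep(lo, each = sw), rep(hi, each = sw)),
             nrow = sw)
    }
    v <- matrix(0, nrow = sw, ncol = np)
    fx <- apply(x, 1, cost_of)
    n_eval <- sw
    pbest <- x
    pbest_f <- fx
    g <- which.min(fx)
    gbest <- x[g, ]
    gbest_f <- fx[g]
    stall <- 0L
    iter <- 0L
    while (iter < config$max_iter && stall < config$patience) {
      iter <- iter + 1L
      r1 <- matrix(runif(sw * np), sw)
      r2 <- matrix(runif(sw * np), sw)
      v <- config$inertia * v +
        config$cognitive * r1 * (pbest - x) +
        config$social * r2 * sweep(x, 2, gbest, function(a, b) b - a)
      x <- x + v
      for (j in seq_len(np)) {
        lowhit <- x[, j] < lo[j]
        highhit <- x[, j] > hi[j]
        x[lowhit, j] <- lo[j]
        x[highhit, j] <- hi[j]
        v[lowhit | highhit, j] <- 0
      }
      fx <- apply(x, 1, cost_of)
      n_eval <- n_eval + sw
      imp <- fx < pbest_f
      pbest[imp, ] <- x[imp, ]
      pbest_f[imp] <- fx[imp]
      g <- which.min(pbest_f)
      if (pbest_f[g] < gbest_f) {
        gbest_f <- pbest_f[g]
        gbest <- pbest[g, ]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    list(gbest = gbest, gbest_f = gbest_f, n_eval = n_eval, n_iter = iter)
  })
  if (!is.finite(out$gbest_f)) {
    stop("optimization failed: no feasible evaluation", call. = FALSE)
  }
  p <- itf(out$gbest)
  params <- model_parameters(p[1], p[2], p[3], p[4])
  fit_m0_val <- if (fit_m0) p[5] else m0
  traj <- simulate_fatigue(demand, params, fit_m0_val,
                           init = list(ma = min(init$ma, fit_m0_val),
                                       mf = init$mf))
  meas_df <- data.frame(t = meas_t, energy = meas_e)
  structure(
    list(params = params, m0 = fit_m0_val,
         epsilon = cost_epsilon(traj, meas_df, normalization),
         r2 = r_squared(traj, meas_df),
         n_eval = out$n_eval, n_iter = out$n_iter,
         seed = seed, run_index = as.integer(run_index),
         normalization = normalization),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> run %d (seed %d): epsilon %.4g, R2 %.3f, %d evaluations\n",
    x$run_index, x$seed, x$epsilon, x$r2, x$n_eval))
  print(x$params)
  invisible(x)
}

#' Repeated calibration runs with derived seeds
#'
#' Runs [fit_pso()] `n_runs` times with distinct seeds derived from the
#' master `seed` and keeps the run with the smallest cost, mirroring the
#' protocol of taking the most successful of ten optimization runs per
#' athlete.
#'
#' @inheritParams fit_pso
#' @param n_runs Number of independent runs (default 10).
#' @param seed Master seed from which per-run seeds are derived.
#' @param ... Passed on to [fit_pso()].
#' @return A list of class `fit_run_set` with elements `best` (the
#'   minimum-cost `fit_result`) and `runs` (all results, in run order).
#' @export
multi_run <- function(demand, measured, m0, n_runs = 10L,
                      bounds = bounds_spec(), config = pso_config(),
                      seed = 1L, ...) {
  stopifnot(n_runs >= 1L)
  run_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_runs))
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- run_seeds[i]
    runs[[i]] <- fit_pso(demand, measured, m0, bounds = bounds,
                         config = cfg, run_index = i, ...)
  }
  eps <- vapply(runs, `[[`, numeric(1), "epsilon")
  structure(list(best = runs[[which.min(eps)]], runs = runs,
                 master_seed = as.integer(seed)),
            class = "fit_run_set")
}

#' @export
print.fit_run_set <- function(x, ...) {
  cat(sprintf("<fit_run_set> %d runs (master seed %d); best run %d\n",
              length(x$runs), x$master_seed, x$best$run_index))
  print(x$best)
  invisible(x)
}

#' @export
as.data.frame.fit_run_set <- function(x, ...) {
  do.call(rbind, lapply(x$runs, function(fr) {
    data.frame(run = fr$run_index, seed = fr$seed, n_eval = fr$n_eval,
               alpha_a = fr$params$alpha_a, beta_d = fr$params$beta_d,
               f = fr$params$f, r = fr$params$r,
               epsilon = fr$epsilon, r2 = fr$r2)
  }))
}

#' Evaluate fitted parameters on a session
#'
#' Deterministic forward simulation of a session's demand with fixed
#' parameters, followed by cost and goodness-of-fit computation on the
#' whole-second grid — the workflow used to carry sprint-test parameters
#' over to match data.
#'
#' @inheritParams fit_pso
#' @param params A [model_parameters()] object (e.g. from a fit).
#' @return A list with elements `epsilon`, `r2`, `n` (evaluation points)
#'   and the simulated `trajectory`.
#' @export
evaluate_on_session <- function(params, m0, demand, measured,
                                normalization = c("per_second", "per_minute"),
                                init = NULL) {
  normalization <- match.arg(normalization)
  meas_df <- if (is.data.frame(measured)) measured
             else data.frame(t = demand$times, energy = as.numeric(measured))
  if (is.null(init)) init <- list(ma = min(meas_df$energy[1], m0), mf = 0)
  traj <- simulate_fatigue(demand, params, m0, init = init)
  list(epsilon = cost_epsilon(traj, meas_df, normalization),
       r2 = r_squared(traj, meas_df),
       n = nrow(meas_df), trajectory = traj)
}
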