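# Stiff-capable time integration of the kinetic module (deSolve/lsoda), with
# pre-equilibration to the resting state, trajectory extraction, and moiety
# accounting.

as_input_fun <- function(input) {
  if (inherits(input, "ikk_profile")) {
    p <- input
    list(fun = function(t) ikk_at(p, t), basal = p$basal,
         knots = p$knot_times)
  } else if (is.function(input)) {
    list(fun = input, basal = input(0), knots = numeric(0))
  } else if (is.numeric(input) && length(input) == 1) {
    list(fun = function(t) rep(input, length(t)), basal = input, knots = numeric(0))
  } else {
    stop("input must be an ikk_profile, a function of time, or a single number",
         call. = FALSE)
  }
}

model_state <- function(model) {
  stats::setNames(model$species$init, model$species$name)
}

#' Relax a kinetic model to its resting steady state
#'
#' Integrates the model under a constant basal input until the maximum
#' absolute time derivative falls below `tol` (in concentration per hour),
#' then writes the relaxed state back into the species initial amounts.
#' Stimulation experiments start from this self-consistent resting cell.
#'
#' @param model A `kinetic_model`.
#' @param basal Constant clamped-input value during relaxation.
#' @param tol Convergence threshold on `max |d(state)/dt|`.
#' @param t_block Hours integrated per convergence check.
#' @param max_blocks Maximum number of blocks before giving up.
#' @param rtol,atol Integrator tolerances.
#' @return The model with updated initial amounts; the reached derivative
#'   norm is attached as attribute `deriv_norm`.
#' @export
equilibrate_model <- function(model, basal, tol = 1e-9, t_block = 400,
                              max_blocks = 12, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(model, "kinetic_model"))
  comp <- compile_rates(model)
  input_fun <- function(t) rep(basal, length(t))
  ode_fun <- function(t, y, parms) list(comp$derivs(t, y, input_fun))
  y <- model_state(model)
  y[comp$clamped] <- basal
  dnorm <- Inf
  for (b in seq_len(max_blocks)) {
    out <- deSolve::lsoda(y, c(0, t_block), ode_fun, parms = NULL,
                          rtol = rtol, atol = atol)
    if (nrow(out) < 2) stop("equilibration integration failed", call. = FALSE)
    y <- out[nrow(out), -1]
    dnorm <- max(abs(comp$derivs(0, y, input_fun)))
    if (dnorm < tol) break
  }
  if (dnorm >= tol) {
    stop("no steady state reached after ", max_blocks * t_block,
         " h (max |d/dt| = ", signif(dnorm, 3), ")", call. = FALSE)
  }
  model$species$init <- pmax(unname(y), 0)
  attr(model, "deriv_norm") <- dnorm
  model
}

#' Simulate the kinetic module under a time-varying IKK input
#'
#' Integrates the mass-action ODE system with `deSolve::lsoda`. By default the
#' model is first relaxed to its resting steady state under the input's basal
#' value, after which the stimulus profile is applied at t = 0. Dense output
#' covers at least `n_points` times plus every profile knot inside the
#' horizon.
#'
#' @param model A `kinetic_model`.
#' @param input An `ikk_profile`, a function of time, or a constant.
#' @param t_end Simulation horizon in hours (> 0).
#' @param rtol,atol Integrator tolerances.
#' @param equilibrate Relax to the basal steady state before stimulating.
#' @param n_points Minimum number of dense-output times.
#' @return An object of class `trajectory` with fields `times` and `amounts`
#'   (species x times, concentration units), plus the model used.
#' @export
simulate_model <- function(model, input, t_end = 12, rtol = 1e-8, atol = 1e-12,
                           equilibrate = TRUE, n_points = 201) {
  stopifnot(inherits(model, "kinetic_model"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  inp <- as_input_fun(input)
  if (equilibrate) model <- equilibrate_model(model, basal = inp$basal,
                                              rtol = rtol, atol = min(atol, 1e-12))
  comp <- compile_rates(model)
  ode_fun <- function(t, y, parms) list(comp$derivs(t, y, inp$fun))
  times <- sort(unique(c(seq(0, t_end, length.out = max(n_points, 2)),
                         inp$knots[inp$knots >= 0 & inp$knots <= t_end])))
  y0 <- model_state(model)
  y0[comp$clamped] <- inp$fun(0)
  out <- deSolve::lsoda(y0, times, ode_fun, parms = NULL, rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    stop("integrator failure at t = ", out[nrow(out), 1], " h", call. = FALSE)
  }
  amounts <- t(out[, -1, drop = FALSE])
  rownames(amounts) <- comp$species
  for (ci in comp$clamped) amounts[ci, ] <- inp$fun(times)
  neg <- min(amounts)
  if (neg < -1000 * atol) {
    stop("negative state beyond integrator tolerance (min = ", signif(neg, 3), ")",
         call. = FALSE)
  }
  structure(list(times = times, amounts = amounts, model = model,
                 rtol = rtol, atol = atol), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$amounts), " species x ", length(x$times),
      " times on [", min(x$times), ", ", max(x$times), "] h\n", sep = "")
  invisible(x)
}

#' Sample a species time course from a trajectory
#'
#' Nuclear free NF-kB (`NFkBn`) is the model's readout of transcriptional
#' activity; its concentration is linearly interpolated from the dense output
#' at the requested grid times.
#'
#' @param traj A `trajectory`.
#' @param grid Times (hours) inside the simulated horizon.
#' @param species Species name to extract.
#' @return Numeric vector of concentrations at `grid`.
#' @export
nfkb_activity <- function(traj, grid, species = "NFkBn") {
  stopifnot(inherits(traj, "trajectory"))
  grid <- as.numeric(grid)
  if (any(grid < min(traj$times)) || any(grid > max(traj$times))) {
    stop("grid time(s) outside the simulated horizon [", min(traj$times), ", ",
         max(traj$times), "] h", call. = FALSE)
  }
  if (!species %in% rownames(traj$amounts)) stop("unknown species: ", species, call. = FALSE)
  stats::approx(traj$times, traj$amounts[species, ], xout = grid)$y
}

#' Volume-weighted total of a conserved moiety
#'
#' @param x A `kinetic_model` (uses initial amounts) or a `trajectory`
#'   (returns the total over time).
#' @param name Moiety name declared in the model file.
#' @return A single total (model) or a vector over time (trajectory), in
#'   cytoplasmic-equivalent concentration units.
#' @export
moiety_total <- function(x, name = "NFkB_total") {
  if (inherits(x, "trajectory")) {
    model <- x$model
    m <- find_moiety(model, name)
    w <- moiety_weight_vector(model, m)
    as.numeric(w %*% x$amounts)
  } else if (inherits(x, "kinetic_model")) {
    m <- find_moiety(x, name)
    w <- moiety_weight_vector(x, m)
    sum(w * x$species$init)
  } else {
    stop("x must be a kinetic_model or trajectory", call. = FALSE)
  }
}

find_moiety <- function(model, name) {
  for (m in model$moieties) if (m$name == name) return(m)
  stop("moiety not declared in model: ", name, call. = FALSE)
}
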