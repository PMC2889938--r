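# Profile normalisation and the inverse matching step: place NCA-derived and
# simulated NF-kB activity profiles on a common relative scale and select the
# candidate IKK input whose simulated response best matches the data-derived
# profile by Pearson correlation.

#' Normalise a series to a maximum of 1
#'
#' @param x Numeric series whose maximum is positive.
#' @return `x / max(x)`; the output maximum is exactly 1.
#' @export
normalize_max1 <- function(x) {
  if (!is.numeric(x) || !length(x)) stop("x must be a non-empty numeric series", call. = FALSE)
  m <- max(x)
  if (!is.finite(m) || m <= 0) stop("series maximum must be positive", call. = FALSE)
  x / m
}

#' Convert simulated nuclear NF-kB concentrations to relative log activity
#'
#' Because the expression data entering NCA are log ratios, the simulated
#' concentration series is converted to the log of its ratio to the resting
#' (t = 0) value: `r_j = ln(max(c_j, eps) / max(c_0, eps))`, with a floor
#' `eps` (by default 1e-6 of the total NF-kB moiety) guarding against log(0)
#' for a near-empty resting nucleus. The result is normalised to peak 1 when
#' its maximum is positive; otherwise it is returned unscaled with attribute
#' `normalized = FALSE`.
#'
#' @param conc Non-negative concentration series; the first entry is t = 0.
#' @param total Total NF-kB moiety (sets the default floor).
#' @param eps Explicit floor overriding the default.
#' @return Numeric series with attribute `normalized` (logical).
#' @export
sim_to_activity <- function(conc, total = NULL, eps = NULL) {
  if (!is.numeric(conc) || !length(conc)) stop("conc must be numeric", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (all(conc == 0)) stop("all-zero concentration series", call. = FALSE)
  if (is.null(eps)) {
    if (is.null(total)) stop("provide 'total' (NF-kB moiety) or an explicit 'eps'", call. = FALSE)
    eps <- 1e-6 * total
  }
  r <- log(pmax(conc, eps) / max(conc[1], eps))
  if (max(r) > 0) {
    out <- normalize_max1(r)
    attr(out, "normalized") <- TRUE
  } else {
    out <- r
    attr(out, "normalized") <- FALSE
  }
  out
}

#' Sample Pearson correlation coefficient
#'
#' Thin validated wrapper around [stats::cor()]: both series must have equal
#' length of at least 3 and non-zero variance (a zero-variance series is an
#' error here, distinct from `NA` propagation).
#'
#' @param x,y Numeric series.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("series contain missing values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance series", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Simulate all candidate IKK profiles and extract relative NF-kB activities
#'
#' The model is relaxed once to the resting state per distinct basal value,
#' then each candidate is simulated from that state and its nuclear NF-kB
#' series on `grid` is converted with [sim_to_activity()].
#'
#' @param model A `kinetic_model`.
#' @param candidates List of `ikk_profile` objects.
#' @param grid Comparison time grid (hours), starting at 0.
#' @param rtol,atol Integrator tolerances.
#' @return Matrix (candidates x grid) of relative activities, with candidate
#'   ids as row names and attribute `integrals` (IKK time integrals).
#' @export
candidate_activities <- function(model, candidates, grid, rtol = 1e-8, atol = 1e-12) {
  stopifnot(length(candidates) >= 1)
  grid <- time_grid(grid)
  total <- moiety_total(model, "NFkB_total")
  basals <- vapply(candidates, `[[`, 0, "basal")
  eq_cache <- list()
  acts <- matrix(NA_real_, length(candidates), length(grid))
  rownames(acts) <- vapply(seq_along(candidates), function(i) {
    id <- candidates[[i]]$id
    if (is.null(id)) sprintf("candidate_%03d", i) else id
  }, "")
  failures <- character(0)
  for (i in seq_along(candidates)) {
    key <- sprintf("%.15g", basals[i])
    if (is.null(eq_cache[[key]])) {
      eq_cache[[key]] <- equilibrate_model(model, basal = basals[i],
                                           rtol = rtol, atol = min(atol, 1e-12))
    }
    act <- tryCatch({
      traj <- simulate_model(eq_cache[[key]], candidates[[i]], t_end = max(grid),
                             rtol = rtol, atol = atol, equilibrate = FALSE)
      as.numeric(sim_to_activity(nfkb_activity(traj, grid), total = total))
    }, error = function(e) {
      failures <<- c(failures, conditionMessage(e))
      NULL
    })
    if (!is.null(act)) acts[i, ] <- act
  }
  if (all(is.na(acts[, 1]))) {
    stop("all candidate simulations failed: ", paste(unique(failures), collapse = "; "),
         call. = FALSE)
  }
  attr(acts, "integrals") <- vapply(candidates, profile_integral, 0)
  acts
}

#' Select the IKK candidate whose simulated NF-kB profile best matches a target
#'
#' For each candidate the model is simulated, the nuclear NF-kB series on the
#' comparison grid is converted to relative log activity, and its Pearson
#' correlation with the max-1-normalised target (the NCA-reconstructed NF-kB
#' activity of one condition) is computed. The candidate with maximal r wins;
#' exact ties are broken by the smaller IKK time integral (parsimony), then
#' by candidate order. Pearson correlation is invariant under positive affine
#' maps, so the ranking does not depend on the normalisation conventions.
#'
#' @param target Data-derived NF-kB activity on `grid` (one condition).
#' @param candidates List of `ikk_profile` objects.
#' @param model A `kinetic_model` (not needed when `activities` is supplied).
#' @param grid Comparison time grid; must match the target's grid.
#' @param drop_t0 Drop the t = 0 point from the comparison (the Methods-style
#'   five-point mapping) instead of keeping it.
#' @param activities Optional precomputed matrix from [candidate_activities()].
#' @param refine Optionally polish the winner's knot heights with a
#'   derivative-free maximiser of r (off by default).
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `match_result`: `best_profile`, `best_id`,
#'   `pcc`, `per_candidate` (data frame of id, pcc, ikk_integral),
#'   `normalized_target`, `normalized_best`, and `grid`.
#' @export
match_profiles <- function(target, candidates, model = NULL, grid,
                           drop_t0 = FALSE, activities = NULL, refine = FALSE,
                           rtol = 1e-8, atol = 1e-12) {
  grid <- time_grid(grid)
  target <- as.numeric(target)
  if (length(target) != length(grid)) stop("target length must match the grid", call. = FALSE)
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  if (is.null(activities)) {
    if (is.null(model)) stop("provide 'model' or precomputed 'activities'", call. = FALSE)
    activities <- candidate_activities(model, candidates, grid, rtol = rtol, atol = atol)
  }
  integrals <- attr(activities, "integrals")
  if (is.null(integrals)) integrals <- vapply(candidates, profile_integral, 0)
  tnorm <- normalize_max1(target)
  keep <- if (drop_t0) -1L else seq_along(grid)
  r <- vapply(seq_along(candidates), function(i) {
    a <- activities[i, keep]
    if (anyNA(a) || stats::sd(a) == 0) return(NA_real_)
    pearson_cc(tnorm[keep], a)
  }, 0)
  if (all(is.na(r))) stop("no candidate produced a usable simulated profile", call. = FALSE)
  best_r <- max(r, na.rm = TRUE)
  tied <- which(!is.na(r) & r >= best_r - 1e-12)
  winner <- tied[order(integrals[tied], tied)][1]
  best_profile <- candidates[[winner]]
  if (refine) {
    if (is.null(model)) stop("refinement needs the kinetic model", call. = FALSE)
    refined <- refine_winner(tnorm, best_profile, model, grid, keep, rtol, atol)
    if (refined$pcc > r[winner]) {
      best_profile <- refined$profile
      r[winner] <- refined$pcc
      activities[winner, ] <- refined$activity
      best_r <- refined$pcc
    }
  }
  structure(list(
    best_profile = best_profile,
    best_id = rownames(activities)[winner],
    pcc = unname(r[winner]),
    per_candidate = data.frame(id = rownames(activities), pcc = r,
                               ikk_integral = integrals, stringsAsFactors = FALSE),
    normalized_target = tnorm,
    normalized_best = activities[winner, ],
    grid = grid, drop_t0 = drop_t0), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> winner '", x$best_id, "' with Pearson r = ",
      signif(x$pcc, 4), " over ", nrow(x$per_candidate), " candidate(s)\n", sep = "")
  invisible(x)
}

# Local Nelder-Mead polish of the winning profile's knot heights.
refine_winner <- function(tnorm, profile, model, grid, keep, rtol, atol) {
  eq <- equilibrate_model(model, basal = profile$basal, rtol = rtol,
                          atol = min(atol, 1e-12))
  total <- moiety_total(model, "NFkB_total")
  objective <- function(v) {
    vals <- abs(v)
    p <- ikk_profile(vals, profile$knot_times, basal = profile$basal)
    a <- tryCatch({
      traj <- simulate_model(eq, p, t_end = max(grid), rtol = rtol, atol = atol,
                             equilibrate = FALSE)
      as.numeric(sim_to_activity(nfkb_activity(traj, grid), total = total))
    }, error = function(e) NULL)
    if (is.null(a) || stats::sd(a[keep]) == 0) return(2)
    -pearson_cc(tnorm[keep], a[keep])
  }
  opt <- stats::optim(profile$knot_values, objective, method = "Nelder-Mead",
                      control = list(maxit = 60))
  p <- ikk_profile(abs(opt$par), profile$knot_times, basal = profile$basal,
                   id = paste0(profile$id, "_refined"))
  traj <- simulate_model(eq, p, t_end = max(grid), rtol = rtol, atol = atol,
                         equilibrate = FALSE)
  act <- as.numeric(sim_to_activity(nfkb_activity(traj, grid), total = total))
  list(profile = p, pcc = -opt$value, activity = act)
}
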