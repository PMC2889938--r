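# Candidate time-varying IKK inputs: continuous piecewise-linear profiles on a
# knot grid, plus a parametric pulse-decay(+second wave) candidate generator.

#' Construct a piecewise-linear IKK activity profile
#'
#' Activity is linearly interpolated between knots and equals `basal` before
#' the first and after the last knot. The default knot set includes 1 h (the
#' kinase-assay sampling grid) even though expression grids omit it, giving
#' the inverse search extra freedom in the early response.
#'
#' @param knot_values Non-negative activity values at the knots.
#' @param knot_times Strictly increasing knot times in hours.
#' @param basal Activity outside the knot span (and before stimulation).
#' @param id Optional identifier string.
#' @return An object of class `ikk_profile`.
#' @export
ikk_profile <- function(knot_values, knot_times = c(0, 0.5, 1, 2, 4, 6, 12),
                        basal = knot_values[1], id = NULL) {
  knot_times <- as.numeric(knot_times)
  knot_values <- as.numeric(knot_values)
  if (length(knot_times) != length(knot_values)) {
    stop("knot_times and knot_values must have the same length", call. = FALSE)
  }
  if (length(knot_times) < 2 || any(diff(knot_times) <= 0)) {
    stop("knot_times must be strictly increasing with length >= 2", call. = FALSE)
  }
  if (any(!is.finite(knot_values)) || any(knot_values < 0)) {
    stop("knot_values must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(basal) || basal < 0) stop("basal must be finite and >= 0", call. = FALSE)
  structure(list(knot_times = knot_times, knot_values = knot_values,
                 basal = as.numeric(basal), id = id), class = "ikk_profile")
}

#' @export
print.ikk_profile <- function(x, ...) {
  cat("<ikk_profile>", if (!is.null(x$id)) paste0(" '", x$id, "'"), " ",
      length(x$knot_times), " knots on [", x$knot_times[1], ", ",
      x$knot_times[length(x$knot_times)], "] h, peak ", max(x$knot_values),
      ", basal ", x$basal, "\n", sep = "")
  invisible(x)
}

#' Evaluate an IKK profile
#'
#' @param p An `ikk_profile`.
#' @param t Numeric vector of times (hours).
#' @return Activity values; `basal` outside the knot span.
#' @export
ikk_at <- function(p, t) {
  stopifnot(inherits(p, "ikk_profile"))
  if (any(!is.finite(t))) stop("times must be finite", call. = FALSE)
  kt <- p$knot_times; kv <- p$knot_values
  out <- rep(p$basal, length(t))
  inside <- t >= kt[1] & t <= kt[length(kt)]
  if (any(inside)) {
    ti <- t[inside]
    i <- findInterval(ti, kt, rightmost.closed = TRUE)
    w <- (ti - kt[i]) / (kt[i + 1] - kt[i])
    out[inside] <- kv[i] + w * (kv[i + 1] - kv[i])
  }
  out
}

# Time integral of the profile over its knot span (trapezoid; exact for a
# piecewise-linear curve). Used as the parsimony tie-break in matching.
profile_integral <- function(p) {
  kt <- p$knot_times; kv <- p$knot_values
  sum(diff(kt) * (utils::head(kv, -1) + utils::tail(kv, -1)) / 2)
}

#' Generate candidate IKK profiles on a parametric grid
#'
#' Renders the Cartesian product of `peak_times` x `peak_heights` x
#' `decay_fractions` (optionally x second-wave options) as piecewise-linear
#' profiles: the activity rises linearly from `basal` at the first knot to the
#' peak height at the peak time, then decays geometrically by the decay
#' fraction at each subsequent knot; a second wave adds its height at the
#' stated knot. Duplicate profiles are removed; the order is deterministic.
#'
#' @param peak_times Peak times; each must be one of `knot_times`.
#' @param peak_heights Peak activity values (> basal).
#' @param decay_fractions Per-knot geometric decay fractions in (0, 1].
#' @param second_wave `NULL`, or a data frame with columns `time` (a knot)
#'   and `height` giving additive second-wave options; profiles without a
#'   second wave are always included.
#' @param knot_times Shared knot grid.
#' @param basal Basal activity.
#' @return List of `ikk_profile` objects with descriptive ids.
#' @export
generate_candidates <- function(peak_times, peak_heights, decay_fractions,
                                second_wave = NULL,
                                knot_times = c(0, 0.5, 1, 2, 4, 6, 12),
                                basal = 0) {
  if (!length(peak_times) || !length(peak_heights) || !length(decay_fractions)) {
    stop("empty candidate grid", call. = FALSE)
  }
  if (!all(peak_times %in% knot_times)) {
    stop("every peak time must be a knot time", call. = FALSE)
  }
  if (!is.null(second_wave)) {
    second_wave <- as.data.frame(second_wave)
    stopifnot(all(c("time", "height") %in% names(second_wave)))
    if (!all(second_wave$time %in% knot_times)) {
      stop("every second-wave time must be a knot time", call. = FALSE)
    }
  }
  waves <- c(list(NULL), if (!is.null(second_wave)) {
    lapply(seq_len(nrow(second_wave)), function(i) second_wave[i, ])
  })
  out <- list()
  seen <- character(0)
  for (w in waves) for (pt in peak_times) for (h in peak_heights) for (d in decay_fractions) {
    vals <- numeric(length(knot_times))
    rising <- knot_times <= pt
    vals[rising] <- basal + (h - basal) * (knot_times[rising] - knot_times[1]) /
      max(pt - knot_times[1], .Machine$double.eps)
    n_after <- sum(!rising)
    if (n_after > 0) vals[!rising] <- h * d^seq_len(n_after)
    id <- sprintf("pk%g_h%g_d%g", pt, h, d)
    if (!is.null(w)) {
      vals[knot_times == w$time] <- vals[knot_times == w$time] + w$height
      id <- sprintf("%s_w%gx%g", id, w$time, w$height)
    }
    key <- paste(sprintf("%.15g", vals), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- ikk_profile(vals, knot_times, basal = basal, id = id)
  }
  out
}

#' Read an IKK profile from a two-column TSV (`time_h`, `ikk_activity`)
#' @param path Input path.
#' @param basal Basal activity outside the knot span; defaults to the first value.
#' @return An `ikk_profile`.
#' @export
read_ikk <- function(path, basal = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("time_h", "ikk_activity") %in% names(df))) {
    stop("IKK file needs 'time_h' and 'ikk_activity' columns", call. = FALSE)
  }
  ikk_profile(df$ikk_activity, df$time_h,
              basal = if (is.null(basal)) df$ikk_activity[1] else basal)
}

#' Write an IKK profile as TSV
#' @param p An `ikk_profile`.
#' @param path Output path.
#' @export
write_ikk <- function(p, path) {
  stopifnot(inherits(p, "ikk_profile"))
  lines <- c("time_h\tikk_activity",
             sprintf("%.17g\t%.17g", p$knot_times, p$knot_values))
  writeLines(lines, path)
  invisible(path)
}
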