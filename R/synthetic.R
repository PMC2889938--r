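# Synthetic-data generator: expression matrices with the log-linear bipartite
# structure the pipeline assumes (E = S A + noise), identifiable supports, and
# a closed-loop bundle whose NF-kB activity row is produced by the forward
# kinetic simulation of a known IKK input.

#' Specify a synthetic NCA instance
#'
#' Defaults mirror the study layout the pipeline targets: 54 NF-kB target
#' genes with 77 regulatory edges over 3 TFs, three LPS-dose conditions
#' sampled at 0, 0.5, 2, 4, 6 and 12 h, dose-scaled activity amplitudes with
#' less than 50% spread across the dose range, and additive Gaussian noise of
#' 0.1 on the log2-ratio scale. The first TF is designated NF-kB.
#'
#' @param n_genes Number of target genes I.
#' @param n_tfs Number of TFs K (TF 1 is `NFKB`).
#' @param conditions Condition labels (one per dose).
#' @param grid Shared sampling time grid (hours).
#' @param n_edges Total number of TF->gene edges (>= n_genes so every gene is
#'   regulated).
#' @param strength_meanlog,strength_sdlog Log-normal magnitude parameters of
#'   the influence strengths.
#' @param sign_prob Probability that an edge is activating (+1).
#' @param amplitudes Per-condition activity amplitudes of the NF-kB row.
#' @param nfkb_peak Peak time (a grid point) of the NF-kB activity pulse.
#' @param other_peaks Peak times for the remaining TFs (recycled).
#' @param noise_sd Additive Gaussian noise on log2 ratios.
#' @param seed RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 54, n_tfs = 3,
                           conditions = c("lps0.01", "lps0.1", "lps1"),
                           grid = c(0, 0.5, 2, 4, 6, 12),
                           n_edges = 77,
                           strength_meanlog = 0, strength_sdlog = 0.4,
                           sign_prob = 0.8,
                           amplitudes = c(0.6, 0.8, 1.0),
                           nfkb_peak = 2, other_peaks = c(4, 6, 0.5),
                           noise_sd = 0.1, seed = 0) {
  grid <- time_grid(grid)
  stopifnot(n_genes >= n_tfs, n_tfs >= 1, n_edges >= n_genes,
            n_edges <= n_genes * n_tfs, noise_sd >= 0,
            length(amplitudes) == length(conditions), all(amplitudes > 0),
            nfkb_peak %in% grid)
  structure(list(n_genes = n_genes, n_tfs = n_tfs, conditions = conditions,
                 grid = grid, n_edges = n_edges,
                 strength_meanlog = strength_meanlog,
                 strength_sdlog = strength_sdlog, sign_prob = sign_prob,
                 amplitudes = amplitudes, nfkb_peak = nfkb_peak,
                 other_peaks = other_peaks, noise_sd = noise_sd, seed = seed,
                 tf_ids = c("NFKB", if (n_tfs > 1) paste0("TF", 2:n_tfs)),
                 gene_ids = sprintf("G%03d", seq_len(n_genes))),
            class = "synthetic_spec")
}

# Smooth gamma-shaped pulse on a grid: zero at t = 0, peak value 1 at
# `peak_time`, smooth rise and decay.
activity_pulse <- function(times, peak_time, shape = 2) {
  stopifnot(peak_time > 0)
  x <- times / peak_time
  (x^shape) * exp(shape * (1 - x))
}

# Random identifiable support with exactly n_edges edges: every gene gets one
# base TF (all TFs covered), remaining edges drawn without replacement from
# the unused (gene, TF) pairs. Resampled until check_identifiability passes.
draw_support <- function(spec, J_total, max_tries = 50) {
  I <- spec$n_genes; K <- spec$n_tfs
  for (try in seq_len(max_tries)) {
    base <- sample(c(seq_len(K), sample.int(K, I - K, replace = TRUE)))
    support <- matrix(FALSE, I, K, dimnames = list(spec$gene_ids, spec$tf_ids))
    support[cbind(seq_len(I), base)] <- TRUE
    free <- which(!support)
    extra <- spec$n_edges - I
    if (extra > 0) support[sample(free, extra)] <- TRUE
    if (check_identifiability(support, J_total)$identifiable) return(support)
  }
  stop("no identifiable support found within ", max_tries, " resamples", call. = FALSE)
}

# Build (expr, net, S_true) around a supplied activity matrix A_true.
instance_from_activity <- function(spec, A_true) {
  J <- length(spec$grid); D <- length(spec$conditions)
  support <- draw_support(spec, J_total = J * D)
  signs <- matrix(0L, spec$n_genes, spec$n_tfs)
  signs[support] <- ifelse(stats::runif(sum(support)) < spec$sign_prob, 1L, -1L)
  S_true <- matrix(0, spec$n_genes, spec$n_tfs,
                   dimnames = list(spec$gene_ids, spec$tf_ids))
  S_true[support] <- signs[support] *
    stats::rlnorm(sum(support), spec$strength_meanlog, spec$strength_sdlog)
  E <- S_true %*% A_true +
    matrix(stats::rnorm(spec$n_genes * J * D, sd = spec$noise_sd),
           spec$n_genes, J * D)
  grids <- stats::setNames(rep(list(spec$grid), D), spec$conditions)
  expr <- expression_matrix(E, spec$gene_ids, spec$conditions, grids)
  idx <- which(support, arr.ind = TRUE)
  edges <- data.frame(tf = spec$tf_ids[idx[, 2]], gene = spec$gene_ids[idx[, 1]],
                      sign = signs[support], stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$tf, spec$tf_ids), edges$gene), ]
  rownames(edges) <- NULL
  list(expr = expr, net = regulatory_network(edges), S_true = S_true,
       support = support)
}

# Activity rows for the non-NF-kB TFs: unit-amplitude pulses peaking at the
# assigned grid times, identical across conditions.
other_tf_rows <- function(spec) {
  D <- length(spec$conditions); J <- length(spec$grid)
  K <- spec$n_tfs
  if (K < 2) return(NULL)
  peaks <- rep(spec$other_peaks, length.out = K - 1)
  rows <- t(vapply(peaks, function(p) {
    rep(activity_pulse(spec$grid, p), D)
  }, numeric(J * D)))
  rownames(rows) <- spec$tf_ids[-1]
  rows
}

#' Generate a synthetic NCA instance with known factors
#'
#' Produces `E = S_true %*% A_true + noise` on the spec's condition/grid
#' layout. The NF-kB activity row is a smooth pulse peaking at
#' `spec$nfkb_peak` in every condition, scaled by the per-condition
#' amplitudes; remaining TF rows are unit pulses at other peak times. The
#' support is resampled until it passes [check_identifiability()]. Generation
#' is deterministic given `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `expr` (`expr_matrix`), `net` (`reg_network`), `S_true`,
#'   `A_true`, and `spec`.
#' @export
gen_nca_instance <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    D <- length(spec$conditions); J <- length(spec$grid)
    nfkb_row <- unlist(lapply(spec$amplitudes, function(a) {
      a * activity_pulse(spec$grid, spec$nfkb_peak)
    }), use.names = FALSE)
    A_true <- rbind(NFKB = nfkb_row, other_tf_rows(spec))
    colnames(A_true) <- unlist(lapply(spec$conditions, function(cc) {
      paste0(cc, "@", as.character(spec$grid))
    }), use.names = FALSE)
    inst <- instance_from_activity(spec, A_true)
    c(inst[c("expr", "net", "S_true")], list(A_true = A_true, spec = spec))
  })
}

#' Generate a closed-loop synthetic bundle from a ground-truth IKK profile
#'
#' Simulates the kinetic model under `ikk_truth`, converts the nuclear NF-kB
#' series on the spec's grid to relative log activity, uses it (scaled by the
#' per-condition amplitudes) as the NF-kB activity row, and generates the
#' expression matrix around it. The bundle carries the ground truth needed by
#' end-to-end recovery tests of the full pipeline
#' (fit_nca -> match_profiles).
#'
#' @param ikk_truth An `ikk_profile`.
#' @param model A `kinetic_model`.
#' @param spec A `synthetic_spec`.
#' @param nfkb_shape Optional precomputed relative activity on the spec grid
#'   (skips the forward simulation; useful when generating many bundles from
#'   one truth).
#' @param rtol,atol Integrator tolerances for the forward simulation.
#' @return List with `expr`, `net`, `S_true`, `A_true` (`A_implied`),
#'   `ikk_truth`, `nfkb_shape`, and `spec`.
#' @export
gen_end_to_end <- function(ikk_truth, model, spec, nfkb_shape = NULL,
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(ikk_truth, "ikk_profile"))
  if (is.null(nfkb_shape)) {
    traj <- simulate_model(model, ikk_truth, t_end = max(spec$grid),
                           rtol = rtol, atol = atol)
    nfkb_shape <- as.numeric(sim_to_activity(
      nfkb_activity(traj, spec$grid), total = moiety_total(model, "NFkB_total")))
  }
  stopifnot(length(nfkb_shape) == length(spec$grid))
  with_seed(spec$seed, {
    nfkb_row <- unlist(lapply(spec$amplitudes, function(a) a * nfkb_shape),
                       use.names = FALSE)
    A_true <- rbind(NFKB = nfkb_row, other_tf_rows(spec))
    colnames(A_true) <- unlist(lapply(spec$conditions, function(cc) {
      paste0(cc, "@", as.character(spec$grid))
    }), use.names = FALSE)
    inst <- instance_from_activity(spec, A_true)
    c(inst[c("expr", "net", "S_true")],
      list(A_true = A_true, ikk_truth = ikk_truth, nfkb_shape = nfkb_shape,
           spec = spec))
  })
}
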