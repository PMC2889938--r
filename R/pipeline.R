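# Whole-pipeline driver: filter -> NCA fit -> candidate generation ->
# per-condition IKK matching, with reproducible seeds, structured logging and
# TSV/JSON artifacts. The command-line wrapper in inst/scripts/nfkblink.R is a
# thin shell over these functions.

pipeline_defaults <- function() {
  list(
    seed = 0,
    out_dir = "nfkblink_out",
    expression = NULL,
    network = NULL,
    model = NULL,
    tf = "NFKB",
    filter = list(min_abs_logratio = 1.0),
    nca = list(tol = 1e-8, max_iter = 1000, n_restarts = 5),
    candidates = list(peak_times = c(0.5, 2, 4, 6),
                      peak_heights = c(0.05, 0.1, 0.2),
                      decay_fractions = c(0.25, 0.5, 0.75),
                      second_wave = NULL,
                      knot_times = c(0, 0.5, 1, 2, 4, 6, 12),
                      basal = 1e-4),
    match = list(drop_t0 = FALSE),
    sim = list(rtol = 1e-8, atol = 1e-12)
  )
}

merge_config <- function(defaults, user) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

write_matrix_tsv <- function(M, path, rowname_header) {
  header <- paste(c(rowname_header, colnames(M)), collapse = "\t")
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(rownames(M)[i], sprintf("%.17g", M[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
}

#' Run the full linking pipeline
#'
#' Stages: read the expression matrix and regulatory network, filter weakly
#' expressed genes, fit the NCA decomposition, generate candidate IKK
#' profiles, and match the reconstructed NF-kB activity of every condition
#' against the forward-simulated candidates. All stage parameters live in one
#' config (a named list or a YAML file path); unknown keys are rejected and a
#' resolved copy of the config is written alongside the outputs, so a run can
#' be reproduced from its own artifacts.
#'
#' Outputs in `out_dir`: `S.tsv`, `A.tsv`, `fit.json`, one
#' `match_<condition>.json` per condition, `resolved_config.yaml` and
#' `pipeline.log`.
#'
#' @param config Named list or path to a YAML config file. Recognised keys:
#'   `seed`, `out_dir`, `expression` (path or vector of per-condition paths),
#'   `network` (path), `model` (path or `NULL` for the bundled default),
#'   `tf`, `filter$min_abs_logratio`, `nca$(tol, max_iter, n_restarts)`,
#'   `candidates$(peak_times, peak_heights, decay_fractions, second_wave,
#'   knot_times, basal)`, `match$drop_t0`, `sim$(rtol, atol)`.
#' @return Invisibly, a list with the fitted `nca_result`, the candidate
#'   list, and the per-condition `match_result`s.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  yaml::write_yaml(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))

  expr <- stage("read_expression", {
    if (is.null(cfg$expression)) stop("no expression input configured")
    mats <- lapply(cfg$expression, read_expression)
    concat_conditions(mats)
  })
  say("read expression: ", length(expr$genes), " genes x ", ncol(expr$values),
      " columns (", length(expr$conditions), " condition(s))")
  net <- stage("read_network", {
    if (is.null(cfg$network)) stop("no network input configured")
    read_network(cfg$network)
  })
  say("read network: ", length(net$tfs), " TF(s), ", nrow(net$edges), " edge(s)")

  flt <- stage("filter_expressed",
               filter_expressed(expr, net, cfg$filter$min_abs_logratio))
  say("filtered at |log2| >= ", cfg$filter$min_abs_logratio, ": ",
      length(flt$expr$genes), " genes, ", nrow(flt$net$edges), " edges remain")

  fit <- stage("fit_nca", fit_nca(flt$expr, flt$net, tol = cfg$nca$tol,
                                  max_iter = cfg$nca$max_iter, seed = cfg$seed,
                                  n_restarts = cfg$nca$n_restarts))
  say("NCA fit: relative residual ", signif(fit$residual, 4), " after ",
      fit$n_iter, " iteration(s)")
  write_matrix_tsv(fit$S, file.path(cfg$out_dir, "S.tsv"), "gene_id")
  write_matrix_tsv(fit$A, file.path(cfg$out_dir, "A.tsv"), "tf_id")
  jsonlite::write_json(
    list(residual = fit$residual, n_iter = fit$n_iter, converged = fit$converged,
         identifiable = fit$identifiability$identifiable,
         violations = fit$identifiability$violations),
    file.path(cfg$out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)

  model <- stage("load_model", load_model(cfg$model))
  say("model: ", nrow(model$species), " species, ", length(model$reactions),
      " reactions")
  cands <- stage("generate_candidates", do.call(generate_candidates, cfg$candidates))
  say("generated ", length(cands), " candidate IKK profile(s)")

  if (!cfg$tf %in% fit$tfs) {
    stop("stage 'match_profiles': TF '", cfg$tf, "' not in the fitted network",
         call. = FALSE)
  }
  matches <- list()
  acts <- NULL
  for (cond in fit$conditions) {
    cols <- condition_columns(flt$expr, cond)
    grid <- fit$grids[[cond]]
    if (is.null(acts)) {
      acts <- stage("candidate_activities",
                    candidate_activities(model, cands, grid,
                                         rtol = cfg$sim$rtol, atol = cfg$sim$atol))
    }
    m <- stage("match_profiles",
               match_profiles(fit$A[cfg$tf, cols], cands, grid = grid,
                              drop_t0 = cfg$match$drop_t0, activities = acts))
    matches[[cond]] <- m
    say("condition ", cond, ": winner '", m$best_id, "' (r = ",
        signif(m$pcc, 4), ")")
    jsonlite::write_json(
      list(condition = cond, winner = m$best_id, pcc = m$pcc,
           knot_times = m$best_profile$knot_times,
           knot_values = m$best_profile$knot_values,
           normalized_target = m$normalized_target,
           normalized_best = as.numeric(m$normalized_best),
           per_candidate = m$per_candidate),
      file.path(cfg$out_dir, paste0("match_", gsub("[^A-Za-z0-9._-]", "_", cond), ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  say("done")
  invisible(list(fit = fit, candidates = cands, matches = matches, config = cfg))
}
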