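# Network Component Analysis: support-constrained bipartite decomposition of a
# log-ratio expression matrix E (I x J) into influence strengths S (I x K) and
# TF activities A (K x J), E ~ S %*% A with S zero outside the known regulatory
# support. Solved by alternating least squares with restricted per-gene rows.

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

numeric_rank <- function(M, tol = NULL) {
  if (nrow(M) == 0 || ncol(M) == 0) return(0L)
  d <- svd(M, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

#' Check NCA identifiability of a support pattern
#'
#' Applies the three identifiability criteria for support-constrained bipartite
#' decomposition via a generic-rank test: the support is filled with
#' independent standard-normal draws (repeated `m` times under a fixed seed,
#' rank taken as the maximum over fills, so that a generic fill decides):
#' (1) the filled strength matrix has full column rank K; (2) for every
#' regulator k, deleting column k together with all rows in which k is active
#' leaves a matrix of full column rank K - 1; (3) the number of samples is at
#' least K.
#'
#' @param support Logical I x K matrix; `TRUE` marks an allowed non-zero.
#' @param J_total Total number of expression columns available for the fit.
#' @param m Number of random fills per rank evaluation.
#' @param seed RNG seed for the fills.
#' @return List with `identifiable` (logical) and `violations`
#'   (character vector naming the failing criterion and TF).
#' @export
check_identifiability <- function(support, J_total, m = 5, seed = 0) {
  support <- as.matrix(support)
  storage.mode(support) <- "logical"
  I <- nrow(support); K <- ncol(support)
  if (K < 1 || I < K) stop("need I >= K >= 1", call. = FALSE)
  empty <- which(colSums(support) == 0)
  if (length(empty)) {
    nm <- if (!is.null(colnames(support))) colnames(support)[empty] else as.character(empty)
    stop("TF(s) with empty regulon: ", paste(nm, collapse = ", "), call. = FALSE)
  }
  tf_names <- colnames(support)
  if (is.null(tf_names)) tf_names <- paste0("TF", seq_len(K))
  violations <- character(0)
  fills <- with_seed(seed, lapply(seq_len(m), function(r) {
    S <- matrix(0, I, K)
    S[support] <- stats::rnorm(sum(support))
    S
  }))
  rank_of <- function(f) max(vapply(fills, function(S) numeric_rank(f(S)), 0L))
  if (rank_of(identity) < K) {
    violations <- c(violations, "criterion 1: filled strength matrix is column-rank deficient")
  }
  if (K > 1) {
    for (k in seq_len(K)) {
      rows <- !support[, k]
      rk <- rank_of(function(S) S[rows, -k, drop = FALSE])
      if (rk < K - 1) {
        violations <- c(violations, paste0(
          "criterion 2: removing ", tf_names[k],
          " and its regulon leaves a rank-deficient submatrix"))
      }
    }
  }
  if (J_total < K) {
    violations <- c(violations, paste0("criterion 3: J_total (", J_total,
                                       ") < number of TFs (", K, ")"))
  }
  list(identifiable = length(violations) == 0, violations = violations)
}

# E, support and name bookkeeping for a (expr, net) pair. Rows are the network
# genes in expression-matrix order; every network gene must be measured.
nca_design <- function(expr, net) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(net, "reg_network"))
  missing_genes <- setdiff(net$genes, expr$genes)
  if (length(missing_genes)) {
    stop("network gene(s) absent from the expression matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  genes <- expr$genes[expr$genes %in% net$genes]
  tfs <- net$tfs
  support <- matrix(FALSE, length(genes), length(tfs), dimnames = list(genes, tfs))
  support[cbind(match(net$edges$gene, genes), match(net$edges$tf, tfs))] <- TRUE
  list(E = expr$values[genes, , drop = FALSE], support = support,
       genes = genes, tfs = tfs)
}

frob <- function(M) sqrt(sum(M * M))

solve_ls <- function(G, b, ridge = 1e-10) {
  # symmetric positive (semi)definite normal equations with ridge fallback
  out <- tryCatch(solve(G, b), error = function(e) NULL)
  if (is.null(out) || anyNA(out)) {
    warning("rank-deficient least-squares system; applying ridge fallback", call. = FALSE)
    out <- solve(G + diag(ridge, nrow(G)), b)
  }
  out
}

als_once <- function(E, support, tol, max_iter) {
  I <- nrow(E); K <- ncol(support)
  normE <- frob(E)
  S <- matrix(0, I, K)
  S[support] <- stats::rnorm(sum(support))
  A <- matrix(0, K, ncol(E))
  res_hist <- numeric(0)
  prev <- Inf
  converged <- FALSE
  supp_idx <- lapply(seq_len(I), function(i) which(support[i, ]))
  for (it in seq_len(max_iter)) {
    # activity step: full least squares, columns independent
    A <- solve_ls(crossprod(S), crossprod(S, E))
    # strength step: restricted least squares per gene row
    for (i in seq_len(I)) {
      idx <- supp_idx[[i]]
      Ai <- A[idx, , drop = FALSE]
      S[i, idx] <- solve_ls(tcrossprod(Ai), Ai %*% E[i, ])
    }
    res <- frob(E - S %*% A) / normE
    if (!is.finite(res)) stop("non-finite NCA residual at iteration ", it, call. = FALSE)
    res_hist <- c(res_hist, res)
    if (is.finite(prev) && (prev - res) < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- res
  }
  list(S = S, A = A, residual = res_hist[length(res_hist)],
       residual_history = res_hist, n_iter = length(res_hist), converged = converged)
}

#' Fit a Network Component Analysis decomposition
#'
#' Decomposes the (merged, multi-condition) log2-ratio expression matrix into
#' `E ~ S %*% A` where `S` is zero outside the regulatory support and `A`
#' holds one activity row per TF across all columns. Solved by alternating
#' least squares: the non-zero entries of `S` are initialised from standard
#' normal draws, then the activity step (full least squares, columns
#' independent) and the strength step (restricted least squares per gene row)
#' alternate until the relative decrease of the residual falls below `tol`.
#' The best of `n_restarts` random restarts is kept and passed through
#' [normalize_decomposition()].
#'
#' A single strength matrix is shared across all conditions, so relative
#' inter-dose activity amplitudes are preserved in `A`.
#'
#' @param expr An `expr_matrix` (typically from [concat_conditions()]).
#' @param net A `reg_network` providing the support of `S`.
#' @param tol Convergence tolerance on the relative residual decrease.
#' @param max_iter Maximum alternating iterations per restart.
#' @param seed RNG seed; restart r uses `seed + r - 1`.
#' @param n_restarts Number of random restarts; lowest residual wins.
#' @param check How to treat identifiability violations: `"error"`, `"warn"`,
#'   or `"skip"`.
#' @return An object of class `nca_result` with fields `S`, `A`, `support`,
#'   `residual` (relative Frobenius error), `residual_history`, `n_iter`,
#'   `converged`, `identifiability`, plus gene/TF/condition bookkeeping.
#' @export
fit_nca <- function(expr, net, tol = 1e-8, max_iter = 1000, seed = 0,
                    n_restarts = 5, check = c("error", "warn", "skip")) {
  check <- match.arg(check)
  des <- nca_design(expr, net)
  ident <- check_identifiability(des$support, ncol(des$E))
  if (!ident$identifiable && check != "skip") {
    msg <- paste0("support pattern is not identifiable: ",
                  paste(ident$violations, collapse = "; "))
    if (check == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  E <- des$E
  normE <- frob(E)
  if (normE == 0) {
    # degenerate: the zero matrix is reproduced exactly by A = 0
    K <- length(des$tfs)
    res <- structure(list(
      S = matrix(0, nrow(E), K, dimnames = list(des$genes, des$tfs)),
      A = matrix(0, K, ncol(E), dimnames = list(des$tfs, colnames(E))),
      support = des$support, residual = 0, residual_history = 0,
      n_iter = 1L, converged = TRUE, normalized = FALSE,
      identifiability = ident, genes = des$genes, tfs = des$tfs,
      conditions = expr$conditions, grids = expr$grids), class = "nca_result")
    return(res)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1, als_once(E, des$support, tol, max_iter))
    if (is.null(best) || fit$residual < best$residual) best <- fit
  }
  dimnames(best$S) <- list(des$genes, des$tfs)
  dimnames(best$A) <- list(des$tfs, colnames(E))
  res <- structure(c(best, list(support = des$support, identifiability = ident,
                                normalized = FALSE, genes = des$genes, tfs = des$tfs,
                                conditions = expr$conditions, grids = expr$grids)),
                   class = "nca_result")
  normalize_decomposition(res)
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result> ", length(x$genes), " genes x ", length(x$tfs),
      " TFs, ", ncol(x$A), " columns; relative residual ",
      signif(x$residual, 4), " after ", x$n_iter, " iteration(s)",
      if (x$converged) " (converged)" else " (max_iter reached)", "\n", sep = "")
  invisible(x)
}

#' Resolve the NCA scaling ambiguity by the positive-peak, max-1 convention
#'
#' `S %*% A` is invariant under `S -> S D`, `A -> D^-1 A` for diagonal `D`.
#' For each TF row of `A` the sign is flipped (together with the matching `S`
#' column) so that the entry of largest magnitude is positive, then the row is
#' divided by its maximum and the `S` column multiplied by it, so each
#' activity row peaks at exactly 1. The reconstruction is unchanged to machine
#' precision. Idempotent.
#'
#' @param res An `nca_result`.
#' @return The normalised `nca_result`.
#' @export
normalize_decomposition <- function(res) {
  stopifnot(inherits(res, "nca_result"))
  A <- res$A; S <- res$S
  for (k in seq_len(nrow(A))) {
    a <- A[k, ]
    if (all(a == 0)) stop("all-zero activity row for TF ", rownames(A)[k], call. = FALSE)
    peak <- which.max(abs(a))
    if (a[peak] < 0) {
      a <- -a
      S[, k] <- -S[, k]
    }
    m <- max(a)
    A[k, ] <- a / m
    S[, k] <- S[, k] * m
  }
  res$A <- A
  res$S <- S
  res$normalized <- TRUE
  res
}

#' Rank regulon genes by absolute influence strength
#'
#' @param res An `nca_result`.
#' @param tf TF identifier.
#' @param top_n Maximum number of genes returned (>= 1).
#' @return Data frame `(gene, strength)` sorted by decreasing `|strength|`,
#'   ties broken by gene id.
#' @export
influence_ranking <- function(res, tf, top_n = 20) {
  stopifnot(inherits(res, "nca_result"))
  if (!tf %in% res$tfs) stop("unknown TF: ", tf, call. = FALSE)
  if (!is.numeric(top_n) || top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  in_regulon <- res$support[, tf]
  genes <- res$genes[in_regulon]
  strengths <- res$S[in_regulon, tf]
  ord <- order(-abs(strengths), genes)
  out <- data.frame(gene = genes[ord], strength = unname(strengths[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_n)
}

#' Pearson correlation of regulon gene expression with a TF activity profile
#'
#' @param expr The `expr_matrix` used in the fit (columns must match `res$A`).
#' @param res An `nca_result`.
#' @param tf TF identifier.
#' @return Named numeric vector of Pearson r per regulon gene; a zero-variance
#'   expression row yields `NaN` with a warning.
#' @export
gene_tf_correlation <- function(expr, res, tf) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(res, "nca_result"))
  if (!tf %in% res$tfs) stop("unknown TF: ", tf, call. = FALSE)
  if (ncol(res$A) < 3) stop("need at least 3 columns for a correlation", call. = FALSE)
  genes <- res$genes[res$support[, tf]]
  a <- res$A[tf, ]
  out <- vapply(genes, function(g) {
    e <- expr$values[g, ]
    if (stats::sd(e) == 0 || stats::sd(a) == 0) {
      warning("zero-variance series for gene ", g, "; correlation is NaN", call. = FALSE)
      return(NaN)
    }
    stats::cor(e, a)
  }, 0)
  out
}
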