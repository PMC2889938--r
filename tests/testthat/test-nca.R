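# NCA: identifiability checking, alternating-least-squares fitting,
# normalisation conventions, influence ranking and gene-TF correlation.

# Independent identifiability oracle: explicit rank computation on freshly
# drawn random fills (different RNG stream than the implementation's).
oracle_identifiable <- function(support, J_total, reps = 7) {
  K <- ncol(support)
  rank_qr <- function(M) if (any(dim(M) == 0)) 0L else qr(M)$rank
  best1 <- 0L
  best2 <- rep(0L, K)
  for (r in seq_len(reps)) {
    S <- matrix(0, nrow(support), K)
    S[support] <- stats::runif(sum(support), -1, 1)
    best1 <- max(best1, rank_qr(S))
    for (k in seq_len(K)) {
      best2[k] <- max(best2[k], rank_qr(S[!support[, k], -k, drop = FALSE]))
    }
  }
  best1 == K && (K == 1 || all(best2 == K - 1)) && J_total >= K
}

test_that("identifiability criteria match a brute-force rank oracle", {
  # K = 1 degenerate case
  s1 <- matrix(TRUE, 4, 1)
  expect_true(check_identifiability(s1, 1)$identifiable)
  # identical regulons violate criterion 2
  s2 <- matrix(TRUE, 5, 2)
  rep2 <- check_identifiability(s2, 6)
  expect_false(rep2$identifiable)
  expect_true(any(grepl("criterion 2", rep2$violations)))
  # too few samples violates criterion 3
  s3 <- cbind(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE))
  rep3 <- check_identifiability(s3, 1)
  expect_true(any(grepl("criterion 3", rep3$violations)))
  # empty regulon is an error
  expect_error(check_identifiability(cbind(c(TRUE, TRUE), c(FALSE, FALSE)), 5),
               "empty regulon")
  # random small supports agree with the oracle
  set.seed(42)
  for (i in 1:40) {
    I <- sample(3:10, 1); K <- sample(2:3, 1)
    support <- matrix(stats::runif(I * K) < 0.5, I, K)
    support[cbind(seq_len(I), sample.int(K, I, TRUE))] <- TRUE  # no empty rows
    if (any(colSums(support) == 0)) next
    J <- sample(2:6, 1)
    expect_equal(check_identifiability(support, J)$identifiable,
                 oracle_identifiable(support, J),
                 info = paste("case", i))
  }
})

test_that("noiseless synthetic data is recovered exactly up to scale", {
  inst <- gen_nca_instance(small_spec(noise_sd = 0))
  fit <- fit_nca(inst$expr, inst$net, seed = 1)
  expect_lt(fit$residual, 1e-6)
  for (k in seq_len(nrow(fit$A))) {
    expect_gt(abs(cor(fit$A[k, ], inst$A_true[k, ])), 0.999)
  }
  # strengths recovered up to the row scaling absorbed by normalisation
  expect_equal(fit$S != 0, inst$S_true != 0)
})

test_that("ALS residual history is non-increasing and the zero matrix is exact", {
  inst <- gen_nca_instance(small_spec(noise_sd = 0.2))
  fit <- fit_nca(inst$expr, inst$net, seed = 2)
  expect_true(all(diff(fit$residual_history) <= 1e-12))
  expect_true(all(fit$S[!fit$support] == 0))
  expect_true(fit$residual >= 0 && fit$residual <= 1)

  zero <- expression_matrix(matrix(0, 3, 4), c("g1", "g2", "g3"), "c",
                            list(c = c(0, 1, 2, 3)))
  net <- regulatory_network(data.frame(tf = "T1", gene = c("g1", "g2", "g3")))
  zfit <- fit_nca(zero, net)
  expect_equal(zfit$residual, 0)
  expect_equal(zfit$n_iter, 1L)
  expect_true(zfit$converged)
  expect_true(all(zfit$S %*% zfit$A == 0))
})

test_that("K = 1 with full support attains the rank-1 SVD error", {
  set.seed(9)
  E <- matrix(rnorm(8 * 6), 8, 6)
  genes <- sprintf("g%d", 1:8)
  expr <- expression_matrix(E, genes, "c", list(c = c(0, 1, 2, 3, 4, 5)))
  net <- regulatory_network(data.frame(tf = "T1", gene = genes))
  fit <- fit_nca(expr, net, seed = 0)
  sv <- svd(E)
  best_rank1 <- sqrt(sum(sv$d[-1]^2)) / sqrt(sum(sv$d^2))
  expect_equal(fit$residual, best_rank1, tolerance = 1e-7)
})

test_that("fit is equivariant under gene-row permutation", {
  inst <- gen_nca_instance(small_spec(noise_sd = 0))
  fit1 <- fit_nca(inst$expr, inst$net, seed = 4)
  perm <- rev(seq_along(inst$expr$genes))
  expr_p <- expression_matrix(inst$expr$values[perm, ], inst$expr$genes[perm],
                              inst$expr$conditions, inst$expr$grids)
  fit2 <- fit_nca(expr_p, inst$net, seed = 4)
  expect_equal(fit2$A, fit1$A, tolerance = 1e-5)
  expect_equal(fit2$S[inst$expr$genes, ], fit1$S, tolerance = 1e-5)
})

test_that("normalisation resolves scale and sign without changing the product", {
  inst <- gen_nca_instance(small_spec(noise_sd = 0.1, seed = 8))
  fit <- fit_nca(inst$expr, inst$net, seed = 0)
  # every activity row peaks at exactly 1
  expect_equal(unname(apply(fit$A, 1, max)), rep(1, nrow(fit$A)))
  # idempotence
  again <- normalize_decomposition(fit)
  expect_identical(again$A, fit$A)
  expect_identical(again$S, fit$S)
  # an all-negative activity row is flipped to a positive peak
  res <- fit
  res$A[1, ] <- -abs(res$A[1, ]) - 0.1
  res2 <- normalize_decomposition(res)
  expect_equal(max(res2$A[1, ]), 1)
  prod_before <- res$S %*% res$A
  prod_after <- res2$S %*% res2$A
  expect_lt(max(abs(prod_before - prod_after)) / max(abs(prod_before)), 1e-10)
})

test_that("influence ranking orders by absolute strength with lexicographic ties", {
  inst <- gen_nca_instance(small_spec(noise_sd = 0))
  fit <- fit_nca(inst$expr, inst$net, seed = 1)
  # hand-crafted strengths on a copy
  res <- fit
  res$support[, ] <- FALSE
  res$support[1:3, 1] <- TRUE
  res$S[, ] <- 0
  res$S[1:3, 1] <- c(2, -3, 0.5)
  rk <- influence_ranking(res, res$tfs[1], top_n = 2)
  expect_equal(rk$gene, res$genes[c(2, 1)])
  expect_equal(rk$strength, c(-3, 2))
  expect_equal(nrow(influence_ranking(res, res$tfs[1], top_n = 20)), 3)
  expect_error(influence_ranking(res, res$tfs[1], top_n = 0), "top_n")
  # planted ordering is recovered at zero noise
  tf <- "NFKB"
  true_order <- order(-abs(inst$S_true[, tf]))
  regulon <- which(inst$S_true[, tf] != 0)
  top <- influence_ranking(fit, tf, top_n = 5)
  planted_top <- rownames(inst$S_true)[intersect(true_order, regulon)][1:5]
  expect_setequal(top$gene, planted_top)
})

test_that("gene-TF correlations are exact for log-linear constructions", {
  inst <- gen_nca_instance(synthetic_spec(n_genes = 6, n_tfs = 1, n_edges = 6,
                                          noise_sd = 0, seed = 2,
                                          conditions = "c1", amplitudes = 1,
                                          sign_prob = 1))
  fit <- fit_nca(inst$expr, inst$net, seed = 0)
  r <- gene_tf_correlation(inst$expr, fit, "NFKB")
  expect_true(all(r > 1 - 1e-8))
  # negated row correlates at -1; zero-variance row yields NaN with a warning
  vals <- inst$expr$values
  vals[2, ] <- -vals[1, ]
  vals[3, ] <- 1.5
  expr2 <- expression_matrix(vals, inst$expr$genes, inst$expr$conditions, inst$expr$grids)
  expect_warning(r2 <- gene_tf_correlation(expr2, fit, "NFKB"), "zero-variance")
  expect_equal(unname(r2[2]), -unname(r2[1]))
  expect_true(is.nan(r2[3]))
})
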