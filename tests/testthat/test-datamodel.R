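# Containers and TSV round trips for expression matrices and networks.

make_expr_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("wide-TSV expression parsing recovers genes, conditions and grids", {
  path <- make_expr_tsv(c(
    "gene_id\tc1@0\tc1@2",
    "g1\t0.5\t1.25",
    "g2\t-1\t0",
    "g3\t2\t-0.5"))
  e <- read_expression(path)
  expect_s3_class(e, "expr_matrix")
  expect_equal(e$genes, c("g1", "g2", "g3"))
  expect_equal(e$conditions, "c1")
  expect_equal(e$grids$c1, c(0, 2))
  expect_equal(unname(e$values[2, ]), c(-1, 0))
})

test_that("expression validation rejects malformed inputs", {
  expect_error(read_expression(make_expr_tsv(c(
    "gene_id\tc1@0\tc1@2", "g1\t0\t1", "g1\t1\t2"))), "duplicate gene.*g1")
  expect_error(read_expression(make_expr_tsv(c(
    "gene_id\tc1@0\tc1@zz", "g1\t0\t1"))), "time token")
  expect_error(read_expression(make_expr_tsv(c(
    "gene_id\tc1@0\tc1@2", "g1\t0\t1", "g2\t1"))), ".")  # ragged row
  expect_error(read_expression(make_expr_tsv(c(
    "gene_id\tc1@0\tc1@2", "g1\t0\tfoo"))), "non-numeric")
  expect_error(read_expression(make_expr_tsv(c(
    "gene_id\tc1@0\tc2@1\tc1@2", "g1\t0\t1\t2"))), "contiguous")
  # NaN policy: fail by default, gene-wise removal on request
  nan_path <- make_expr_tsv(c("gene_id\tc1@0\tc1@2", "g1\t0\tNaN", "g2\t1\t2"))
  expect_error(read_expression(nan_path), "missing values.*g1")
  e <- read_expression(nan_path, drop_na_genes = TRUE)
  expect_equal(e$genes, "g2")
})

test_that("expression write/read round trip is the identity", {
  sp <- synthetic_spec(seed = 11)
  inst <- gen_nca_instance(sp)
  expect_equal(dim(inst$expr$values), c(54, 18))
  path <- tempfile(fileext = ".tsv")
  write_expression(inst$expr, path)
  back <- read_expression(path)
  expect_identical(back$genes, inst$expr$genes)
  expect_identical(back$conditions, inst$expr$conditions)
  expect_equal(back$grids, inst$expr$grids)
  expect_identical(back$values, inst$expr$values)
})

test_that("network parsing, deduplication and validation behave as specified", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# curated edges", "tf_id\tgene_id\tsign",
               "T1\tg1\t1", "T1\tg2\t-1", "T2\tg1\t0", "T2\tg3\t1",
               "T1\tg1\t1"), path)
  net <- read_network(path)
  expect_equal(length(net$tfs), 2)
  expect_equal(nrow(net$edges), 4)

  writeLines(c("tf_id\tgene_id\tsign", "T1\tg1\t1", "T1\tg1\t-1"), path)
  expect_error(read_network(path), "conflicting signs")
  writeLines(c("tf_id\tgene_id", "T1\tT1"), path)
  expect_error(read_network(path), "self-loop")
  # missing sign column defaults to 0
  writeLines(c("tf_id\tgene_id", "T1\tg1"), path)
  expect_equal(read_network(path)$edges$sign, 0L)
})

test_that("network round trip preserves the paper-scale edge count", {
  inst <- gen_nca_instance(synthetic_spec(seed = 5))
  expect_equal(nrow(inst$net$edges), 77)
  expect_equal(length(unique(inst$net$edges$gene)), 54)
  expect_equal(length(inst$net$tfs), 3)
  path <- tempfile(fileext = ".tsv")
  write_network(inst$net, path)
  back <- read_network(path)
  expect_identical(back$edges, inst$net$edges)
})

test_that("filter_expressed removes exactly the sub-threshold genes and is idempotent", {
  sp <- synthetic_spec(n_genes = 20, n_tfs = 2, n_edges = 28, noise_sd = 0,
                       seed = 7, conditions = "c1", amplitudes = 1)
  inst <- gen_nca_instance(sp)
  # threshold 0 is the identity
  flt0 <- filter_expressed(inst$expr, inst$net, 0)
  expect_identical(flt0$expr$values, inst$expr$values)
  expect_identical(flt0$net$edges, inst$net$edges)
  # inject known noise-only genes below threshold 1.0
  vals <- inst$expr$values
  quiet <- c("G003", "G011")
  vals[quiet, ] <- 0.05
  loud <- setdiff(rownames(vals)[apply(abs(vals), 1, max) >= 1], quiet)
  expr2 <- expression_matrix(vals, inst$expr$genes, inst$expr$conditions, inst$expr$grids)
  flt <- filter_expressed(expr2, inst$net, 1.0)
  expect_setequal(flt$expr$genes, loud)
  expect_false(any(flt$net$edges$gene %in% quiet))
  expect_true(all(table(flt$net$edges$tf) >= 1))
  # idempotence at a fixed threshold
  flt_again <- filter_expressed(flt$expr, flt$net, 1.0)
  expect_identical(flt_again$expr$values, flt$expr$values)
  expect_identical(flt_again$net$edges, flt$net$edges)
  # all genes removed is an error
  expect_error(filter_expressed(expr2, inst$net, 1e6), "empty model")
})

test_that("concat_conditions aligns genes, keeps grids, and is associative", {
  sp <- function(cc, seed) synthetic_spec(n_genes = 8, n_tfs = 2, n_edges = 11,
                                          conditions = cc, amplitudes = 1,
                                          seed = seed, noise_sd = 0)
  e1 <- gen_nca_instance(sp("a", 1))$expr
  e2 <- gen_nca_instance(sp("b", 1))$expr
  e3 <- gen_nca_instance(sp("c", 1))$expr
  # single input is the identity
  expect_identical(concat_conditions(list(e1)), e1)
  merged <- concat_conditions(list(e1, e2, e3))
  expect_equal(ncol(merged$values), 18)
  expect_equal(merged$conditions, c("a", "b", "c"))
  # permuted gene order is aligned to the first input
  perm <- sample(seq_along(e2$genes))
  e2p <- expression_matrix(e2$values[perm, ], e2$genes[perm], e2$conditions, e2$grids)
  merged_p <- concat_conditions(list(e1, e2p))
  expect_identical(merged_p$values[, 7:12], e2$values[e1$genes, ])
  # associativity over condition blocks
  left <- concat_conditions(list(concat_conditions(list(e1, e2)), e3))
  expect_identical(left$values, merged$values)
  # mismatched gene sets report the symmetric difference
  e_bad <- expression_matrix(e1$values[-1, ], e1$genes[-1], "z", stats::setNames(e1$grids, "z"))
  expect_error(concat_conditions(list(e1, e_bad)), "G001")
  expect_error(concat_conditions(list(e1, e1)), "disjoint")
})
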