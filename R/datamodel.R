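# Core containers and tab-delimited readers/writers: time grids, multi-condition
# expression matrices (log2 ratios), and bipartite TF -> gene regulatory networks.

#' Validate a sampling-time grid
#'
#' A time grid is a strictly increasing numeric vector of sampling times in
#' hours, starting at or after 0, with at least two points.
#'
#' @param times Numeric vector of times in hours.
#' @return The validated grid as a plain numeric vector.
#' @export
time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2) {
    stop("a time grid needs at least two numeric times", call. = FALSE)
  }
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("time grid contains non-finite times", call. = FALSE)
  if (times[1] < 0) stop("time grid must start at a non-negative time", call. = FALSE)
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  times
}

#' Construct a multi-condition expression matrix
#'
#' Holds log2-ratio expression values for I genes across one or more stimulus
#' conditions, each condition sampled on its own time grid. Columns are ordered
#' condition-by-condition and labelled `<condition>@<time_h>`.
#'
#' @param values Numeric matrix, genes x total time points (log2 ratios).
#' @param genes Character vector of unique gene identifiers (rows).
#' @param conditions Character vector of condition labels, in column-block order.
#' @param grids Named list (by condition) of time grids, see [time_grid()].
#' @param drop_na_genes If `TRUE`, rows containing missing values are removed;
#'   the default is to fail validation on any `NA`/`NaN`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, genes, conditions, grids, drop_na_genes = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  genes <- as.character(genes)
  conditions <- as.character(conditions)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (nrow(values) != length(genes)) stop("row count does not match gene ids", call. = FALSE)
  if (anyDuplicated(conditions)) stop("duplicate condition labels", call. = FALSE)
  if (!all(conditions %in% names(grids))) stop("every condition needs a time grid", call. = FALSE)
  grids <- lapply(grids[conditions], time_grid)
  if (ncol(values) != sum(lengths(grids))) {
    stop("column count (", ncol(values), ") does not equal the sum of grid lengths (",
         sum(lengths(grids)), ")", call. = FALSE)
  }
  if (anyNA(values)) {
    if (!drop_na_genes) {
      bad <- genes[apply(is.na(values), 1, any)]
      stop("missing values in gene(s): ", paste(utils::head(bad, 5), collapse = ", "),
           " (set drop_na_genes = TRUE to remove them)", call. = FALSE)
    }
    keep <- !apply(is.na(values), 1, any)
    if (!any(keep)) stop("all genes removed by NA filtering", call. = FALSE)
    values <- values[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  labels <- unlist(lapply(conditions, function(cc) paste0(cc, "@", as.character(grids[[cc]]))),
                   use.names = FALSE)
  dimnames(values) <- list(genes, labels)
  structure(list(genes = genes, conditions = conditions, grids = grids, values = values),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", length(x$genes), " genes x ", ncol(x$values),
      " columns (", length(x$conditions), " condition(s): ",
      paste(x$conditions, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Column indices of one condition block.
condition_columns <- function(expr, condition) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!condition %in% expr$conditions) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  sizes <- lengths(expr$grids)
  offset <- cumsum(c(0, sizes))[match(condition, expr$conditions)]
  offset + seq_len(sizes[[condition]])
}

#' Read a wide-TSV expression matrix
#'
#' Expected layout: first column `gene_id`; remaining headers `<condition>@<time_h>`
#' (for example `lps0.01@2`), grouped by condition with strictly increasing times
#' inside each condition block. Values are decimal log2 ratios.
#'
#' @param path Path to a tab-delimited file.
#' @param drop_na_genes Passed to [expression_matrix()].
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, drop_na_genes = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2) stop("expression file needs a gene_id column plus data columns", call. = FALSE)
  if (names(df)[1] != "gene_id") stop("first column header must be 'gene_id'", call. = FALSE)
  headers <- names(df)[-1]
  parsed <- regmatches(headers, regexec("^(.+)@([^@]+)$", headers))
  bad <- headers[lengths(parsed) != 3]
  if (length(bad)) {
    stop("column header(s) not of the form <condition>@<time_h>: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  conds <- vapply(parsed, `[`, "", 2)
  times <- suppressWarnings(as.numeric(vapply(parsed, `[`, "", 3)))
  if (anyNA(times)) {
    stop("unparseable time token in header(s): ",
         paste(headers[is.na(times)], collapse = ", "), call. = FALSE)
  }
  # condition blocks must be contiguous
  rle_conds <- rle(conds)$values
  if (anyDuplicated(rle_conds)) {
    stop("columns of each condition must be contiguous", call. = FALSE)
  }
  grids <- lapply(split(times, factor(conds, levels = rle_conds)), time_grid)
  chr <- as.matrix(df[-1])
  vals <- suppressWarnings(matrix(as.numeric(chr), nrow = nrow(chr)))
  nonnum <- is.na(vals) & !(is.na(chr) | chr %in% c("NA", "NaN"))
  if (any(nonnum)) {
    stop("non-numeric expression value(s) in ", path, ": ",
         paste(utils::head(unique(chr[nonnum]), 3), collapse = ", "), call. = FALSE)
  }
  expression_matrix(vals, genes = df$gene_id, conditions = rle_conds,
                    grids = grids, drop_na_genes = drop_na_genes)
}

#' Write an expression matrix as wide TSV
#'
#' Inverse of [read_expression()]; round-trips exactly.
#'
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  header <- paste(c("gene_id", colnames(expr$values)), collapse = "\t")
  body <- vapply(seq_along(expr$genes), function(i) {
    paste(c(expr$genes[i], sprintf("%.17g", expr$values[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct a TF -> gene regulatory network
#'
#' The edge set defines the support (allowed non-zeros) of the NCA influence
#' strength matrix. Signs are advisory: +1 activation, -1 repression, 0 unknown.
#'
#' @param edges Data frame with columns `tf`, `gene` and optionally `sign`.
#' @return An object of class `reg_network` with fields `tfs`, `genes`, `edges`.
#' @export
regulatory_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("tf", "gene") %in% names(edges))) {
    stop("edges need 'tf' and 'gene' columns", call. = FALSE)
  }
  if (is.null(edges$sign)) edges$sign <- 0L
  edges <- edges[, c("tf", "gene", "sign")]
  edges$tf <- as.character(edges$tf)
  edges$gene <- as.character(edges$gene)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) == 0) stop("network has no edges", call. = FALSE)
  if (any(!nzchar(edges$tf)) || any(!nzchar(edges$gene))) {
    stop("empty tf or gene field in edge list", call. = FALSE)
  }
  if (any(edges$tf == edges$gene)) {
    stop("self-loop edge(s): ", paste(unique(edges$tf[edges$tf == edges$gene]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(edges$sign %in% c(-1L, 0L, 1L))) stop("sign must be -1, 0 or +1", call. = FALSE)
  key <- paste(edges$tf, edges$gene, sep = "\r")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      s <- unique(edges$sign[key == k])
      if (length(s) > 1) {
        stop("conflicting signs for repeated edge ", sub("\r", " -> ", k), call. = FALSE)
      }
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(tfs = unique(edges$tf), genes = unique(edges$gene), edges = edges),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat("<reg_network> ", length(x$tfs), " TF(s), ", length(x$genes), " gene(s), ",
      nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

#' Read a regulatory-network TSV
#'
#' Tab-delimited with header `tf_id<TAB>gene_id[<TAB>sign]`; `#` starts a
#' comment line. A missing sign column means sign 0 (unknown).
#'
#' @param path Path to the edge-list file.
#' @return A `reg_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character", fill = FALSE)
  if (!all(c("tf_id", "gene_id") %in% names(df))) {
    stop("network file needs 'tf_id' and 'gene_id' columns", call. = FALSE)
  }
  edges <- data.frame(tf = df$tf_id, gene = df$gene_id, stringsAsFactors = FALSE)
  if ("sign" %in% names(df)) {
    sgn <- suppressWarnings(as.integer(df$sign))
    if (anyNA(sgn)) stop("unparseable sign value(s) in ", path, call. = FALSE)
    edges$sign <- sgn
  }
  regulatory_network(edges)
}

#' Write a regulatory network as TSV
#' @param net A `reg_network`.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  lines <- c("tf_id\tgene_id\tsign",
             sprintf("%s\t%s\t%d", net$edges$tf, net$edges$gene, net$edges$sign))
  writeLines(lines, path)
  invisible(path)
}

#' Filter weakly expressed target genes
#'
#' Removes genes whose maximum absolute log2 ratio over all columns is below
#' `min_abs_logratio`, drops their regulatory edges, and drops TFs left without
#' edges. The default threshold of 1.0 corresponds to a two-fold change.
#'
#' @param expr An `expr_matrix`.
#' @param net A `reg_network`.
#' @param min_abs_logratio Non-negative threshold on max |log2 ratio|.
#' @return List with elements `expr` and `net`, mutually consistent.
#' @export
filter_expressed <- function(expr, net, min_abs_logratio = 1) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(net, "reg_network"))
  if (!is.numeric(min_abs_logratio) || min_abs_logratio < 0) {
    stop("min_abs_logratio must be >= 0", call. = FALSE)
  }
  keep <- apply(abs(expr$values), 1, max) >= min_abs_logratio
  if (!any(keep)) stop("all genes fall below the expression threshold (empty model)", call. = FALSE)
  expr2 <- expression_matrix(expr$values[keep, , drop = FALSE], expr$genes[keep],
                             expr$conditions, expr$grids)
  edges <- net$edges[net$edges$gene %in% expr2$genes, , drop = FALSE]
  if (nrow(edges) == 0) stop("no regulatory edges remain after filtering", call. = FALSE)
  rownames(edges) <- NULL
  list(expr = expr2, net = regulatory_network(edges))
}

#' Merge per-condition expression matrices column-wise
#'
#' All inputs must share the same gene set (order may differ; rows are aligned
#' to the first input) and carry disjoint condition labels. Used to assemble
#' the expanded multi-dose matrix fitted jointly by NCA.
#'
#' @param exprs List of `expr_matrix` objects.
#' @return A single merged `expr_matrix`.
#' @export
concat_conditions <- function(exprs) {
  if (inherits(exprs, "expr_matrix")) exprs <- list(exprs)
  stopifnot(length(exprs) >= 1, all(vapply(exprs, inherits, TRUE, "expr_matrix")))
  if (length(exprs) == 1) return(exprs[[1]])
  ref <- exprs[[1]]
  for (i in seq_along(exprs)[-1]) {
    miss <- setdiff(ref$genes, exprs[[i]]$genes)
    extra <- setdiff(exprs[[i]]$genes, ref$genes)
    if (length(miss) || length(extra)) {
      stop("gene sets differ between inputs 1 and ", i, "; only in 1: {",
           paste(miss, collapse = ", "), "}, only in ", i, ": {",
           paste(extra, collapse = ", "), "}", call. = FALSE)
    }
  }
  conds <- unlist(lapply(exprs, `[[`, "conditions"), use.names = FALSE)
  if (anyDuplicated(conds)) {
    stop("condition labels must be disjoint across inputs; repeated: ",
         paste(unique(conds[duplicated(conds)]), collapse = ", "), call. = FALSE)
  }
  vals <- do.call(cbind, lapply(exprs, function(e) e$values[ref$genes, , drop = FALSE]))
  grids <- do.call(c, lapply(exprs, `[[`, "grids"))
  expression_matrix(vals, ref$genes, conds, grids)
}
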