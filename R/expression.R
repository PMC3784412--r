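#' Construct an expression matrix with detection calls
#'
#' Couples a genes x samples matrix of log2 intensities with a congruent
#' matrix of Present/Marginal/Absent detection calls and a sample sheet.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param calls character matrix over `{"P","M","A"}`, same dimnames.
#' @param samples data frame with columns `sample_id`, `tissue`,
#'   `timepoint`, `replicate`; one row per column of `values`.
#' @return an `expression_matrix` (list of the three parts)
#' @export
expression_matrix <- function(values, calls, samples) {
  stopifnot(is.matrix(values), is.matrix(calls),
            identical(dim(values), dim(calls)),
            identical(rownames(values), rownames(calls)),
            identical(colnames(values), colnames(calls)))
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "timepoint", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (!identical(as.character(samples$sample_id), colnames(values))) {
    stop("sample sheet must match matrix columns in order")
  }
  bad <- !calls %in% c("P", "M", "A")
  if (any(bad)) stop("detection calls must be P, M or A")
  structure(list(values = values, calls = calls, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d tissue(s))\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$tissue))))
  invisible(x)
}

#' Remove genes with too few Present calls
#'
#' A pairwise correlation needs at least 5 values, so genes with fewer than
#' `k` Present detection calls across all samples are dropped.
#'
#' @param m an [expression_matrix()]
#' @param k minimum number of Present calls (default 5)
#' @return the filtered `expression_matrix`
#' @export
filter_min_present <- function(m, k = 5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (k > ncol(m$values)) stop("k exceeds the number of samples")
  keep <- rowSums(m$calls == "P") >= k
  expression_matrix(m$values[keep, , drop = FALSE],
                    m$calls[keep, , drop = FALSE], m$samples)
}

#' Log2-transform raw intensities
#'
#' @param x raw intensity values (matrix or vector)
#' @param floor values below `floor` are clamped up before the log; a floor
#'   of 1 maps them to 0
#' @return elementwise `log2(pmax(x, floor))`
#' @export
log2_transform <- function(x, floor = 1) {
  if (floor <= 0) stop("floor must be positive")
  log2(pmax(x, floor))
}

#' Per-tissue expressed calls
#'
#' A gene is called expressed in a tissue when its transcript is Present in
#' replicates of that tissue: in all of them (default, the conservative
#' both-replicates rule) or in at least one (`rule = "any"`).
#'
#' @param m an [expression_matrix()]
#' @param tissue tissue name as in the sample sheet
#' @param rule `"all"` or `"any"`
#' @return named logical vector over genes
#' @export
expressed_in_tissue <- function(m, tissue, rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(m, "expression_matrix"))
  cols <- which(m$samples$tissue == tissue)
  if (!length(cols)) stop("unknown tissue: ", tissue)
  p <- m$calls[, cols, drop = FALSE] == "P"
  if (rule == "all") rowSums(p) == length(cols) else rowSums(p) > 0
}

#' Pairwise expression correlation of two genes
#'
#' @param m an [expression_matrix()]
#' @param gene_a,gene_b gene ids
#' @param method `"spearman"` (default) or `"pearson"`
#' @return correlation in `[-1, 1]`, or `NA` if either profile has zero
#'   variance
#' @export
pairwise_correlation <- function(m, gene_a, gene_b,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expression_matrix"))
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(m$values)) stop("gene not in matrix: ", g)
  }
  a <- m$values[gene_a, ]
  b <- m$values[gene_b, ]
  if (length(a) < 5) stop("at least 5 samples are needed for the correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = method)
}

#' Read / write an expression matrix
#'
#' Values and calls are genes x samples TSVs with identical layout (first
#' column `gene_id`); the sample sheet is a TSV with columns `sample_id`,
#' `tissue`, `timepoint`, `replicate`.
#'
#' @param values_path,calls_path,samples_path file paths
#' @return an `expression_matrix`
#' @export
read_expression <- function(values_path, calls_path, samples_path) {
  v <- utils::read.delim(values_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cl <- utils::read.delim(calls_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  values <- as.matrix(v[, -1, drop = FALSE])
  rownames(values) <- v[[1]]
  calls <- as.matrix(cl[, -1, drop = FALSE])
  rownames(calls) <- cl[[1]]
  expression_matrix(values, calls, samples)
}

#' @rdname read_expression
#' @param m matrix to write
#' @export
write_expression <- function(m, values_path, calls_path, samples_path) {
  .write_gene_table <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_gene_table(m$values, values_path)
  .write_gene_table(m$calls, calls_path)
  utils::write.table(m$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}
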