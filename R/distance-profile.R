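#' Co-expression as a function of genomic distance
#'
#' For every pair of genes on the same chromosome whose start sites are less
#' than `max_dist` apart, the pairwise expression correlation contributes to
#' the half-open distance bin `[lo, hi)` containing the start-site distance
#' (a pair 351 kb apart lands in the 350-360 kb bin at the default width).
#' Pairs with an undefined (zero-variance) correlation are dropped from both
#' numerator and denominator.
#'
#' @param m a filtered [expression_matrix()]
#' @param ann an ordered, overlap-resolved [genome_annotation()]
#' @param bin_width bin width in bp (default 10 kb)
#' @param max_dist largest start-site distance considered (default 60 Mb)
#' @param method correlation method, `"spearman"` or `"pearson"`
#' @return data frame `(bin_lo, bin_hi, mean_corr, n_pairs)` covering
#'   `[0, max_dist)`; empty bins have `n_pairs = 0` and `NA` mean
#' @export
binned_distance_correlation <- function(m, ann, bin_width = 1e4,
                                        max_dist = 6e7,
                                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (bin_width <= 0) stop("bin_width must be positive")
  stopifnot(inherits(m, "expression_matrix"), inherits(ann, "genome_annotation"))
  genes <- ann[ann$gene_id %in% rownames(m$values), , drop = FALSE]
  n_bins <- ceiling(max_dist / bin_width)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  z <- .standardize_profiles(m$values[genes$gene_id, , drop = FALSE], method)
  for (chr in unique(genes$chrom)) {
    on_chr <- which(genes$chrom == chr)
    if (length(on_chr) < 2) next
    zc <- z[on_chr, , drop = FALSE]
    starts <- genes$start[on_chr]
    cc <- tcrossprod(zc)
    dd <- abs(outer(starts, starts, "-"))
    up <- upper.tri(cc)
    corr <- cc[up]
    dist <- dd[up]
    keep <- !is.na(corr) & dist < max_dist
    if (!any(keep)) next
    bin <- floor(dist[keep] / bin_width) + 1
    sums <- sums + unname(.bin_sum(corr[keep], bin, n_bins))
    counts <- counts + unname(.bin_sum(rep(1, sum(keep)), bin, n_bins))
  }
  data.frame(bin_lo = (seq_len(n_bins) - 1) * bin_width,
             bin_hi = seq_len(n_bins) * bin_width,
             mean_corr = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = as.integer(counts))
}

.bin_sum <- function(x, bin, n_bins) {
  out <- numeric(n_bins)
  agg <- rowsum(x, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Different-chromosome co-expression baseline
#'
#' Mean pairwise correlation over gene pairs on different chromosomes: the
#' horizontal reference line of the distance profile. When the number of
#' cross-chromosome pairs is at most `max_pairs` the exhaustive mean is
#' computed in closed form; otherwise `max_pairs` pairs are sampled
#' uniformly (seeded) and the estimate is reported with its standard error.
#'
#' @inheritParams binned_distance_correlation
#' @param max_pairs cap above which pairs are subsampled (default 2e6)
#' @param seed RNG seed for the subsample
#' @return list `(mean_corr, se, n_pairs, sampled)`
#' @export
cross_chromosome_baseline <- function(m, ann, method = c("spearman", "pearson"),
                                      max_pairs = 2e6, seed = 1) {
  method <- match.arg(method)
  genes <- ann[ann$gene_id %in% rownames(m$values), , drop = FALSE]
  if (length(unique(genes$chrom)) < 2) {
    stop("baseline needs genes on at least 2 chromosomes")
  }
  z <- .standardize_profiles(m$values[genes$gene_id, , drop = FALSE], method)
  ok <- !is.na(z[, 1])
  z <- z[ok, , drop = FALSE]
  chrom <- genes$chrom[ok]
  n_per <- table(chrom)
  n <- nrow(z)
  total_pairs <- (n^2 - sum(n_per^2)) / 2
  if (total_pairs <= 0) stop("no cross-chromosome pairs with defined correlation")
  if (total_pairs <= max_pairs) {
    # sum of all pairwise correlations = (||colsum||^2 - n) / 2 per group
    all_sum <- (sum(colSums(z)^2) - n) / 2
    within <- sum(vapply(split(seq_len(n), chrom), function(i) {
      (sum(colSums(z[i, , drop = FALSE])^2) - length(i)) / 2
    }, numeric(1)))
    return(list(mean_corr = (all_sum - within) / total_pairs, se = NA_real_,
                n_pairs = total_pairs, sampled = FALSE))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  got <- 0
  acc <- numeric(0)
  while (got < max_pairs) {
    take <- min(max_pairs - got, 5e5)
    i <- sample.int(n, 2 * take, replace = TRUE)
    a <- i[seq_len(take)]
    b <- i[seq.int(take + 1, 2 * take)]
    cross <- chrom[a] != chrom[b]
    if (!any(cross)) next
    acc <- c(acc, rowSums(z[a[cross], , drop = FALSE] * z[b[cross], , drop = FALSE]))
    got <- got + sum(cross)
  }
  acc <- acc[seq_len(max_pairs)]
  list(mean_corr = mean(acc), se = stats::sd(acc) / sqrt(length(acc)),
       n_pairs = length(acc), sampled = TRUE)
}

# keep caller RNG state untouched by seeded internals
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Plot a distance-correlation profile
#'
#' Fig-style diagnostic: circle area proportional to the number of pairs per
#' bin, with the different-chromosome baseline as a horizontal line.
#'
#' @param profile output of [binned_distance_correlation()]
#' @param baseline optional output of [cross_chromosome_baseline()]
#' @return a ggplot object
#' @export
plot_distance_profile <- function(profile, baseline = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- profile[profile$n_pairs > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lo / 1000,
                                        y = .data$mean_corr,
                                        size = .data$n_pairs)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_size_area() +
    ggplot2::labs(x = "genomic distance (kb)", y = "mean correlation",
                  size = "gene pairs")
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline$mean_corr,
                                 colour = "red")
  }
  p
}
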