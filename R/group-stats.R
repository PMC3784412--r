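#' Compare two score distributions
#'
#' Thin wrapper pairing the Wilcoxon rank-sum test (continuity-corrected on
#' the normal-approximation path) with the two-sample Kolmogorov-Smirnov
#' test, the standard pair for asking whether two gene sets' scores differ
#' in location and in distribution.
#'
#' @param sample_a,sample_b numeric samples (missing values removed; each
#'   needs at least 3 observations)
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @param exact passed to [stats::wilcox.test()]; `NULL` (default) uses the
#'   exact null for small tie-free samples
#' @return list `(wilcoxon_stat, wilcoxon_p, ks_stat, ks_p)`
#' @export
compare_distributions <- function(sample_a, sample_b,
                                  alternative = "two.sided", exact = NULL) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    stop("each sample needs at least 3 non-missing values")
  }
  w <- stats::wilcox.test(sample_a, sample_b, alternative = alternative,
                          correct = TRUE, exact = exact)
  k <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                       alternative = alternative))
  list(wilcoxon_stat = unname(w$statistic), wilcoxon_p = w$p.value,
       ks_stat = unname(k$statistic), ks_p = k$p.value)
}

#' Hub enrichment between two gene sets
#'
#' Chi-square test on the 2x2 table of hub status (at least `hub_min` known
#' protein interactions) against set membership.
#'
#' @param interaction_counts named numeric vector, gene -> number of known
#'   protein interactions
#' @param set_a,set_b character vectors of gene ids (disjoint sets)
#' @param hub_min interactions needed to call a gene a hub (default 10)
#' @param correct apply Yates continuity correction (default `FALSE`)
#' @return list `(table, statistic, p)` with the 2x2 hub-by-set table
#' @export
hub_enrichment <- function(interaction_counts, set_a, set_b, hub_min = 10,
                           correct = FALSE) {
  if (!length(set_a) || !length(set_b)) stop("gene sets must be non-empty")
  miss <- setdiff(c(set_a, set_b), names(interaction_counts))
  if (length(miss)) stop("no interaction count for: ",
                         paste(miss, collapse = ", "))
  hub <- function(g) interaction_counts[g] >= hub_min
  tab <- rbind(a = c(hub = sum(hub(set_a)), non_hub = sum(!hub(set_a))),
               b = c(hub = sum(hub(set_b)), non_hub = sum(!hub(set_b))))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value)
}

#' Compare best TNS across regulation classes
#'
#' One row per unordered pair of gene classes (for example up-, down- and
#' un-regulated genes between two developmental stages), comparing their
#' best-TNS distributions with [compare_distributions()].
#'
#' @param best_tns named numeric vector of per-gene best TNS (or the data
#'   frame from [best_tns_per_gene()])
#' @param classes named character/factor vector, gene -> class label;
#'   classes must be disjoint by construction (one label per gene)
#' @return data frame with columns `class_a`, `class_b`, `n_a`, `n_b`, the
#'   test statistics and p-values
#' @export
tns_by_regulation_class <- function(best_tns, classes) {
  if (is.data.frame(best_tns)) {
    best_tns <- stats::setNames(best_tns$best_tns, best_tns$gene_id)
  }
  classes <- classes[names(classes) %in% names(best_tns)]
  lv <- sort(unique(as.character(classes)))
  if (length(lv) < 2) {
    return(data.frame(class_a = character(0), class_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      wilcoxon_stat = numeric(0), wilcoxon_p = numeric(0),
                      ks_stat = numeric(0), ks_p = numeric(0)))
  }
  pairs <- utils::combn(lv, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- best_tns[names(classes)[classes == pairs[1, j]]]
    b <- best_tns[names(classes)[classes == pairs[2, j]]]
    res <- compare_distributions(a, b)
    data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
               n_a = length(a), n_b = length(b),
               wilcoxon_stat = res$wilcoxon_stat, wilcoxon_p = res$wilcoxon_p,
               ks_stat = res$ks_stat, ks_p = res$ks_p,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname hub_enrichment
#' @param path TSV with columns `gene_id`, `n_interactions`
#' @export
read_interaction_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character"))
  stats::setNames(df$n_interactions, df$gene_id)
}
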