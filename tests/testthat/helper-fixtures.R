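# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately use the naive O(n^2) / per-base formulation so
# they stay independent of the package's vectorized implementations.

make_ann <- function(starts, ends, chrom = "chr1", gene_id = NULL,
                     probed = TRUE, chrom_sizes = NULL) {
  n <- length(starts)
  if (is.null(gene_id)) gene_id <- sprintf("g%02d", seq_len(n))
  genome_annotation(
    data.frame(gene_id = gene_id, symbol = gene_id,
               chrom = rep_len(chrom, n), start = starts, end = ends,
               strand = rep_len("+", n), probed = rep_len(probed, n)),
    chrom_sizes = chrom_sizes, coords = "0-based")
}

make_expr <- function(values, calls = NULL, tissue = "mammary") {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(calls)) {
    calls <- matrix("P", nrow(values), ncol(values))
  }
  dimnames(calls) <- dimnames(values)
  ns <- ncol(values)
  expression_matrix(values, calls,
                    data.frame(sample_id = colnames(values),
                               tissue = rep_len(tissue, ns),
                               timepoint = seq_len(ns), replicate = 1L))
}

# mean pairwise correlation by direct cor() calls on every pair
bf_anc <- function(values, ids, method = "spearman") {
  pairs <- utils::combn(ids, 2)
  mean(vapply(seq_len(ncol(pairs)), function(j) {
    stats::cor(values[pairs[1, j], ], values[pairs[2, j], ], method = method)
  }, numeric(1)))
}

# per-base island mass oracle (regions small enough to enumerate)
bf_region_mass <- function(sets, chrom, start, end) {
  if (inherits(sets, "island_set")) sets <- list(sets)
  bases <- seq.int(start, end - 1)
  total <- 0
  for (s in sets) {
    for (i in seq_len(nrow(s))) {
      if (s$chrom[i] != chrom) next
      total <- total + s$height[i] * sum(bases >= s$start[i] & bases < s$end[i])
    }
  }
  total
}

# brute-force island merge: grow islands window by window
bf_call_islands <- function(flags, scores, W, gap_bp) {
  el <- which(flags)
  if (!length(el)) {
    return(data.frame(start = numeric(0), end = numeric(0), score = numeric(0)))
  }
  islands <- list()
  cur <- el[1]
  for (i in el[-1]) {
    if ((i - cur[length(cur)] - 1) * W <= gap_bp) cur <- c(cur, i)
    else {
      islands[[length(islands) + 1]] <- cur
      cur <- i
    }
  }
  islands[[length(islands) + 1]] <- cur
  do.call(rbind, lapply(islands, function(g) {
    data.frame(start = (min(g) - 1) * W, end = max(g) * W,
               score = sum(scores[g]))
  }))
}

# maximal runs of TRUE of length >= 2, as list of index vectors
bf_runs <- function(flags) {
  out <- list()
  i <- 1
  n <- length(flags)
  while (i <= n) {
    if (flags[i]) {
      j <- i
      while (j < n && flags[j + 1]) j <- j + 1
      if (j - i + 1 >= 2) out[[length(out) + 1]] <- i:j
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
bf_ranksum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# shared heavyweight synthetic fixtures, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

recovery_fixture <- function() {
  cached("recovery", {
    ann <- simulate_genome(seed = 101)
    truth <- synthetic_truth(ann, n_plants = 20, plant_size = 4,
                             target_anc = 0.8, n_protect = 8, seed = 102)
    expr <- simulate_expression(ann, truth, seed = 103)
    m <- filter_min_present(expr$matrix)
    smap <- simulate_synteny(ann, truth, seed = 104)
    windows <- score_neighborhoods(m, ann, smap, n_perm = 1000, seed = 105)
    list(ann = ann, truth = truth, m = m, smap = smap, windows = windows)
  })
}

chromatin_fixture <- function() {
  cached("chromatin", {
    ann <- simulate_genome(seed = 201)
    truth <- synthetic_truth(ann, seed = 202)
    islands <- simulate_islands(truth, chrom_sizes(ann), seed = 203)
    list(ann = ann, truth = truth, islands = islands,
         table = gene_chromatin_table(ann, islands))
  })
}
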