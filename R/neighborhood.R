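#' Enumerate candidate gene-neighborhood windows
#'
#' Every run of `k` consecutive probed genes per chromosome, for `k` from
#' `min_k` to `max_k`, is a candidate neighborhood. The probed-gene sequence
#' defines adjacency: unprobed genes are skipped.
#'
#' @param ann an ordered, overlap-resolved [genome_annotation()]
#' @param min_k,max_k window size bounds in genes (defaults 2 and 10)
#' @return data frame `(chrom, first, k)` where `first` is the 1-based index
#'   of the window's first gene within the chromosome's probed-gene sequence
#' @export
enumerate_windows <- function(ann, min_k = 2, max_k = 10) {
  if (min_k < 2) stop("min_k must be at least 2")
  if (max_k < min_k) stop("max_k must be >= min_k")
  stopifnot(inherits(ann, "genome_annotation"))
  probed <- ann[ann$probed, , drop = FALSE]
  counts <- table(probed$chrom)
  out <- lapply(names(counts), function(chr) {
    n <- counts[[chr]]
    ks <- seq.int(min_k, max_k)
    ks <- ks[ks <= n]
    if (!length(ks)) return(NULL)
    do.call(rbind, lapply(ks, function(k) {
      data.frame(chrom = chr, first = seq_len(n - k + 1), k = k)
    }))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(0), first = integer(0),
                                      k = integer(0))
  rownames(out) <- NULL
  out
}

#' Average neighborhood correlation of a gene window
#'
#' Mean of all `choose(k, 2)` pairwise expression correlations among the
#' window's genes. If any pair's correlation is undefined (a zero-variance
#' profile) the window is unscorable and `NA` is returned.
#'
#' @param gene_ids the window's gene ids
#' @param m an [expression_matrix()]
#' @param method correlation method
#' @return ANC in `[-1, 1]`, or `NA`
#' @export
anc <- function(gene_ids, m, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(gene_ids) >= 2)
  z <- .standardize_profiles(m$values[gene_ids, , drop = FALSE], method)
  if (anyNA(z)) return(NA_real_)
  cc <- tcrossprod(z)
  mean(cc[upper.tri(cc)])
}

#' Empirical null distribution of ANC for one window size
#'
#' The randomized-transcriptome null: expression profiles are shuffled
#' across genome positions (the annotation stays fixed, profiles are
#' permuted) and the ANC of every size-`k` window is recomputed. The pooled
#' null sample over all permutations supports the add-one p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`.
#'
#' @param m a filtered [expression_matrix()]
#' @param ann an ordered, overlap-resolved [genome_annotation()]
#' @param k window size
#' @param n_perm number of permutations
#' @param seed RNG seed
#' @param method correlation method
#' @param permutations optional matrix of explicit row orders (one
#'   permutation per row) overriding random shuffles; enables exhaustive
#'   enumeration on tiny inputs
#' @return numeric vector: pooled null ANC sample
#' @export
anc_null <- function(m, ann, k, n_perm = 1000, seed = 1,
                     method = c("spearman", "pearson"), permutations = NULL) {
  method <- match.arg(method)
  eng <- .scoring_engine(m, ann, method)
  null_k <- .null_anc_samples(eng, k, n_perm, seed, permutations)
  unlist(null_k, use.names = FALSE)
}

#' Total neighborhood score
#'
#' `TNS = SS * ANC` when the permutation p-value is at most `alpha` and the
#' ANC is positive; otherwise 0. Clamped to `[0, 1]`; `NA` ANC or p gives
#' `NA` (unscorable window).
#'
#' @param anc average neighborhood correlation
#' @param ss synteny score
#' @param p permutation p-value
#' @param alpha significance gate (default 0.05)
#' @return TNS in `[0, 1]` (or `NA`)
#' @export
tns <- function(anc, ss, p, alpha = 0.05) {
  out <- ifelse(p <= alpha & anc > 0, pmin(pmax(ss * anc, 0), 1), 0)
  out[is.na(anc) | is.na(p)] <- NA_real_
  out
}

# shared standardized-profile state for observed and null window scoring:
# genes = probed genes present in the matrix, in genome order
.scoring_engine <- function(m, ann, method) {
  genes <- ann[ann$probed & ann$gene_id %in% rownames(m$values), , drop = FALSE]
  z <- .standardize_profiles(m$values[genes$gene_id, , drop = FALSE], method)
  chrom_idx <- split(seq_len(nrow(genes)), genes$chrom)
  list(genes = genes, z = z, chrom_idx = chrom_idx)
}

.observed_anc <- function(eng, min_k, max_k) {
  max_off <- max_k - 1
  lapply(eng$chrom_idx, function(idx) {
    zc <- eng$z[idx, , drop = FALSE]
    off <- .offset_correlations(zc, min(max_off, nrow(zc) - 1))
    bad <- is.na(zc[, 1])
    ks <- seq.int(min_k, min(max_k, nrow(zc)))
    stats::setNames(lapply(ks, function(k) .window_anc(off, nrow(zc), k, bad)),
                    ks)
  })
}

# per-permutation null ANC samples for sizes `ks`, as list k -> list of
# per-permutation vectors pooled over chromosomes
.null_anc_samples <- function(eng, ks, n_perm, seed, permutations = NULL) {
  n <- nrow(eng$z)
  if (is.null(permutations)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    perm_fun <- function(i) sample.int(n)
    n_it <- n_perm
  } else {
    stopifnot(ncol(permutations) == n)
    perm_fun <- function(i) permutations[i, ]
    n_it <- nrow(permutations)
  }
  max_k <- max(ks)
  out <- stats::setNames(lapply(ks, function(k) vector("list", n_it)),
                         as.character(ks))
  for (it in seq_len(n_it)) {
    zp <- eng$z[perm_fun(it), , drop = FALSE]
    for (ci in eng$chrom_idx) {
      zc <- zp[ci, , drop = FALSE]
      nc <- nrow(zc)
      if (nc < min(ks)) next
      off <- .offset_correlations(zc, min(max_k - 1, nc - 1))
      bad <- is.na(zc[, 1])
      for (k in ks[ks <= nc]) {
        v <- .window_anc(off, nc, k, bad)
        key <- as.character(k)
        out[[key]][[it]] <- c(out[[key]][[it]], v[!is.na(v)])
      }
    }
  }
  lapply(out, function(lst) lst[!vapply(lst, is.null, logical(1))])
}

#' Score all candidate neighborhoods
#'
#' The main scoring pass: enumerates every window of `min_k` to `max_k`
#' consecutive probed genes, computes its ANC, its synteny score over the
#' comparison genomes, a permutation p-value against the
#' randomized-transcriptome null (conditioned on window size), and the TNS.
#'
#' @inheritParams anc_null
#' @param smap a [synteny_map()]
#' @param min_k,max_k window size range (defaults 2-10)
#' @param alpha TNS significance gate
#' @param strict_order see [synteny_score()]
#' @return data frame with one row per window: `chrom`, `start`, `end`
#'   (neighborhood span, min start to max end), `n_genes`, `gene_ids`
#'   (comma-separated), `first` (index of first gene in the chromosome's
#'   probed sequence), `ANC`, `SS`, `p`, `TNS`
#' @export
score_neighborhoods <- function(m, ann, smap, min_k = 2, max_k = 10,
                                n_perm = 1000, seed = 1, alpha = 0.05,
                                method = c("spearman", "pearson"),
                                strict_order = FALSE) {
  method <- match.arg(method)
  if (min_k < 2) stop("min_k must be at least 2")
  if (n_perm < 100) stop("n_perm must be at least 100")
  eng <- .scoring_engine(m, ann, method)
  ks <- seq.int(min_k, max_k)
  obs <- .observed_anc(eng, min_k, max_k)
  nulls <- .null_anc_samples(eng, ks, n_perm, seed)
  null_sorted <- lapply(nulls, function(lst) sort(unlist(lst, use.names = FALSE)))

  rows <- list()
  for (chr in names(eng$chrom_idx)) {
    idx <- eng$chrom_idx[[chr]]
    g <- eng$genes[idx, , drop = FALSE]
    if (!strict_order) {
      bm <- .block_matrix(g$gene_id, smap)
    }
    for (key in names(obs[[chr]])) {
      k <- as.integer(key)
      a <- obs[[chr]][[key]]
      n_win <- length(a)
      if (!n_win) next
      if (strict_order) {
        ss <- vapply(seq_len(n_win), function(i) {
          synteny_score(g$gene_id[i:(i + k - 1)], smap, strict_order = TRUE)
        }, numeric(1))
      } else {
        ss <- .window_ss(bm, k)
      }
      nullv <- null_sorted[[key]]
      n_null <- length(nullv)
      cnt_ge <- n_null - findInterval(a, nullv, left.open = TRUE)
      p <- (1 + cnt_ge) / (1 + n_null)
      p[is.na(a)] <- NA_real_
      first <- seq_len(n_win)
      starts <- g$start[first]
      ends <- vapply(first, function(i) max(g$end[i:(i + k - 1)]), numeric(1))
      gene_ids <- vapply(first, function(i) {
        paste(g$gene_id[i:(i + k - 1)], collapse = ",")
      }, character(1))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, start = starts, end = ends, n_genes = k,
        gene_ids = gene_ids, first = first,
        ANC = a, SS = ss, p = p, TNS = tns(a, ss, p, alpha),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_genes = integer(0), gene_ids = character(0),
               first = integer(0), ANC = numeric(0), SS = numeric(0),
               p = numeric(0), TNS = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Best TNS per gene
#'
#' The highest TNS over all scored windows containing each gene. Genes in no
#' window (for example singletons on their chromosome) score 0; `NA` TNS
#' windows (unscorable) are ignored.
#'
#' @param windows output of [score_neighborhoods()]
#' @param ann the annotation the windows were scored on
#' @return data frame `(gene_id, best_tns)` over probed genes
#' @export
best_tns_per_gene <- function(windows, ann) {
  genes <- ann[ann$probed, , drop = FALSE]
  best <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  if (nrow(windows)) {
    ids <- strsplit(windows$gene_ids, ",", fixed = TRUE)
    flat <- unlist(ids, use.names = FALSE)
    w <- rep(windows$TNS, lengths(ids))
    keep <- !is.na(w) & flat %in% names(best)
    if (any(keep)) {
      mx <- tapply(w[keep], flat[keep], max)
      best[names(mx)] <- pmax(best[names(mx)], mx)
    }
  }
  data.frame(gene_id = names(best), best_tns = unname(best),
             stringsAsFactors = FALSE)
}

#' Detection-call run neighborhoods
#'
#' Maximal runs of two or more adjacent probed genes all expressed in a
#' tissue: the simple run-based neighborhood definition used for
#' cross-tissue comparisons when too few replicates exist for
#' correlation-based scoring.
#'
#' @param expressed named logical vector over probed genes (see
#'   [expressed_in_tissue()])
#' @param ann an ordered [genome_annotation()]
#' @return data frame `(chrom, start, end, n_genes, gene_ids)`; one row per
#'   run
#' @export
present_run_neighborhoods <- function(expressed, ann) {
  genes <- ann[ann$probed, , drop = FALSE]
  flag <- .aligned_flags(expressed, genes)
  rows <- list()
  for (chr in unique(genes$chrom)) {
    on_chr <- which(genes$chrom == chr)
    r <- rle(flag[on_chr])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values & r$lengths >= 2)
    for (j in runs) {
      i <- on_chr[starts[j]:ends[j]]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, start = min(genes$start[i]), end = max(genes$end[i]),
        n_genes = length(i),
        gene_ids = paste(genes$gene_id[i], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_genes = integer(0), gene_ids = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Isolated expressed genes
#'
#' Genes expressed in the tissue whose flanking probed genes (both of them;
#' at a chromosome end, the single flank) are not expressed.
#'
#' @inheritParams present_run_neighborhoods
#' @return character vector of isolated gene ids
#' @export
isolated_genes <- function(expressed, ann) {
  genes <- ann[ann$probed, , drop = FALSE]
  flag <- .aligned_flags(expressed, genes)
  iso <- character(0)
  for (chr in unique(genes$chrom)) {
    i <- which(genes$chrom == chr)
    f <- flag[i]
    n <- length(f)
    left <- c(FALSE, f[-n])
    right <- c(f[-1], FALSE)
    iso <- c(iso, genes$gene_id[i[f & !left & !right]])
  }
  iso
}

.aligned_flags <- function(expressed, genes) {
  if (is.null(names(expressed))) {
    stopifnot(length(expressed) == nrow(genes))
    return(as.logical(expressed))
  }
  f <- expressed[genes$gene_id]
  f[is.na(f)] <- FALSE
  unname(as.logical(f))
}

#' Fraction of neighborhoods shared with a second tissue
#'
#' A neighborhood is shared when transcripts of all its genes are also
#' detectably expressed in the second tissue.
#'
#' @param neighborhoods output of [present_run_neighborhoods()] for tissue A
#' @param expressed_b named logical expressed vector for tissue B
#' @return percentage (0-100) of A-neighborhoods shared with B
#' @export
shared_fraction <- function(neighborhoods, expressed_b) {
  if (!nrow(neighborhoods)) return(NA_real_)
  ids <- strsplit(neighborhoods$gene_ids, ",", fixed = TRUE)
  shared <- vapply(ids, function(g) {
    f <- expressed_b[g]
    !anyNA(f) && all(f)
  }, logical(1))
  100 * mean(shared)
}

#' Permutation test for neighborhood membership excess
#'
#' Tests whether more expressed genes occur in runs (and fewer are isolated)
#' than expected by chance, by permuting the expressed flags across gene
#' positions. In-run counts use an upper-tail p, isolated counts a
#' lower-tail p, both with the add-one estimator.
#'
#' @inheritParams present_run_neighborhoods
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed
#' @param permutations optional explicit permutation matrix (rows = orders)
#'   for exhaustive enumeration on tiny inputs
#' @return list `(in_run_obs, in_run_p, isolated_obs, isolated_p, n_perm)`
#' @export
membership_excess_test <- function(expressed, ann, n_perm = 1000, seed = 1,
                                   permutations = NULL) {
  genes <- ann[ann$probed, , drop = FALSE]
  flag <- .aligned_flags(expressed, genes)
  if (is.null(permutations) && n_perm < 100) stop("n_perm must be at least 100")
  chrom <- genes$chrom
  count_stats <- function(f) {
    in_run <- 0L
    iso <- 0L
    for (chr in unique(chrom)) {
      fc <- f[chrom == chr]
      n <- length(fc)
      left <- c(FALSE, fc[-n])
      right <- c(fc[-1], FALSE)
      neigh <- fc & (left | right)
      in_run <- in_run + sum(neigh)
      iso <- iso + sum(fc & !left & !right)
    }
    c(in_run = in_run, iso = iso)
  }
  obs <- count_stats(flag)
  if (is.null(permutations)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    perm_fun <- function(i) sample(flag)
    n_it <- n_perm
  } else {
    perm_fun <- function(i) flag[permutations[i, ]]
    n_it <- nrow(permutations)
  }
  ge_run <- 0L
  le_iso <- 0L
  for (it in seq_len(n_it)) {
    s <- count_stats(perm_fun(it))
    if (s["in_run"] >= obs["in_run"]) ge_run <- ge_run + 1L
    if (s["iso"] <= obs["iso"]) le_iso <- le_iso + 1L
  }
  list(in_run_obs = unname(obs["in_run"]),
       in_run_p = (1 + ge_run) / (1 + n_it),
       isolated_obs = unname(obs["iso"]),
       isolated_p = (1 + le_iso) / (1 + n_it),
       n_perm = n_it)
}
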