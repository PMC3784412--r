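# Internal correlation engine.
#
# Profiles are rank-transformed (Spearman) or left as is (Pearson), centered
# and scaled to unit norm, so that the correlation of two genes is the plain
# dot product of their standardized rows. All windowed and pairwise
# statistics run on this representation.

.standardize_profiles <- function(values, method = "spearman") {
  stopifnot(method %in% c("spearman", "pearson"))
  v <- values
  if (method == "spearman") {
    v <- t(apply(v, 1, rank))
  }
  ctr <- v - rowMeans(v)
  nrm <- sqrt(rowSums(ctr^2))
  zero <- nrm < 1e-12
  nrm[zero] <- 1
  z <- ctr / nrm
  z[zero, ] <- NA_real_
  z
}

# correlations of rows offset by d = 1..max_off along the matrix:
# out[[d]][i] = cor(row i, row i + d)
.offset_correlations <- function(z, max_off) {
  n <- nrow(z)
  lapply(seq_len(max_off), function(d) {
    if (n <= d) return(numeric(0))
    rowSums(z[seq_len(n - d), , drop = FALSE] *
            z[seq.int(1 + d, n), , drop = FALSE])
  })
}

# mean pairwise correlation of every window of k consecutive rows, from the
# offset-correlation lists (cumulative-sum sliding windows); a window
# containing any unscorable (zero-variance) row is NA
.window_anc <- function(offsets, n, k, bad_rows = NULL) {
  n_win <- n - k + 1
  if (n_win <= 0) return(numeric(0))
  total <- numeric(n_win)
  for (d in seq_len(k - 1)) {
    cd <- offsets[[d]]
    cd[is.na(cd)] <- 0
    s <- c(0, cumsum(cd))
    # pairs at offset d inside window starting i: positions i .. i+k-1-d
    total <- total + (s[seq_len(n_win) + (k - d)] - s[seq_len(n_win)])
  }
  anc <- total / choose(k, 2)
  if (!is.null(bad_rows) && any(bad_rows)) {
    b <- c(0, cumsum(as.integer(bad_rows)))
    anc[(b[seq_len(n_win) + k] - b[seq_len(n_win)]) > 0] <- NA_real_
  }
  anc
}
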