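#' Construct / read a mapped-tag library
#'
#' Tag positions for one mark in one tissue, post-mapping. This feeds the
#' simplified broad-island caller; the main analysis path consumes
#' externally called islands instead.
#'
#' @param tags data frame with columns `chrom`, `pos` (bp, 0-based) and
#'   optionally `strand`
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @param effective_genome_length mappable genome length in bp used for the
#'   background rate; defaults to the sum of `chrom_sizes`
#' @return a `tag_library`
#' @export
tag_library <- function(tags, chrom_sizes, effective_genome_length = NULL) {
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "pos"), names(tags))
  if (length(miss)) stop("tag table missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(tags$strand)) tags$strand <- rep_len("+", nrow(tags))
  tags$chrom <- as.character(tags$chrom)
  absent <- setdiff(unique(tags$chrom), names(chrom_sizes))
  if (length(absent)) stop("tags on chromosomes absent from chrom_sizes: ",
                           paste(absent, collapse = ", "))
  if (any(tags$pos < 0) || any(tags$pos >= chrom_sizes[tags$chrom])) {
    stop("tag positions must lie within chromosome bounds")
  }
  if (is.null(effective_genome_length)) {
    effective_genome_length <- sum(chrom_sizes)
  }
  structure(list(tags = tags[c("chrom", "pos", "strand")],
                 chrom_sizes = chrom_sizes,
                 total_count = nrow(tags),
                 effective_genome_length = effective_genome_length),
            class = "tag_library")
}

#' @rdname tag_library
#' @param path TSV `(chrom, pos, strand)`, no header (BED3-with-strand
#'   dialect: a 3+ column file is read as `chrom, start, [end,] strand`)
#' @export
read_tags <- function(path, chrom_sizes, effective_genome_length = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  tags <- data.frame(chrom = as.character(df[[1]]), pos = df[[2]])
  if (ncol(df) >= 4) tags$strand <- df[[4]] else if (ncol(df) == 3) {
    tags$strand <- df[[3]]
  }
  tag_library(tags, chrom_sizes, effective_genome_length)
}

#' Fixed-width window tag counts
#'
#' Partitions each chromosome into windows of `W` bp (200 bp by default,
#' about one nucleosome plus linker) and counts the tags falling in each;
#' tag at position p belongs to window `floor(p / W)`. Counts are conserved:
#' every tag lands in exactly one window.
#'
#' @param lib a [tag_library()]
#' @param W window width in bp
#' @return a `window_track`: list with `W` and per-chromosome integer count
#'   vectors
#' @export
window_counts <- function(lib, W = 200) {
  stopifnot(inherits(lib, "tag_library"))
  if (W <= 0) stop("window size must be positive")
  counts <- lapply(names(lib$chrom_sizes), function(chr) {
    n_win <- ceiling(lib$chrom_sizes[[chr]] / W)
    pos <- lib$tags$pos[lib$tags$chrom == chr]
    tabulate(floor(pos / W) + 1L, nbins = n_win)
  })
  structure(list(W = W, counts = stats::setNames(counts, names(lib$chrom_sizes)),
                 total_count = lib$total_count,
                 effective_genome_length = lib$effective_genome_length),
            class = "window_track")
}

#' Eligible windows and Poisson window scores
#'
#' A window is eligible when its tag count is improbably high under the
#' Poisson background: upper-tail probability `P(X >= count)` below
#' `p_thresh` (a threshold of 1 or more makes every window eligible). The
#' window score is `-ln P(X >= count)`, zero for empty windows.
#'
#' @param track a [window_track()]
#' @param lambda0 expected background tags per window; defaults to the
#'   library-wide rate `total_count * W / effective_genome_length`
#' @param p_thresh eligibility threshold on the Poisson upper tail
#' @return list with per-chromosome logical `eligible` and numeric `scores`,
#'   plus the `lambda0` used
#' @export
eligible_windows <- function(track, lambda0 = NULL, p_thresh = 0.01) {
  stopifnot(inherits(track, "window_track"))
  if (is.null(lambda0)) {
    lambda0 <- track$total_count * track$W / track$effective_genome_length
  }
  if (lambda0 <= 0) stop("lambda0 must be positive")
  score_fun <- function(cnt) {
    sc <- -stats::ppois(cnt - 1, lambda0, lower.tail = FALSE, log.p = TRUE)
    sc[cnt == 0] <- 0
    sc
  }
  scores <- lapply(track$counts, score_fun)
  eligible <- if (p_thresh >= 1) {
    lapply(track$counts, function(cnt) rep(TRUE, length(cnt)))
  } else {
    lapply(scores, function(sc) sc > -log(p_thresh))
  }
  list(eligible = eligible, scores = scores, lambda0 = lambda0)
}

#' Merge eligible windows into islands
#'
#' Maximal groups of eligible windows whose consecutive members are
#' separated by at most `gap_bp` of ineligible windows form one island,
#' spanning the first window's start to the last window's end. The island
#' score is the sum of its eligible windows' scores; its height is
#' score / width. Islands below `min_score` are discarded.
#'
#' @param track a [window_track()]
#' @param flags,scores per-chromosome eligibility flags and window scores
#'   (see [eligible_windows()])
#' @param gap_bp allowed ineligible stretch inside an island; must be a
#'   multiple of the window size
#' @param min_score minimum island score kept (default 0: keep all)
#' @return an [island_set()] (columns `chrom, start, end, height` plus
#'   `score` and `n_windows`)
#' @export
call_islands <- function(track, flags, scores, gap_bp, min_score = 0) {
  stopifnot(inherits(track, "window_track"))
  W <- track$W
  if (gap_bp < 0 || gap_bp %% W != 0) {
    stop("gap_bp must be a nonnegative multiple of the window size")
  }
  rows <- list()
  for (chr in names(track$counts)) {
    el <- which(flags[[chr]])
    if (!length(el)) next
    sc <- scores[[chr]]
    # break when more than gap_bp/W ineligible windows separate neighbors
    brk <- c(FALSE, diff(el) - 1 > gap_bp / W)
    grp <- cumsum(brk)
    for (g in split(el, grp)) {
      island_score <- sum(sc[g])
      if (island_score < min_score) next
      start <- (min(g) - 1) * W
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, start = start, end = max(g) * W,
        height = island_score / (max(g) * W - start),
        score = island_score, n_windows = length(g))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               height = numeric(0), score = numeric(0), n_windows = integer(0))
  }
  res <- island_set(out)
  res$score <- out$score[match(paste(res$chrom, res$start),
                               paste(out$chrom, out$start))]
  res$n_windows <- out$n_windows[match(paste(res$chrom, res$start),
                                       paste(out$chrom, out$start))]
  res
}

#' Aggregate island score
#'
#' @param islands output of [call_islands()] (or any island set with a
#'   `score` column)
#' @return sum of island scores
#' @export
aggregate_score <- function(islands) {
  if (!nrow(islands)) return(0)
  sum(islands$score)
}

#' Gap-size scan
#'
#' Runs the island caller over an ascending grid of gap sizes and records
#' the aggregate island score at each; the chosen gap is the smallest gap
#' attaining the maximum aggregate score. Broad, internally gappy marks need
#' a large gap before their fragments merge into islands that clear
#' `min_island_score`; punctate marks saturate immediately.
#'
#' @param lib a [tag_library()]
#' @param W window width in bp
#' @param gap_multiples ascending gaps in bp (multiples of `W`)
#' @param p_thresh eligibility threshold, see [eligible_windows()]
#' @param lambda0 background rate per window (default: library-wide rate,
#'   rescaled by the control library if given)
#' @param control optional input/unenriched [tag_library()]; used only to
#'   rescale `lambda0` by the ratio of library sizes
#' @param min_island_score island score filter applied at every gap
#' @return list `(table, chosen_gap)`: `table` has one row per gap with
#'   `gap`, `n_islands`, `aggregate_score`
#' @export
gap_scan <- function(lib, W = 200, gap_multiples = W * c(0:3, 5, 10, 25, 50, 100),
                     p_thresh = 1e-4, lambda0 = NULL, control = NULL,
                     min_island_score = 100) {
  if (!length(gap_multiples)) stop("gap_multiples must be non-empty")
  if (is.unsorted(gap_multiples, strictly = TRUE)) {
    stop("gap_multiples must be strictly ascending")
  }
  track <- window_counts(lib, W)
  if (is.null(lambda0) && !is.null(control)) {
    ctl_rate <- control$total_count * W / control$effective_genome_length
    lambda0 <- ctl_rate * lib$total_count / control$total_count
  }
  ew <- eligible_windows(track, lambda0 = lambda0, p_thresh = p_thresh)
  tab <- do.call(rbind, lapply(gap_multiples, function(g) {
    isl <- call_islands(track, ew$eligible, ew$scores, g,
                        min_score = min_island_score)
    data.frame(gap = g, n_islands = nrow(isl),
               aggregate_score = aggregate_score(isl))
  }))
  chosen <- tab$gap[which.max(tab$aggregate_score)]
  list(table = tab, chosen_gap = chosen)
}
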