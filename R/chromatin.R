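#' Construct / read a broad-mark island set
#'
#' An `island_set` holds the non-overlapping enrichment islands of one
#' histone mark in one tissue: interval plus a nonnegative height (the
#' caller's per-island enrichment level). Island files are BED-like TSVs
#' `(chrom, start, end, score)` in 0-based half-open coordinates.
#'
#' @param islands data frame with columns `chrom`, `start`, `end`, `height`
#'   (a `score` column is accepted as `height`)
#' @param mark histone mark name (e.g. `"H3K27me3"`)
#' @param tissue tissue name (e.g. `"mammary"`)
#' @return an `island_set`, sorted by (chrom, start)
#' @export
island_set <- function(islands, mark = NA_character_, tissue = NA_character_) {
  islands <- as.data.frame(islands, stringsAsFactors = FALSE)
  if (is.null(islands$height) && !is.null(islands$score)) {
    islands$height <- islands$score
  }
  need <- c("chrom", "start", "end", "height")
  miss <- setdiff(need, names(islands))
  if (length(miss)) stop("island table missing columns: ",
                         paste(miss, collapse = ", "))
  islands <- islands[need]
  islands$chrom <- as.character(islands$chrom)
  if (any(islands$end <= islands$start)) stop("island with end <= start")
  if (any(islands$height < 0)) stop("negative island height")
  islands <- islands[order(islands$chrom, islands$start), , drop = FALSE]
  if (nrow(islands) > 1) {
    same <- islands$chrom[-nrow(islands)] == islands$chrom[-1]
    ov <- same & islands$end[-nrow(islands)] > islands$start[-1]
    if (any(ov)) stop("islands within a set must be non-overlapping")
  }
  rownames(islands) <- NULL
  structure(islands, mark = mark, tissue = tissue,
            class = c("island_set", "data.frame"))
}

#' @rdname island_set
#' @param path BED-like TSV `(chrom, start, end, score)`, no header
#' @export
read_islands <- function(path, mark = NA_character_, tissue = NA_character_) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "height")
  island_set(df, mark = mark, tissue = tissue)
}

#' @rdname island_set
#' @param x set to write
#' @export
write_islands <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("chrom", "start", "end", "height")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Island mass over genomic regions
#'
#' The summed peak mass across a region: each island contributes its height
#' times the width of its overlap with the region (islands partially
#' overlapping contribute only the clipped width).
#'
#' @param sets an `island_set` or list of island sets (summed together)
#' @param regions data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open)
#' @return numeric vector of masses (score x bp), one per region
#' @export
region_mass <- function(sets, regions) {
  if (inherits(sets, "island_set")) sets <- list(sets)
  regions <- as.data.frame(regions)
  out <- numeric(nrow(regions))
  if (!nrow(regions)) return(out)
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1, regions$end))
  for (s in sets) {
    if (!nrow(s)) next
    igr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start + 1, s$end))
    hits <- GenomicRanges::findOverlaps(rgr, igr)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits)
    j <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(IRanges::pintersect(rgr[q], igr[j]))
    out <- out + unname(.bin_sum(w * s$height[j], q, nrow(regions)))
  }
  out
}

#' Chromatin active / silenced domain ratios
#'
#' `cadr()` is the tissue-to-control ratio of the summed active-mark island
#' mass (H3K4me2 + H3K36me3) across a region; `csdr()` the same ratio for
#' the silencing mark (H3K27me3). A symmetric pseudomass `eps` is added to
#' numerator and denominator so empty regions give a ratio of 1.
#'
#' @param regions data frame `(chrom, start, end)`
#' @param mam_k4,mam_k36,liv_k4,liv_k36 active-mark island sets for the
#'   tissue of interest ("mammary") and the control tissue ("liver")
#' @param eps pseudomass (score x bp, default 1)
#' @return nonnegative ratio(s), one per region
#' @export
cadr <- function(regions, mam_k4, mam_k36, liv_k4, liv_k36, eps = 1) {
  mass_m <- region_mass(list(mam_k4, mam_k36), regions)
  mass_l <- region_mass(list(liv_k4, liv_k36), regions)
  (mass_m + eps) / (mass_l + eps)
}

#' @rdname cadr
#' @param mam_k27,liv_k27 silencing-mark island sets
#' @export
csdr <- function(regions, mam_k27, liv_k27, eps = 1) {
  (region_mass(mam_k27, regions) + eps) / (region_mass(liv_k27, regions) + eps)
}

#' Combined chromatin domain score
#'
#' `DS = log2(CADR + 1) - log2(CSDR + 1)`. Positive scores indicate more
#' active and/or less silenced chromatin in the tissue of interest relative
#' to the control tissue; negative the reverse; near zero, a shared state.
#'
#' @param cadr,csdr domain ratios (nonnegative)
#' @param base logarithm base (default 2)
#' @return signed score(s)
#' @export
domain_score <- function(cadr, csdr, base = 2) {
  stopifnot(all(cadr >= 0, na.rm = TRUE), all(csdr >= 0, na.rm = TRUE))
  log(cadr + 1, base) - log(csdr + 1, base)
}

#' Per-gene chromatin scores
#'
#' CADR, CSDR and DS for every gene, over the genomic region from
#' transcription start to transcription end.
#'
#' @param ann a [genome_annotation()]
#' @param islands named list of six island sets: `mam_k4`, `mam_k36`,
#'   `mam_k27`, `liv_k4`, `liv_k36`, `liv_k27`
#' @param eps pseudomass, see [cadr()]
#' @param base log base for DS and the log-ratio columns
#' @return data frame `(gene_id, cadr, csdr, log_cadr, log_csdr, ds)`
#' @export
gene_chromatin_table <- function(ann, islands, eps = 1, base = 2) {
  .check_island_bundle(islands)
  regions <- as.data.frame(ann)[, c("chrom", "start", "end")]
  ca <- cadr(regions, islands$mam_k4, islands$mam_k36,
             islands$liv_k4, islands$liv_k36, eps = eps)
  cs <- csdr(regions, islands$mam_k27, islands$liv_k27, eps = eps)
  data.frame(gene_id = ann$gene_id, cadr = ca, csdr = cs,
             log_cadr = log(ca, base), log_csdr = log(cs, base),
             ds = domain_score(ca, cs, base), stringsAsFactors = FALSE)
}

#' Neighborhood-level chromatin ratios
#'
#' NCADR and NCSDR: the same computation as per-gene CADR/CSDR, over the
#' whole neighborhood span (its start and end points) instead of a single
#' gene's transcription unit.
#'
#' @param windows output of [score_neighborhoods()] (any data frame with
#'   `chrom`, `start`, `end`)
#' @inheritParams gene_chromatin_table
#' @return `windows` with `NCADR`, `NCSDR` and `NDS` columns appended
#' @export
neighborhood_ratios <- function(windows, islands, eps = 1, base = 2) {
  .check_island_bundle(islands)
  regions <- windows[, c("chrom", "start", "end")]
  windows$NCADR <- cadr(regions, islands$mam_k4, islands$mam_k36,
                        islands$liv_k4, islands$liv_k36, eps = eps)
  windows$NCSDR <- csdr(regions, islands$mam_k27, islands$liv_k27, eps = eps)
  windows$NDS <- domain_score(windows$NCADR, windows$NCSDR, base)
  windows
}

.check_island_bundle <- function(islands) {
  need <- c("mam_k4", "mam_k36", "mam_k27", "liv_k4", "liv_k36", "liv_k27")
  miss <- setdiff(need, names(islands))
  if (length(miss)) stop("island bundle missing sets: ",
                         paste(miss, collapse = ", "))
}

#' Classify a gene's differential chromatin state
#'
#' Threshold rule on the log domain ratios: uniquely active when
#' `log_cadr > active_thresh` and `log_csdr <= silent_thresh`; uniquely
#' silenced when `log_csdr > silent_thresh` and `log_cadr <= active_thresh`;
#' both above threshold is inconsistent (active and silenced at once);
#' otherwise the chromatin state is shared between the tissues.
#'
#' @param log_cadr,log_csdr log-scale domain ratios
#' @param active_thresh,silent_thresh thresholds (default 8, i.e. a 256-fold
#'   mass ratio on the log2 scale)
#' @return factor with levels `uniquely_active`, `uniquely_silenced`,
#'   `shared`, `inconsistent`
#' @export
classify_gene <- function(log_cadr, log_csdr, active_thresh = 8,
                          silent_thresh = 8) {
  act <- log_cadr > active_thresh
  sil <- log_csdr > silent_thresh
  out <- ifelse(act & sil, "inconsistent",
         ifelse(act, "uniquely_active",
         ifelse(sil, "uniquely_silenced", "shared")))
  factor(out, levels = c("uniquely_active", "uniquely_silenced", "shared",
                         "inconsistent"))
}

#' Classify a gene pair's joint chromatin state
#'
#' Each gene is called active (`DS > t`), silent (`DS < -t`) or neutral.
#' Both active gives an active pair; both silent a silent pair; one active
#' and one silent a discordant pair; everything else (at least one neutral,
#' none conflicting) is concordant. Symmetric in its arguments.
#'
#' @param ds_a,ds_b domain scores of the two genes
#' @param t state threshold (default 2)
#' @return factor with levels `active`, `silent`, `concordant`, `discordant`
#' @export
classify_pair <- function(ds_a, ds_b, t = 2) {
  state <- function(ds) ifelse(ds > t, 1L, ifelse(ds < -t, -1L, 0L))
  a <- state(ds_a)
  b <- state(ds_b)
  out <- ifelse(a == 1 & b == 1, "active",
         ifelse(a == -1 & b == -1, "silent",
         ifelse(a * b == -1, "discordant", "concordant")))
  factor(out, levels = c("active", "silent", "concordant", "discordant"))
}

#' Domain-score distribution summary
#'
#' @param ds per-gene domain scores
#' @param band half-width of the shared-chromatin band (default 2)
#' @return list `(min, max, frac_within_band)`: the DS range and the
#'   fraction of genes with `-band <= DS <= band`
#' @export
ds_summary <- function(ds, band = 2) {
  ds <- ds[!is.na(ds)]
  if (!length(ds)) stop("no domain scores supplied")
  list(min = min(ds), max = max(ds),
       frac_within_band = mean(ds >= -band & ds <= band))
}

#' Partition active genes by neighborhood membership
#'
#' Among genes in active domains (`DS >= ds_min`), counts those in
#' neighborhoods (`best TNS > tns_hi`), not in neighborhoods
#' (`best TNS < tns_lo`) and indeterminate (strictly between the bands).
#' Values exactly at a band edge satisfy neither strict inequality and are
#' reported in a separate `boundary` bucket.
#'
#' @param best_tns per-gene best TNS (named vector or the data frame from
#'   [best_tns_per_gene()])
#' @param ds per-gene domain scores aligned to `best_tns`
#' @param ds_min active-domain threshold (default 2)
#' @param tns_hi,tns_lo TNS bands (defaults 0.4 and 0.01)
#' @return named integer vector: `in_neighborhoods`, `not_in_neighborhoods`,
#'   `indeterminate`, `boundary`, plus `n_active`
#' @export
active_gene_partition <- function(best_tns, ds, ds_min = 2, tns_hi = 0.4,
                                  tns_lo = 0.01) {
  if (is.data.frame(best_tns)) best_tns <- best_tns$best_tns
  stopifnot(length(best_tns) == length(ds))
  act <- !is.na(ds) & ds >= ds_min & !is.na(best_tns)
  t <- best_tns[act]
  c(in_neighborhoods = sum(t > tns_hi),
    not_in_neighborhoods = sum(t < tns_lo),
    indeterminate = sum(t > tns_lo & t < tns_hi),
    boundary = sum(t == tns_lo | t == tns_hi),
    n_active = sum(act))
}
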