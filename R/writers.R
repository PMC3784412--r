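# Tab-separated writers for scored windows, per-gene best scores and the
# genome-browser custom track. Coordinates go to disk 1-based inclusive in
# score tables (printed-table dialect) and 0-based half-open in the BED
# track, matching each format's convention.

#' Write / read scored neighborhoods
#'
#' @param windows output of [score_neighborhoods()]
#' @param path output TSV
#' @param provenance optional named character vector written as `# key=value`
#'   header comment lines
#' @export
write_neighborhood_tsv <- function(windows, path, provenance = NULL) {
  out <- windows[, c("chrom", "start", "end", "n_genes", "gene_ids",
                     "ANC", "SS", "p", "TNS")]
  out$start <- out$start + 1
  .write_tsv_commented(out, path, provenance)
  invisible(windows)
}

#' @rdname write_neighborhood_tsv
#' @export
read_neighborhood_tsv <- function(path) {
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out$start <- out$start - 1
  out
}

#' Write / read per-gene best TNS
#'
#' @param best output of [best_tns_per_gene()]
#' @inheritParams write_neighborhood_tsv
#' @export
write_best_tns <- function(best, path, provenance = NULL) {
  .write_tsv_commented(best, path, provenance)
  invisible(best)
}

#' @rdname write_best_tns
#' @export
read_best_tns <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character"))
}

#' Write a genome-browser custom track of TNS windows
#'
#' BED9 track: one feature per scored window, score = `round(TNS * 1000)`,
#' colored by TNS band (red 0.6-1, orange 0.4-0.6, bright yellow 0.1-0.3,
#' light yellow below 0.1).
#'
#' @param windows output of [score_neighborhoods()]
#' @param path output file
#' @param track_name track line name
#' @export
write_ucsc_track <- function(windows, path, track_name = "TNS") {
  w <- windows[!is.na(windows$TNS), , drop = FALSE]
  col <- ifelse(w$TNS >= 0.6, "204,0,0",
         ifelse(w$TNS >= 0.4, "255,128,0",
         ifelse(w$TNS >= 0.1, "255,255,0", "255,255,204")))
  bed <- data.frame(chrom = w$chrom,
                    start = format(w$start, scientific = FALSE, trim = TRUE),
                    end = format(w$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("%s_%dg", sub(",.*", "", w$gene_ids), w$n_genes),
                    score = round(w$TNS * 1000),
                    strand = ".",
                    thickStart = format(w$start, scientific = FALSE, trim = TRUE),
                    thickEnd = format(w$end, scientific = FALSE, trim = TRUE),
                    itemRgb = col)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s" itemRgb="On" useScore=0', track_name), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(windows)
}

.write_tsv_commented <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
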