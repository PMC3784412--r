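#' Construct a genome annotation
#'
#' A `genome_annotation` is a data frame of genes (one row per gene) carrying
#' the coordinate backbone of every downstream computation. Coordinates are
#' stored 0-based half-open internally; printed gene tables in the literature
#' are usually 1-based inclusive, which is the default input convention.
#'
#' @param genes data frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand` (one of `+`, `-`, `*`) and optionally `probed` (logical,
#'   default `TRUE`).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp, or
#'   `NULL` to infer minimal sizes from the genes themselves.
#' @param coords input coordinate convention: `"1-based"` (inclusive, the
#'   printed-table dialect; converted by `start - 1`) or `"0-based"`
#'   (half-open, BED dialect; stored as is).
#' @return A `genome_annotation`: the gene data frame, 0-based half-open,
#'   with a `chrom_sizes` attribute.
#' @export
genome_annotation <- function(genes, chrom_sizes = NULL,
                              coords = c("1-based", "0-based")) {
  coords <- match.arg(coords)
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (is.null(genes$strand)) genes$strand <- "*"
  if (is.null(genes$probed)) genes$probed <- TRUE
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  if (coords == "1-based") genes$start <- genes$start - 1
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(!nzchar(genes$chrom))) stop("empty chromosome name")
  if (any(genes$start < 0)) stop("negative start coordinate")
  if (any(genes$end <= genes$start)) stop("interval with end <= start")
  genes$strand[!genes$strand %in% c("+", "-")] <- "*"
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  } else {
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
    absent <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(absent)) stop("genes on chromosomes absent from chrom_sizes: ",
                             paste(absent, collapse = ", "))
    over <- genes$end > chrom_sizes[genes$chrom]
    if (any(over)) stop("gene intervals extend past chromosome end: ",
                        paste(genes$gene_id[over], collapse = ", "))
  }
  rownames(genes) <- NULL
  structure(genes[, c("gene_id", "symbol", "chrom", "start", "end",
                      "strand", "probed")],
            chrom_sizes = chrom_sizes,
            class = c("genome_annotation", "data.frame"))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes (%d probed) on %d chromosome(s)\n",
              nrow(x), sum(x$probed), length(unique(x$chrom))))
  NextMethod()
}

#' Chromosome sizes of an annotation
#' @param ann a `genome_annotation`
#' @return named numeric vector of chromosome lengths (bp)
#' @export
chrom_sizes <- function(ann) attr(ann, "chrom_sizes")

.reclass_annotation <- function(genes, template) {
  structure(genes, chrom_sizes = attr(template, "chrom_sizes"),
            class = c("genome_annotation", "data.frame"))
}

#' Order genes along the genome
#'
#' Sorts genes per chromosome by (start, end), stably, and assigns a 0-based
#' `gene_index` within each chromosome (the x-axis of genome-wide score
#' tracks). Idempotent.
#'
#' @param ann a `genome_annotation`
#' @return the annotation, sorted, with a `gene_index` column
#' @export
order_genes <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (nrow(ann) == 0) {
    ann$gene_index <- integer(0)
    return(ann)
  }
  ord <- order(ann$chrom, ann$start, ann$end)
  genes <- as.data.frame(ann)[ord, , drop = FALSE]
  rownames(genes) <- NULL
  genes$gene_index <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                                 FUN = function(i) seq_along(i) - 1L)
  .reclass_annotation(genes, ann)
}

#' Collapse overlapping transcripts to one representative
#'
#' Transitively overlapping genes on a chromosome form an overlap component;
#' a single representative per component is retained so that all windowed
#' statistics operate on non-overlapping loci. The representative is the gene
#' with the most Present detection calls in `matrix` (genes absent from the
#' matrix count 0), ties broken by longest interval, then lexicographic
#' `gene_id`.
#'
#' @param ann an ordered `genome_annotation`
#' @param matrix an [expression_matrix()], or `NULL` to use interval length
#'   alone
#' @return the annotation restricted to the surviving genes, re-ordered
#' @export
resolve_overlaps <- function(ann, matrix = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (nrow(ann) == 0) return(order_genes(ann))
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1, ann$end))
  comp <- .overlap_components(gr)
  n_present <- rep(0L, nrow(ann))
  if (!is.null(matrix)) {
    idx <- match(ann$gene_id, rownames(matrix$calls))
    hit <- !is.na(idx)
    n_present[hit] <- rowSums(matrix$calls[idx[hit], , drop = FALSE] == "P")
  }
  span <- ann$end - ann$start
  keep <- vapply(split(seq_len(nrow(ann)), comp), function(i) {
    o <- order(-n_present[i], -span[i], ann$gene_id[i])
    i[o[1]]
  }, integer(1))
  order_genes(.reclass_annotation(as.data.frame(ann)[sort(keep), , drop = FALSE], ann))
}

# connected components of the interval-overlap graph; reduce() merges
# transitively overlapping ranges, so component = containing reduced range
.overlap_components <- function(gr) {
  red <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(gr, red)
  comp <- integer(length(gr))
  comp[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  comp
}

#' Interval span and printed-precision KB formatting
#'
#' @param start,end interval bounds, 0-based half-open
#' @return `interval_span`: span in bp.
#' @export
interval_span <- function(start, end) {
  stopifnot(all(end > start))
  end - start
}

#' @rdname interval_span
#' @param bp span in bp
#' @param decimals decimal places used below `integer_from` KB
#' @param integer_from KB size at and above which the value is rounded to a
#'   whole KB (printed gene-table convention)
#' @return `format_kb`: character KB rendering, e.g. `"33.2"` or `"1,276"`
#' @export
format_kb <- function(bp, decimals = 1, integer_from = 1000) {
  kb <- bp / 1000
  ifelse(kb >= integer_from,
         formatC(round(kb), format = "d", big.mark = ","),
         formatC(round(kb, decimals), format = "f", digits = decimals))
}

#' Overlap length of two intervals
#'
#' Half-open interval intersection; intervals on different chromosomes never
#' overlap. Vectorized.
#'
#' @param chrom_a,start_a,end_a first interval(s)
#' @param chrom_b,start_b,end_b second interval(s)
#' @return overlap in bp (0 if disjoint)
#' @export
overlap_length <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  len <- pmin(end_a, end_b) - pmax(start_a, start_b)
  len[chrom_a != chrom_b] <- 0
  pmax(len, 0)
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand` (and optionally `probed`)
#' @param chrom_sizes optional named vector or path to a two-column
#'   chrom.sizes file
#' @param coords input coordinate convention, see [genome_annotation()]
#' @return a `genome_annotation`
#' @export
read_annotation <- function(path, chrom_sizes = NULL, coords = "1-based") {
  genes <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(gene_id = "character",
                                            chrom = "character"))
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  genome_annotation(genes, chrom_sizes = chrom_sizes, coords = coords)
}

#' @rdname read_annotation
#' @export
read_chrom_sizes <- function(path) {
  cs <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(cs[[2]]), as.character(cs[[1]]))
}

#' @rdname read_annotation
#' @param ann annotation to write
#' @export
write_annotation <- function(ann, path) {
  out <- as.data.frame(ann)
  out$start <- out$start + 1  # back to 1-based inclusive on disk
  utils::write.table(out[, c("gene_id", "symbol", "chrom", "start", "end",
                             "strand", "probed")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
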