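#' Construct / read a synteny map
#'
#' A `synteny_map` stores, per comparison genome, the syntenic-block
#' assignment of every reference gene: `gene_id -> (block_id, order_index)`.
#' Block tables are produced upstream by a synteny-block finder over 1:1
#' orthologs; genes missing from a genome's table have no conserved placement
#' there and break synteny for any window containing them.
#'
#' @param blocks data frame with columns `genome`, `gene_id`, `block_id`,
#'   `order_index`
#' @return a `synteny_map`: named list (one element per genome) of data
#'   frames `(gene_id, block_id, order_index)`
#' @export
synteny_map <- function(blocks) {
  stopifnot(is.data.frame(blocks))
  need <- c("genome", "gene_id", "block_id", "order_index")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) stop("synteny table missing columns: ",
                         paste(miss, collapse = ", "))
  blocks$genome <- as.character(blocks$genome)
  blocks$gene_id <- as.character(blocks$gene_id)
  out <- lapply(split(blocks[c("gene_id", "block_id", "order_index")],
                      blocks$genome),
                function(df) {
                  if (anyDuplicated(df$gene_id)) {
                    stop("duplicate gene_id within one genome's block table")
                  }
                  dup <- stats::ave(df$order_index, df$block_id,
                                    FUN = function(x) anyDuplicated(x) > 0)
                  if (any(dup > 0)) stop("order_index not unique within a block")
                  rownames(df) <- NULL
                  df
                })
  structure(out, class = "synteny_map")
}

#' @rdname synteny_map
#' @param path TSV with header `genome`, `gene_id`, `block_id`, `order_index`
#' @export
read_synteny <- function(path) {
  synteny_map(utils::read.delim(path, stringsAsFactors = FALSE,
                                colClasses = c(gene_id = "character")))
}

#' @rdname synteny_map
#' @param smap map to write
#' @export
write_synteny <- function(smap, path) {
  df <- do.call(rbind, lapply(names(smap), function(g) {
    cbind(genome = g, smap[[g]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(smap)
}

#' Synteny score of a gene window
#'
#' The fraction of comparison genomes in which synteny is maintained for the
#' window: all window genes map to one common syntenic block in that genome.
#' A gene missing from a genome's block table breaks synteny there. With
#' `strict_order = TRUE`, the genes' order indices must additionally form a
#' contiguous monotone run within the block.
#'
#' @param gene_ids ids of the window's genes, in genome order
#' @param smap a [synteny_map()]
#' @param strict_order require preserved contiguous gene order (default off:
#'   block co-membership already encodes order at the block finder's
#'   resolution)
#' @return SS in `[0, 1]`
#' @export
synteny_score <- function(gene_ids, smap, strict_order = FALSE) {
  stopifnot(inherits(smap, "synteny_map"), length(smap) > 0)
  kept <- vapply(smap, function(df) {
    i <- match(gene_ids, df$gene_id)
    if (anyNA(i)) return(FALSE)
    blocks <- df$block_id[i]
    if (length(unique(blocks)) != 1) return(FALSE)
    if (strict_order) {
      o <- df$order_index[i]
      d <- diff(o)
      return(all(d == 1) || all(d == -1))
    }
    TRUE
  }, logical(1))
  mean(kept)
}

# per-genome window synteny, vectorized over all windows of size k on one
# chromosome: window [i, i+k-1] is intact in a genome iff no adjacent break
# (different block, or a missing gene) occurs inside it
.window_ss <- function(block_mat, k) {
  n <- nrow(block_mat)
  n_win <- n - k + 1
  if (n_win <= 0) return(numeric(0))
  if (k == 1) return(rep(1, n_win))
  kept <- matrix(0L, n_win, ncol(block_mat))
  for (g in seq_len(ncol(block_mat))) {
    b <- block_mat[, g]
    brk <- is.na(b[-n]) | is.na(b[-1]) | (b[-n] != b[-1])
    brk[is.na(brk)] <- TRUE
    s <- c(0, cumsum(as.integer(brk)))
    kept[, g] <- (s[seq_len(n_win) + (k - 1)] - s[seq_len(n_win)]) == 0L
  }
  rowMeans(kept)
}

# genes x genomes matrix of block ids (NA = missing), aligned to gene order
.block_matrix <- function(gene_ids, smap) {
  out <- vapply(smap, function(df) {
    as.character(df$block_id)[match(gene_ids, df$gene_id)]
  }, character(length(gene_ids)))
  matrix(out, nrow = length(gene_ids),
         dimnames = list(gene_ids, names(smap)))
}
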