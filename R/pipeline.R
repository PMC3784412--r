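#' Default pipeline configuration
#'
#' All analysis thresholds with their standard defaults: 5-Present filter,
#' window sizes 2-10, permutation alpha 0.05, 10 kb distance bins to 60 Mb,
#' DS band 2, log-ratio classification threshold 8, TNS bands 0.01 / 0.4,
#' hub cutoff 10, caller window 200 bp.
#'
#' @return named list of configuration defaults
#' @export
default_config <- function() {
  list(
    min_present = 5,
    min_k = 2, max_k = 10,
    n_perm = 1000, alpha = 0.05,
    method = "spearman",
    bin_width = 1e4, max_dist = 6e7,
    eps = 1, log_base = 2,
    ds_band = 2, class_thresh = 8,
    tns_lo = 0.01, tns_hi = 0.4,
    hub_min = 10,
    window_size = 200,
    seed = 1)
}

#' Run the end-to-end analysis
#'
#' Chains the stages over one input bundle: read and filter the expression
#' matrix, order the annotation and resolve overlapping transcripts,
#' distance-correlation profile, neighborhood scoring (TNS), per-gene and
#' per-neighborhood chromatin scores, gene and pair classifications, and the
#' summary statistics; writes every table (with provenance headers: package
#' version, config hash, seed) into `out_dir`. All randomness flows from
#' `config$seed`, so two runs with an identical config produce identical
#' outputs.
#'
#' @param config list with an `inputs` element (paths: `annotation`,
#'   `values`, `calls`, `samples`, `synteny`, `islands` = named list or the
#'   six `mam_k4` ... paths, optionally `chrom_sizes`) plus any overrides of
#'   [default_config()]; or the path of a YAML file with that structure
#' @param out_dir results directory (created)
#' @return invisibly, a list with the in-memory results
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config[setdiff(names(config), "inputs")])
  inputs <- config$inputs
  if (is.null(inputs)) stop("config must name its inputs")
  need <- c("annotation", "values", "calls", "samples", "synteny")
  island_keys <- c("mam_k4", "mam_k36", "mam_k27", "liv_k4", "liv_k36", "liv_k27")
  for (f in c(unlist(inputs[need]), unlist(inputs$islands))) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  miss <- setdiff(island_keys, names(inputs$islands))
  if (length(miss)) stop("missing island inputs: ", paste(miss, collapse = ", "))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(tool = paste("hoodscore", as.character(utils::packageVersion("hoodscore"))),
            config_hash = .config_hash(c(cfg, inputs)),
            seed = cfg$seed)

  ann <- read_annotation(inputs$annotation,
                         chrom_sizes = inputs$chrom_sizes,
                         coords = if (is.null(inputs$coords)) "1-based" else inputs$coords)
  m <- read_expression(inputs$values, inputs$calls, inputs$samples)
  m <- filter_min_present(m, cfg$min_present)
  orphan <- setdiff(rownames(m$values), ann$gene_id)
  if (length(orphan)) {
    stop("genes in the expression matrix but not the annotation: ",
         paste(utils::head(orphan, 10), collapse = ", "))
  }
  ann <- resolve_overlaps(order_genes(ann), m)
  keep <- rownames(m$values) %in% ann$gene_id
  m$values <- m$values[keep, , drop = FALSE]
  m$calls <- m$calls[keep, , drop = FALSE]
  smap <- read_synteny(inputs$synteny)
  islands <- lapply(stats::setNames(island_keys, island_keys), function(k) {
    read_islands(inputs$islands[[k]])
  })

  profile <- binned_distance_correlation(m, ann, bin_width = cfg$bin_width,
                                         max_dist = cfg$max_dist,
                                         method = cfg$method)
  baseline <- if (length(unique(ann$chrom)) > 1) {
    cross_chromosome_baseline(m, ann, method = cfg$method, seed = cfg$seed)
  } else NULL

  windows <- score_neighborhoods(m, ann, smap, min_k = cfg$min_k,
                                 max_k = cfg$max_k, n_perm = cfg$n_perm,
                                 seed = cfg$seed, alpha = cfg$alpha,
                                 method = cfg$method)
  windows <- neighborhood_ratios(windows, islands, eps = cfg$eps,
                                 base = cfg$log_base)
  best <- best_tns_per_gene(windows, ann)

  gene_chrom <- gene_chromatin_table(ann, islands, eps = cfg$eps,
                                     base = cfg$log_base)
  gene_chrom$class <- classify_gene(gene_chrom$log_cadr, gene_chrom$log_csdr,
                                    cfg$class_thresh, cfg$class_thresh)
  ds <- stats::setNames(gene_chrom$ds, gene_chrom$gene_id)
  dss <- ds_summary(ds, band = cfg$ds_band)

  # adjacent probed gene pairs, classified by joint chromatin state
  probed <- ann[ann$probed, , drop = FALSE]
  adj <- do.call(rbind, lapply(split(probed$gene_id, probed$chrom), function(g) {
    if (length(g) < 2) return(NULL)
    data.frame(gene_a = g[-length(g)], gene_b = g[-1], stringsAsFactors = FALSE)
  }))
  pair_class <- NULL
  if (!is.null(adj)) {
    adj$class <- classify_pair(ds[adj$gene_a], ds[adj$gene_b], t = cfg$ds_band)
    pair_class <- adj
  }
  partition <- active_gene_partition(
    stats::setNames(best$best_tns, best$gene_id)[gene_chrom$gene_id],
    gene_chrom$ds, ds_min = cfg$ds_band, tns_hi = cfg$tns_hi,
    tns_lo = cfg$tns_lo)

  .write_tsv_commented(profile, file.path(out_dir, "distance_profile.tsv"), prov)
  write_neighborhood_tsv(windows, file.path(out_dir, "neighborhoods.tsv"), prov)
  write_best_tns(best, file.path(out_dir, "best_tns.tsv"), prov)
  write_ucsc_track(windows, file.path(out_dir, "tns_track.bed"))
  .write_tsv_commented(gene_chrom, file.path(out_dir, "gene_chromatin.tsv"), prov)
  if (!is.null(pair_class)) {
    .write_tsv_commented(pair_class, file.path(out_dir, "pair_classes.tsv"), prov)
  }
  summary <- data.frame(
    key = c("n_genes", "n_windows", "baseline_corr", "ds_min", "ds_max",
            "ds_within_band_frac", "active_in_neighborhoods",
            "active_not_in_neighborhoods", "active_indeterminate"),
    value = c(nrow(ann), nrow(windows),
              if (is.null(baseline)) NA else baseline$mean_corr,
              dss$min, dss$max, dss$frac_within_band,
              partition[["in_neighborhoods"]],
              partition[["not_in_neighborhoods"]],
              partition[["indeterminate"]]))
  .write_tsv_commented(summary, file.path(out_dir, "summary.tsv"), prov)

  invisible(list(config = cfg, annotation = ann, matrix = m,
                 profile = profile, baseline = baseline, windows = windows,
                 best_tns = best, gene_chromatin = gene_chrom,
                 pair_classes = pair_class, partition = partition,
                 ds_summary = dss, provenance = prov))
}

# stable hash of the effective configuration (md5 of its canonical
# serialization; used only for provenance)
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}
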