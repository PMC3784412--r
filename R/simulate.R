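# Synthetic-data generators with planted ground truth. Defaults are sized
# for desk-scale runs (2,000 genes on 4 chromosomes, 40 samples) and emulate
# the statistical structure the analysis assumes: co-expressed syntenic
# neighborhoods, distance-decaying background correlation, tissue-specific
# broad chromatin domains, and clustered per-tissue detection calls at an
# ambient expressed rate of about 28%.

#' Simulate a gene annotation
#'
#' Non-overlapping genes laid down left to right per chromosome with
#' exponential intergenic gaps and gene lengths.
#'
#' @param n_genes total genes (split evenly across chromosomes)
#' @param n_chroms number of chromosomes
#' @param mean_gene_len,mean_gap exponential means in bp
#' @param probed_frac fraction of genes carried on the (synthetic)
#'   microarray
#' @param seed RNG seed
#' @return a [genome_annotation()], ordered
#' @export
simulate_genome <- function(n_genes = 2000, n_chroms = 4,
                            mean_gene_len = 15000, mean_gap = 35000,
                            probed_frac = 1, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (n_genes == 0) {
    return(order_genes(genome_annotation(
      data.frame(gene_id = character(0), symbol = character(0),
                 chrom = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), probed = logical(0)),
      coords = "0-based")))
  }
  per <- diff(round(seq(0, n_genes, length.out = n_chroms + 1)))
  rows <- list()
  sizes <- numeric(n_chroms)
  names(sizes) <- sprintf("chr%d", seq_len(n_chroms))
  gid <- 0
  for (ci in seq_len(n_chroms)) {
    n <- per[ci]
    gaps <- stats::rexp(n, 1 / mean_gap) + 500
    lens <- round(stats::rexp(n, 1 / mean_gene_len)) + 1000
    starts <- round(cumsum(gaps) + cumsum(c(0, lens[-n])))
    rows[[ci]] <- data.frame(
      gene_id = sprintf("G%05d", gid + seq_len(n)),
      symbol = sprintf("G%05d", gid + seq_len(n)),
      chrom = names(sizes)[ci],
      start = starts, end = starts + lens,
      strand = sample(c("+", "-"), n, replace = TRUE),
      probed = stats::runif(n) < probed_frac,
      stringsAsFactors = FALSE)
    sizes[ci] <- max(rows[[ci]]$end) + mean_gap
    gid <- gid + n
  }
  order_genes(genome_annotation(do.call(rbind, rows), chrom_sizes = sizes,
                                coords = "0-based"))
}

#' Plant ground truth on a simulated genome
#'
#' Chooses non-overlapping runs of probed genes as planted co-expression
#' neighborhoods and as planted chromatin domains (active = H3K4me2 +
#' H3K36me3 in the tissue of interest; silenced = a broad H3K27me3 block),
#' and records the background correlation-decay parameters.
#'
#' @param ann an ordered [genome_annotation()]
#' @param n_plants number of planted co-expression neighborhoods
#' @param plant_size genes per planted neighborhood
#' @param target_anc the neighborhoods' target average pairwise correlation
#' @param n_protect comparison genomes in which each plant's synteny is
#'   protected
#' @param n_domains planted chromatin domains (split active / silenced)
#' @param domain_genes genes covered by each planted domain
#' @param decay_c,decay_tau background correlation decay
#'   `corr(d) = c * exp(-d / tau)` (c = 0 disables it)
#' @param seed RNG seed
#' @return a `synthetic_truth`: list with `plants` and `domains` data
#'   frames, `decay`, and the seed
#' @export
synthetic_truth <- function(ann, n_plants = 20, plant_size = 4,
                            target_anc = 0.8, n_protect = 8,
                            n_domains = 12, domain_genes = 3,
                            decay_c = 0, decay_tau = 2e5, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  probed <- ann[ann$probed, , drop = FALSE]
  pick_runs <- function(n_runs, run_len, spacing, taken) {
    rows <- list()
    for (chr in unique(probed$chrom)) {
      idx <- which(probed$chrom == chr)
      n <- length(idx)
      if (n < run_len) next
      cand <- seq(1, n - run_len + 1)
      rows[[chr]] <- data.frame(chrom = chr, first = cand)
    }
    cand <- do.call(rbind, rows)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    chosen <- list()
    used <- taken
    for (i in seq_len(nrow(cand))) {
      if (length(chosen) >= n_runs) break
      key <- paste(cand$chrom[i], seq(cand$first[i] - spacing,
                                      cand$first[i] + run_len - 1 + spacing))
      if (any(key %in% used)) next
      used <- c(used, key)
      chosen[[length(chosen) + 1]] <- cand[i, ]
    }
    list(runs = do.call(rbind, chosen), used = used)
  }
  spacing <- 10  # keep plants and domains more than a max window apart
  pl <- pick_runs(n_plants, plant_size, spacing, character(0))
  dm <- pick_runs(n_domains, domain_genes, spacing, pl$used)
  run_span <- function(df, run_len, pad = 2000) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(chrom = character(0), first = integer(0),
                        start = numeric(0), end = numeric(0),
                        gene_ids = character(0)))
    }
    do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      idx <- which(probed$chrom == df$chrom[i])[df$first[i] + seq_len(run_len) - 1]
      data.frame(chrom = df$chrom[i], first = df$first[i],
                 start = max(0, min(probed$start[idx]) - pad),
                 end = max(probed$end[idx]) + pad,
                 gene_ids = paste(probed$gene_id[idx], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  plants <- run_span(pl$runs, plant_size)
  if (nrow(plants)) {
    plants$k <- plant_size
    plants$anc <- target_anc
    plants$n_protect <- n_protect
  }
  domains <- run_span(dm$runs, domain_genes)
  if (nrow(domains)) {
    domains$kind <- rep_len(c("active", "silenced"), nrow(domains))
    domains$tissue <- "mammary"
  }
  structure(list(plants = plants, domains = domains,
                 decay = list(c = decay_c, tau = decay_tau),
                 plant_size = plant_size, domain_genes = domain_genes,
                 seed = seed),
            class = "synthetic_truth")
}

#' Simulate an expression matrix with detection calls
#'
#' Planted neighborhoods share a latent per-condition profile mixed with
#' noise to hit the target ANC; background genes carry a chromosome-local
#' latent factor whose correlation decays as `c * exp(-d / tau)` with
#' start-site distance (an AR(1) field along the gene order). Values are
#' log2 intensities; Present calls arise where the value clears a
#' threshold. With the tissue design, per-tissue expressed flags follow a
#' genome-order Markov chain with the given ambient expressed rate, and
#' expressed genes are shifted up in that tissue's samples.
#'
#' @param ann an ordered [genome_annotation()]
#' @param truth a [synthetic_truth()] (plants and decay honored)
#' @param design `"timepoints"` (one tissue over a time course) or
#'   `"tissues"` (many tissues, few replicates)
#' @param n_conditions number of timepoints or tissues
#' @param reps replicates per condition
#' @param base_mean,base_sd per-gene baseline log2 intensity distribution
#' @param expressed_rate ambient per-tissue expressed fraction (tissue
#'   design)
#' @param persistence probability that an expressed gene's genomic neighbor
#'   is expressed too (tissue design; clusters the expressed flags)
#' @param p_cut,m_cut detection-call thresholds on the log2 value
#' @param seed RNG seed
#' @return list `(matrix, expressed_truth)`: the [expression_matrix()] and,
#'   for the tissue design, the true expressed flags (genes x tissues)
#' @export
simulate_expression <- function(ann, truth, design = c("timepoints", "tissues"),
                                n_conditions = if (design == "timepoints") 10 else 20,
                                reps = if (design == "timepoints") 4 else 2,
                                base_mean = 6.5, base_sd = 0.8,
                                expressed_rate = 0.28, persistence = 0.6,
                                p_cut = 6, m_cut = 5.6, seed = 1) {
  design <- match.arg(design)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  probed <- ann[ann$probed, , drop = FALSE]
  n <- nrow(probed)
  n_samples <- n_conditions * reps
  cond <- rep(seq_len(n_conditions), each = reps)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    tissue = if (design == "timepoints") "mammary" else
      sprintf("tissue%02d", cond),
    timepoint = if (design == "timepoints") cond else 1L,
    replicate = rep(seq_len(reps), n_conditions),
    stringsAsFactors = FALSE)

  # background latent field per condition, AR(1) along each chromosome so
  # corr(g, h) = exp(-dist(g, h) / tau)
  b <- matrix(0, n, n_conditions)
  if (truth$decay$c > 0) {
    for (chr in unique(probed$chrom)) {
      idx <- which(probed$chrom == chr)
      b[idx[1], ] <- stats::rnorm(n_conditions)
      if (length(idx) > 1) {
        rho <- exp(-diff(probed$start[idx]) / truth$decay$tau)
        for (j in seq_along(rho)) {
          b[idx[j + 1], ] <- rho[j] * b[idx[j], ] +
            sqrt(1 - rho[j]^2) * stats::rnorm(n_conditions)
        }
      }
    }
  }
  c_bg <- truth$decay$c
  load_bg <- rep(sqrt(c_bg), n)
  shared <- sqrt(c_bg) * b

  # planted neighborhoods override the background factor with a plant-shared
  # profile at loading sqrt(target ANC)
  if (nrow(truth$plants)) {
    for (i in seq_len(nrow(truth$plants))) {
      ids <- strsplit(truth$plants$gene_ids[i], ",", fixed = TRUE)[[1]]
      gi <- match(ids, probed$gene_id)
      u <- stats::rnorm(n_conditions)
      # unit empirical variance so the realized ANC centers on the target
      if (n_conditions > 1) u <- (u - mean(u)) / stats::sd(u)
      a <- truth$plants$anc[i]
      shared[gi, ] <- sqrt(a) * matrix(u, length(gi), n_conditions, byrow = TRUE)
      load_bg[gi] <- sqrt(a)
    }
  }
  signal <- shared[, cond, drop = FALSE] +
    sqrt(1 - load_bg^2) * matrix(stats::rnorm(n * n_samples), n, n_samples)

  mu <- stats::rnorm(n, base_mean, base_sd)
  if (nrow(truth$plants)) {
    # planted neighborhoods emulate robustly expressed co-regulated
    # clusters: keep their baseline above the detection floor
    plant_ids <- unlist(strsplit(truth$plants$gene_ids, ",", fixed = TRUE))
    pi_ <- match(plant_ids, probed$gene_id)
    mu[pi_] <- pmax(mu[pi_], base_mean)
  }
  values <- mu + signal
  expressed_truth <- NULL
  if (design == "tissues") {
    # clustered per-tissue expressed flags: Markov chain along gene order
    p_stay <- persistence
    p_gain <- expressed_rate * (1 - p_stay) / (1 - expressed_rate)
    expressed_truth <- matrix(FALSE, n, n_conditions,
                              dimnames = list(probed$gene_id,
                                              sprintf("tissue%02d",
                                                      seq_len(n_conditions))))
    for (t in seq_len(n_conditions)) {
      for (chr in unique(probed$chrom)) {
        idx <- which(probed$chrom == chr)
        f <- logical(length(idx))
        f[1] <- stats::runif(1) < expressed_rate
        for (j in seq_along(idx)[-1]) {
          f[j] <- stats::runif(1) < if (f[j - 1]) p_stay else p_gain
        }
        expressed_truth[idx, t] <- f
      }
    }
    shift <- 2 * (expressed_truth[, cond, drop = FALSE] * 2 - 1)
    values <- values + shift
  }
  dimnames(values) <- list(probed$gene_id, samples$sample_id)
  calls <- matrix("A", n, n_samples, dimnames = dimnames(values))
  calls[values >= m_cut] <- "M"
  calls[values >= p_cut] <- "P"
  list(matrix = expression_matrix(round(values, 4), calls, samples),
       expressed_truth = expressed_truth)
}

#' Simulate synteny-block tables for comparison genomes
#'
#' Each comparison genome is the reference gene order fragmented by
#' Bernoulli breakpoints between adjacent genes, with genes dropped at
#' `missing_rate` (no 1:1 ortholog there). Each planted neighborhood is
#' protected in `n_protect` randomly chosen genomes: no internal breakpoint,
#' no dropout.
#'
#' @param ann an ordered [genome_annotation()]
#' @param truth a [synthetic_truth()] (plants honored; `NULL` for none)
#' @param n_genomes number of comparison genomes
#' @param breakpoint_rate per-adjacency breakpoint probability
#' @param missing_rate per-gene dropout probability
#' @param seed RNG seed
#' @return a [synteny_map()]
#' @export
simulate_synteny <- function(ann, truth = NULL, n_genomes = 10,
                             breakpoint_rate = 0.05, missing_rate = 0.1,
                             seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  probed <- ann[ann$probed, , drop = FALSE]
  plants <- if (!is.null(truth)) truth$plants else NULL
  rows <- list()
  for (g in seq_len(n_genomes)) {
    gname <- sprintf("genome%02d", g)
    protect_gene <- character(0)
    protect_adj <- character(0)  # adjacency keyed by left gene id
    if (!is.null(plants) && nrow(plants)) {
      for (i in seq_len(nrow(plants))) {
        sel <- .plant_genomes(plants$chrom[i], plants$first[i],
                              plants$n_protect[i], n_genomes, truth$seed)
        if (g %in% sel) {
          ids <- strsplit(plants$gene_ids[i], ",", fixed = TRUE)[[1]]
          protect_gene <- c(protect_gene, ids)
          protect_adj <- c(protect_adj, ids[-length(ids)])
        }
      }
    }
    for (chr in unique(probed$chrom)) {
      idx <- which(probed$chrom == chr)
      nc <- length(idx)
      brk <- stats::runif(nc - 1) < breakpoint_rate
      drop <- stats::runif(nc) < missing_rate
      ids <- probed$gene_id[idx]
      brk[ids[-nc] %in% protect_adj] <- FALSE
      drop[ids %in% protect_gene] <- FALSE
      block <- cumsum(c(1L, as.integer(brk)))
      keep <- !drop
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- data.frame(
        genome = gname, gene_id = ids[keep],
        block_id = sprintf("%s_%s_b%03d", gname, chr, block[keep]),
        order_index = stats::ave(block[keep], block[keep], FUN = seq_along),
        stringsAsFactors = FALSE)
    }
  }
  synteny_map(do.call(rbind, rows))
}

# deterministic per-plant choice of protected genomes (stable across the
# synteny draw)
.plant_genomes <- function(chrom, first, n_protect, n_genomes, seed) {
  h <- sum(utf8ToInt(paste(chrom, first))) + seed
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(h %% .Machine$integer.max)
  sample.int(n_genomes, min(n_protect, n_genomes))
}

#' Simulate broad-mark island sets for two tissues
#'
#' Background islands are placed identically in both tissues (heights
#' jittered) so their domain ratios sit near 1; planted active domains add
#' H3K4me2 and H3K36me3 islands in the plant's tissue only, planted silenced
#' domains add a broad H3K27me3 block there.
#'
#' @param truth a [synthetic_truth()] (domains honored)
#' @param chrom_sizes named chromosome lengths
#' @param background_per_mb background islands per Mb per mark
#' @param bg_mean_width mean background island width (bp)
#' @param bg_height,planted_height island heights (score units)
#' @param height_jitter_sd sd of the log-normal tissue jitter on background
#'   heights
#' @param seed RNG seed
#' @return named list of six [island_set()]s: `mam_k4`, `mam_k36`,
#'   `mam_k27`, `liv_k4`, `liv_k36`, `liv_k27`
#' @export
simulate_islands <- function(truth, chrom_sizes, background_per_mb = 2,
                             bg_mean_width = 2000, bg_height = 10,
                             planted_height = 50, height_jitter_sd = 0.15,
                             seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  marks <- c("k4", "k36", "k27")
  bg <- lapply(marks, function(mk) {
    rows <- list()
    for (chr in names(chrom_sizes)) {
      size <- chrom_sizes[[chr]]
      n <- stats::rpois(1, background_per_mb * size / 1e6)
      if (!n) next
      w <- round(stats::rexp(n, 1 / bg_mean_width)) + 400
      s <- sort(round(stats::runif(n, 0, size - max(w))))
      e <- s + w
      # greedy non-overlap: drop islands starting before the previous end
      keep <- logical(n); last_end <- -1
      for (i in seq_len(n)) {
        keep[i] <- s[i] > last_end
        if (keep[i]) last_end <- e[i]
      }
      rows[[chr]] <- data.frame(chrom = chr, start = s[keep], end = e[keep])
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0))
    df
  })
  names(bg) <- marks
  jitter_h <- function(df) {
    df$height <- bg_height * exp(stats::rnorm(nrow(df), 0, height_jitter_sd))
    df
  }
  sets <- list()
  dom <- truth$domains
  for (tissue in c("mam", "liv")) {
    for (mk in marks) {
      df <- jitter_h(bg[[mk]])
      planted <- dom[dom$kind == (if (mk == "k27") "silenced" else "active") &
                       dom$tissue == (if (tissue == "mam") "mammary" else "liver"), ,
                     drop = FALSE]
      if (nrow(planted)) {
        # background islands overlapping a plant are displaced by it
        hit <- overlap_any(df, planted)
        df <- df[!hit, , drop = FALSE]
        df <- rbind(df, data.frame(chrom = planted$chrom,
                                   start = planted$start, end = planted$end,
                                   height = planted_height))
      }
      sets[[paste0(tissue, "_", mk)]] <-
        island_set(df, mark = toupper(mk), tissue = tissue)
    }
  }
  sets
}

#' Any-overlap indicator between two interval tables
#'
#' @param a,b data frames with `chrom`, `start`, `end` (0-based half-open)
#' @return logical vector along `a`
#' @export
overlap_any <- function(a, b) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
  IRanges::overlapsAny(ga, gb)
}

#' Simulate mapped tags over planted domains
#'
#' Uniform tag placement at a high rate inside planted domains and a low
#' rate outside. Broad domains can be made internally gappy: zero-tag
#' dropout holes of exponential length alternate with kept segments,
#' emulating the patchiness of broad repressive marks.
#'
#' @param domains data frame `(chrom, start, end)` of planted enriched
#'   domains
#' @param chrom_sizes named chromosome lengths
#' @param reads_per_kb_in,reads_per_kb_out tag rates inside kept domain
#'   segments and in the background
#' @param gappy carve dropout holes inside domains?
#' @param hole_mean_len,seg_mean_len exponential means (bp) of holes and
#'   kept segments
#' @param seed RNG seed
#' @return a [tag_library()]
#' @export
simulate_tags <- function(domains, chrom_sizes, reads_per_kb_in = 25,
                          reads_per_kb_out = 0.5, gappy = FALSE,
                          hole_mean_len = 600, seg_mean_len = 1500,
                          seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  place <- function(chr, lo, hi, rate_per_kb) {
    n <- stats::rpois(1, (hi - lo) / 1000 * rate_per_kb)
    if (!n) return(NULL)
    data.frame(chrom = chr, pos = floor(stats::runif(n, lo, hi)))
  }
  rows <- list()
  for (chr in names(chrom_sizes)) {
    rows[[length(rows) + 1]] <- place(chr, 0, chrom_sizes[[chr]],
                                      reads_per_kb_out)
  }
  if (!is.null(domains) && nrow(domains)) {
    for (i in seq_len(nrow(domains))) {
      lo <- domains$start[i]; hi <- domains$end[i]
      segs <- if (gappy) .carve_segments(lo, hi, seg_mean_len, hole_mean_len)
              else data.frame(lo = lo, hi = hi)
      for (j in seq_len(nrow(segs))) {
        rows[[length(rows) + 1]] <- place(domains$chrom[i], segs$lo[j],
                                          segs$hi[j], reads_per_kb_in)
      }
    }
  }
  tags <- do.call(rbind, rows)
  if (is.null(tags)) tags <- data.frame(chrom = character(0), pos = numeric(0))
  tags$strand <- "+"
  tag_library(tags, chrom_sizes)
}

.carve_segments <- function(lo, hi, seg_mean, hole_mean) {
  segs <- list()
  pos <- lo
  while (pos < hi) {
    seg_len <- max(200, round(stats::rexp(1, 1 / seg_mean)))
    segs[[length(segs) + 1]] <- data.frame(lo = pos, hi = min(pos + seg_len, hi))
    pos <- pos + seg_len + max(200, round(stats::rexp(1, 1 / hole_mean)))
  }
  do.call(rbind, segs)
}

#' Generate and write a full synthetic input bundle
#'
#' Runs every generator with a single seed and writes annotation,
#' expression matrix + calls + sample sheet, synteny table, the six island
#' files, and the ground truth (JSON) into `dir`.
#'
#' @param dir output directory (created)
#' @param seed master seed; each generator derives its own stream from it
#' @param n_genes,n_chroms genome size
#' @param design,n_conditions,reps expression design (see
#'   [simulate_expression()])
#' @param n_plants,plant_size,target_anc,n_protect planted neighborhoods
#' @param decay_c,decay_tau background correlation decay
#' @param n_domains planted chromatin domains
#' @param ... passed to [simulate_islands()]
#' @return invisibly, a list with the generated objects and file paths
#' @export
simulate_bundle <- function(dir, seed = 1, n_genes = 2000, n_chroms = 4,
                            design = "timepoints", n_conditions = 10,
                            reps = 4, n_plants = 20, plant_size = 4,
                            target_anc = 0.8, n_protect = 8,
                            decay_c = 0, decay_tau = 2e5, n_domains = 12,
                            ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_genome(n_genes = n_genes, n_chroms = n_chroms, seed = seed)
  truth <- synthetic_truth(ann, n_plants = n_plants, plant_size = plant_size,
                           target_anc = target_anc, n_protect = n_protect,
                           n_domains = n_domains, decay_c = decay_c,
                           decay_tau = decay_tau, seed = seed + 1)
  expr <- simulate_expression(ann, truth, design = design,
                              n_conditions = n_conditions, reps = reps,
                              seed = seed + 2)
  smap <- simulate_synteny(ann, truth, seed = seed + 3)
  islands <- simulate_islands(truth, chrom_sizes(ann), seed = seed + 4, ...)

  paths <- list(
    annotation = file.path(dir, "annotation.tsv"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    values = file.path(dir, "expression_values.tsv"),
    calls = file.path(dir, "expression_calls.tsv"),
    samples = file.path(dir, "samples.tsv"),
    synteny = file.path(dir, "synteny.tsv"),
    truth = file.path(dir, "truth.json"))
  write_annotation(ann, paths$annotation)
  utils::write.table(data.frame(names(chrom_sizes(ann)), chrom_sizes(ann)),
                     paths$chrom_sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_expression(expr$matrix, paths$values, paths$calls, paths$samples)
  write_synteny(smap, paths$synteny)
  for (nm in names(islands)) {
    paths[[nm]] <- file.path(dir, sprintf("islands_%s.bed", nm))
    write_islands(islands[[nm]], paths[[nm]])
  }
  jsonlite::write_json(
    list(seed = seed, plants = truth$plants, domains = truth$domains,
         decay = truth$decay),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(ann = ann, truth = truth, expr = expr, smap = smap,
                 islands = islands, paths = paths))
}
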