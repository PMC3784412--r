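test_that("window enumeration matches the combinatorial count", {
  ann5 <- order_genes(make_ann(seq(0, 4e4, 1e4), seq(0, 4e4, 1e4) + 5000))
  w5 <- enumerate_windows(ann5)
  expect_equal(nrow(w5), 4 + 3 + 2 + 1)

  ann1 <- order_genes(make_ann(0, 100))
  expect_equal(nrow(enumerate_windows(ann1)), 0)

  ann12 <- order_genes(make_ann(seq(0, 11e4, 1e4), seq(0, 11e4, 1e4) + 5000))
  w12 <- enumerate_windows(ann12)
  # brute-force oracle: sum over k of max(0, n - k + 1)
  expect_equal(nrow(w12), sum(pmax(0, 12 - (2:10) + 1)))
  expect_equal(nrow(w12), 63)

  expect_error(enumerate_windows(ann5, min_k = 1), "at least 2")
  # unprobed genes are skipped: adjacency runs over the probed sequence
  ann_mix <- order_genes(make_ann(seq(0, 4e4, 1e4), seq(0, 4e4, 1e4) + 5000,
                                  probed = c(TRUE, FALSE, TRUE, TRUE, FALSE)))
  expect_equal(nrow(enumerate_windows(ann_mix)), 2 + 1)
})

test_that("anc equals the brute-force mean of pairwise correlations", {
  set.seed(21)
  vals <- matrix(rnorm(4 * 12), 4, 12,
                 dimnames = list(sprintf("g%d", 1:4), NULL))
  m <- make_expr(vals)
  expect_equal(anc(c("g1", "g2"), m), pairwise_correlation(m, "g1", "g2"))
  ident <- make_expr(matrix(rep(1:10, 3), 3, 10, byrow = TRUE,
                            dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(anc(c("a", "b", "c"), ident), 1)
  expect_equal(anc(sprintf("g%d", 1:4), m), bf_anc(vals, sprintf("g%d", 1:4)))
  flat <- make_expr(rbind(a = rep(1, 8), b = rnorm(8)))
  expect_true(is.na(anc(c("a", "b"), flat)))
})

test_that("synteny_score counts genomes where all genes share one block", {
  ids <- c("g1", "g2", "g3")
  same <- synteny_map(do.call(rbind, lapply(1:10, function(g) {
    data.frame(genome = sprintf("gen%02d", g), gene_id = ids,
               block_id = "b1", order_index = 1:3)
  })))
  expect_equal(synteny_score(ids, same), 1)

  half <- synteny_map(do.call(rbind, lapply(1:10, function(g) {
    data.frame(genome = sprintf("gen%02d", g), gene_id = ids,
               block_id = if (g <= 5) "b1" else c("b1", "b1", "b2"),
               order_index = c(1, 2, if (g <= 5) 3 else 1))
  })))
  expect_equal(synteny_score(ids, half), 0.5)

  # missing gene breaks synteny in that genome
  missing <- synteny_map(rbind(
    data.frame(genome = "gen01", gene_id = c("g1", "g2"), block_id = "b1",
               order_index = 1:2),
    data.frame(genome = "gen02", gene_id = ids, block_id = "b1",
               order_index = 1:3)))
  expect_equal(synteny_score(ids, missing), 0.5)

  # randomized assignments equal the exhaustive per-genome oracle
  set.seed(22)
  for (rep in 1:10) {
    blocks <- do.call(rbind, lapply(1:6, function(g) {
      data.frame(genome = sprintf("gen%02d", g), gene_id = ids,
                 block_id = sample(c("b1", "b2"), 3, TRUE),
                 order_index = sample(100, 3))
    }))
    smap <- synteny_map(blocks)
    oracle <- mean(sapply(split(blocks, blocks$genome), function(df) {
      length(unique(df$block_id[match(ids, df$gene_id)])) == 1
    }))
    expect_equal(synteny_score(ids, smap), oracle)
  }
})

test_that("SS is monotone: a window scores no higher than its sub-windows", {
  set.seed(23)
  ids <- sprintf("g%02d", 1:8)
  for (rep in 1:10) {
    blocks <- do.call(rbind, lapply(1:5, function(g) {
      keep <- runif(8) > 0.15
      data.frame(genome = sprintf("gen%02d", g), gene_id = ids[keep],
                 block_id = sample(c("b1", "b2", "b3"), sum(keep), TRUE),
                 order_index = sample(100, sum(keep)))
    }))
    smap <- synteny_map(blocks)
    for (k in 3:8) {
      for (i in seq_len(8 - k + 1)) {
        win <- ids[i:(i + k - 1)]
        ss <- synteny_score(win, smap)
        for (j in seq_len(k - 1)) {
          expect_lte(ss, synteny_score(win[j:(j + 1)], smap))
        }
      }
    }
  }
})

test_that("tns applies the significance gate and the [0, 1] clamp", {
  expect_equal(tns(1, 0.7, 0.001), 0.7)
  expect_equal(tns(0.9, 0.8, 0.06), 0)     # p above alpha
  expect_equal(tns(-0.4, 1, 0.01), 0)      # negative ANC cannot score
  expect_true(is.na(tns(NA, 1, 0.01)))
  set.seed(24)
  a <- runif(200, -1, 1); s <- runif(200); p <- runif(200)
  out <- tns(a, s, p)
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(out[p > 0.05] == 0))
})

test_that("anc_null with explicit permutations equals exhaustive enumeration", {
  set.seed(25)
  ids <- c("a", "b", "c")
  vals <- matrix(rnorm(18), 3, 6, dimnames = list(ids, NULL))
  m <- make_expr(vals)
  ann <- order_genes(make_ann(c(0, 1e4, 2e4), c(5e3, 1.5e4, 2.5e4),
                              gene_id = ids))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  null <- anc_null(m, ann, k = 2, permutations = perms)
  # oracle: each permutation contributes both adjacent-pair correlations
  oracle <- c()
  for (i in seq_len(nrow(perms))) {
    v <- vals[perms[i, ], ]
    oracle <- c(oracle, cor(v[1, ], v[2, ], method = "spearman"),
                cor(v[2, ], v[3, ], method = "spearman"))
  }
  expect_equal(sort(null), sort(oracle))
})

test_that("score_neighborhoods output respects the score invariants", {
  set.seed(26)
  ann <- simulate_genome(n_genes = 120, n_chroms = 2, seed = 41)
  truth <- synthetic_truth(ann, n_plants = 2, plant_size = 3, seed = 42)
  m <- filter_min_present(simulate_expression(ann, truth, seed = 43)$matrix)
  smap <- simulate_synteny(ann, truth, seed = 44)
  w <- score_neighborhoods(m, ann, smap, n_perm = 200, seed = 45)
  ok <- !is.na(w$TNS)
  expect_true(all(w$TNS[ok] >= 0 & w$TNS[ok] <= 1))
  expect_true(all(w$TNS[ok & w$p > 0.05] == 0))
  expect_true(all(w$SS >= 0 & w$SS <= 1))
  expect_true(all(w$end > w$start))
  # ANC spot-check against the direct per-window computation
  pick <- sample(which(ok), 10)
  for (i in pick) {
    ids <- strsplit(w$gene_ids[i], ",")[[1]]
    expect_equal(w$ANC[i], anc(ids, m), tolerance = 1e-10)
  }
  expect_error(score_neighborhoods(m, ann, smap, n_perm = 10), "at least 100")
})

test_that("best_tns_per_gene takes the max over covering windows", {
  w <- data.frame(chrom = "chr1", start = c(0, 0, 10), end = c(20, 30, 40),
                  n_genes = 2, first = 1,
                  gene_ids = c("a,b", "a,b,c", "b,c"),
                  TNS = c(0, 0.3, 0.69))
  ann <- order_genes(make_ann(c(0, 10, 30, 100), c(5, 20, 40, 110),
                              gene_id = c("a", "b", "c", "lonely")))
  best <- best_tns_per_gene(w, ann)
  got <- setNames(best$best_tns, best$gene_id)
  expect_equal(got[["a"]], 0.3)
  expect_equal(got[["b"]], 0.69)
  expect_equal(got[["c"]], 0.69)
  expect_equal(got[["lonely"]], 0)

  # toy genome: equals the brute-force max over enumerated windows
  set.seed(27)
  ann2 <- simulate_genome(n_genes = 30, n_chroms = 1, seed = 51)
  truth <- synthetic_truth(ann2, n_plants = 1, plant_size = 3, seed = 52)
  m <- simulate_expression(ann2, truth, seed = 53)$matrix
  smap <- simulate_synteny(ann2, truth, seed = 54)
  w2 <- score_neighborhoods(m, ann2, smap, n_perm = 100, seed = 55)
  best2 <- setNames(best_tns_per_gene(w2, ann2)$best_tns,
                    best_tns_per_gene(w2, ann2)$gene_id)
  for (g in sample(ann2$gene_id, 8)) {
    covering <- w2$TNS[vapply(strsplit(w2$gene_ids, ","),
                              function(x) g %in% x, logical(1))]
    covering <- covering[!is.na(covering)]
    expect_equal(unname(best2[g]), if (length(covering)) max(covering) else 0)
  }
})

test_that("run, isolated-gene and sharing logic follows the call patterns", {
  starts <- seq(0, 5e4, 1e4)
  ann <- order_genes(make_ann(starts, starts + 5e3))
  flags <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  runs <- present_run_neighborhoods(flags, ann)
  expect_equal(runs$gene_ids, c("g01,g02", "g04,g05,g06"))
  expect_equal(runs$n_genes, c(2L, 3L))
  expect_equal(nrow(present_run_neighborhoods(rep(FALSE, 6), ann)), 0)

  expect_equal(isolated_genes(c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE), ann),
               "g02")
  expect_equal(isolated_genes(c(TRUE, TRUE, rep(FALSE, 4)), ann), character(0))

  # random patterns vs the brute-force run finder
  set.seed(28)
  for (rep in 1:20) {
    f <- runif(6) < 0.5
    got <- present_run_neighborhoods(f, ann)
    oracle <- bf_runs(f)
    expect_equal(nrow(got), length(oracle))
    if (length(oracle)) {
      expect_equal(got$gene_ids,
                   sapply(oracle, function(i) paste(ann$gene_id[i], collapse = ",")))
    }
    iso_oracle <- ann$gene_id[sapply(seq_along(f), function(i) {
      f[i] && !(i > 1 && f[i - 1]) && !(i < 6 && f[i + 1])
    })]
    expect_equal(isolated_genes(f, ann), iso_oracle)
  }

  # sharing percentages
  runs3 <- data.frame(gene_ids = c("a,b", "c,d", "e,f"))
  all_b <- setNames(rep(TRUE, 6), letters[1:6])
  none_b <- setNames(rep(FALSE, 6), letters[1:6])
  part_b <- setNames(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), letters[1:6])
  expect_equal(shared_fraction(runs3, all_b), 100)
  expect_equal(shared_fraction(runs3, none_b), 0)
  expect_equal(shared_fraction(runs3, part_b), 200 / 3)
})

test_that("membership_excess_test matches exhaustive enumeration and finds planted runs", {
  starts <- seq(0, 5e4, 1e4)
  ann <- order_genes(make_ann(starts, starts + 5e3))
  # all genes expressed: every permutation ties the observed count, p = 1
  res_all <- membership_excess_test(rep(TRUE, 6), ann, n_perm = 100, seed = 1)
  expect_equal(res_all$in_run_p, 1)
  expect_equal(res_all$in_run_obs, 6)

  # exhaustive permutations of 6 genes vs direct enumeration
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 6), ]
  flags <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- membership_excess_test(flags, ann, permutations = perms)
  in_run <- function(f) sum(f & (c(FALSE, f[-6]) | c(f[-1], FALSE)))
  iso <- function(f) sum(f & !c(FALSE, f[-6]) & !c(f[-1], FALSE))
  counts <- apply(perms, 1, function(p) in_run(flags[p]))
  isos <- apply(perms, 1, function(p) iso(flags[p]))
  expect_equal(res$in_run_p,
               (1 + sum(counts >= in_run(flags))) / (1 + nrow(perms)))
  expect_equal(res$isolated_p,
               (1 + sum(isos <= iso(flags))) / (1 + nrow(perms)))

  # planted clustering: expressed genes packed into runs give a small p
  big_starts <- seq(0, 99e4, 1e4)
  big_ann <- order_genes(make_ann(big_starts, big_starts + 5e3))
  clustered <- rep(FALSE, 100)
  clustered[c(11:16, 41:46, 71:76)] <- TRUE
  res_cl <- membership_excess_test(clustered, big_ann, n_perm = 500, seed = 2)
  expect_lt(res_cl$in_run_p, 0.05)
  expect_lt(res_cl$isolated_p, 0.05)
})

test_that("score tables and the browser track round-trip through their writers", {
  w <- data.frame(chrom = "chr1", start = c(100, 5000), end = c(4000, 9000),
                  n_genes = c(2L, 3L), gene_ids = c("a,b", "c,d,e"),
                  first = c(1L, 3L), ANC = c(0.9, 0.2), SS = c(0.77, 0.5),
                  p = c(0.001, 0.4), TNS = c(0.69, 0))
  f <- tempfile()
  write_neighborhood_tsv(w, f, provenance = c(tool = "test"))
  back <- read_neighborhood_tsv(f)
  expect_equal(back$start, w$start)
  expect_equal(back$TNS, w$TNS)
  # write -> read -> write is byte-identical
  f2 <- tempfile()
  write_neighborhood_tsv(back, f2, provenance = c(tool = "test"))
  expect_identical(readLines(f), readLines(f2))

  ft <- tempfile()
  write_ucsc_track(w, ft)
  lines <- readLines(ft)
  expect_match(lines[1], "^track")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(fields[5]), 690)      # TNS 0.69 -> BED score 690
  expect_equal(fields[9], "204,0,0")            # red band

  # empty result: valid header-only files
  fe <- tempfile()
  write_neighborhood_tsv(w[0, ], fe)
  expect_equal(nrow(read_neighborhood_tsv(fe)), 0)
  fb <- tempfile()
  write_best_tns(data.frame(gene_id = character(0), best_tns = numeric(0)), fb)
  expect_equal(nrow(read_best_tns(fb)), 0)
})
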