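make_islands <- function(chrom, start, end, height) {
  island_set(data.frame(chrom = chrom, start = start, end = end,
                        height = height))
}
empty_islands <- island_set(data.frame(chrom = character(0), start = numeric(0),
                                       end = numeric(0), height = numeric(0)))

test_that("region_mass is height x clipped width, equal to the per-base oracle", {
  reg <- function(s, e) data.frame(chrom = "c", start = s, end = e)
  isl <- make_islands("c", 100, 200, 3)
  expect_equal(region_mass(empty_islands, reg(0, 1000)), 0)
  expect_equal(region_mass(isl, reg(0, 1000)), 300)
  expect_equal(region_mass(isl, reg(150, 300)), 150)
  expect_equal(region_mass(isl, reg(150, 300)),
               bf_region_mass(isl, "c", 150, 300))

  # >= 100 random fixtures against the per-base oracle
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    s <- sort(sample(seq(0, 9000, 50), n))
    w <- pmin(sample(50:800, n, TRUE), c(diff(s), 1e4))
    isl <- make_islands("c", s, s + w, sample(1:20, n, TRUE))
    for (q in 1:10) {
      bounds <- sort(sample.int(10000, 2))
      if (bounds[1] == bounds[2]) bounds[2] <- bounds[2] + 1
      expect_equal(region_mass(isl, reg(bounds[1], bounds[2])),
                   bf_region_mass(isl, "c", bounds[1], bounds[2]))
    }
    # additivity over a partition of the region
    cut <- sample(seq(bounds[1] + 1, bounds[2]), 1)
    expect_equal(region_mass(isl, reg(bounds[1], bounds[2])),
                 region_mass(isl, reg(bounds[1], cut)) +
                   region_mass(isl, reg(cut, bounds[2])))
  }
  expect_error(make_islands("c", c(0, 50), c(100, 150), 1), "non-overlapping")
})

test_that("cadr and csdr apply the symmetric pseudomass", {
  reg <- data.frame(chrom = "c", start = 0, end = 1000)
  a <- make_islands("c", 0, 1000, 5)
  # equal masses on both sides -> 1
  expect_equal(cadr(reg, a, empty_islands, a, empty_islands), 1)
  # no mass anywhere -> eps/eps = 1
  expect_equal(cadr(reg, empty_islands, empty_islands, empty_islands,
                    empty_islands), 1)
  expect_equal(csdr(reg, empty_islands, empty_islands), 1)
  # masses 1000 vs 10 with eps = 1 -> 1001/11
  num <- make_islands("c", 0, 1000, 1)
  den <- make_islands("c", 0, 10, 1)
  expect_equal(csdr(reg, num, den, eps = 1), 1001 / 11)
  # ratio inversion with eps = 0 and nonzero masses
  expect_equal(csdr(reg, num, den, eps = 0) * csdr(reg, den, num, eps = 0), 1)
})

test_that("domain_score is the log2 difference of shifted ratios", {
  expect_equal(domain_score(1, 1), 0)
  expect_equal(domain_score(3, 0), 2)
  expect_equal(domain_score(0, 3), -2)
  expect_equal(domain_score(7, 7), 0)
  set.seed(52)
  x <- runif(50, 0, 100); y <- runif(50, 0, 100)
  expect_equal(domain_score(x, y), -domain_score(y, x))
  expect_error(domain_score(-1, 0))
})

test_that("gene and neighborhood scores agree with constructed masses", {
  ann <- order_genes(make_ann(c(1000, 6000, 20000), c(3000, 9000, 22000)))
  bundle <- list(
    mam_k4 = make_islands("chr1", 1000, 3000, 10),   # over gene 1
    mam_k36 = empty_islands,
    mam_k27 = make_islands("chr1", 5000, 10000, 8),  # over gene 2
    liv_k4 = empty_islands, liv_k36 = empty_islands, liv_k27 = empty_islands)
  tab <- gene_chromatin_table(ann, bundle)
  # gene 1: active mass 2000 * 10 in mammary only
  expect_equal(tab$cadr[1], (20000 + 1) / 1)
  expect_equal(tab$ds[1], log2(20002) - 1)
  expect_gt(tab$ds[1], 0)
  # gene 2: fully under a mammary-only silencing block -> DS < 0
  expect_equal(tab$csdr[2], (3000 * 8 + 1) / 1)
  expect_lt(tab$ds[2], 0)
  # gene 3: no islands anywhere -> CADR = CSDR = 1, DS = 0
  expect_equal(tab$cadr[3], 1)
  expect_equal(tab$csdr[3], 1)
  expect_equal(tab$ds[3], 0)

  # neighborhood over a single gene's interval equals the gene's scores
  win <- data.frame(chrom = "chr1", start = 1000, end = 3000)
  nr <- neighborhood_ratios(win, bundle)
  expect_equal(nr$NCADR, tab$cadr[1])
  expect_equal(nr$NCSDR, tab$csdr[1])
  # empty marks -> (1, 1)
  empty_bundle <- setNames(rep(list(empty_islands), 6), names(bundle))
  nr0 <- neighborhood_ratios(win, empty_bundle)
  expect_equal(c(nr0$NCADR, nr0$NCSDR, nr0$NDS), c(1, 1, 0))

  # mirrored tissues invert the ratio when eps = 0
  mirror <- bundle[c("liv_k4", "liv_k36", "liv_k27",
                     "mam_k4", "mam_k36", "mam_k27")]
  names(mirror) <- names(bundle)
  tab_m <- gene_chromatin_table(ann, mirror, eps = 0)
  tab_0 <- gene_chromatin_table(ann, bundle, eps = 0)
  expect_equal(tab_m$cadr[1], 1 / tab_0$cadr[1])
})

test_that("per-gene table equals the per-base oracle on a random toy genome", {
  set.seed(53)
  starts <- c(500, 3000, 7000)
  ann <- order_genes(make_ann(starts, starts + c(1500, 2500, 2000)))
  rand_set <- function() {
    s <- sort(sample(seq(0, 9000, 250), 4))
    make_islands("chr1", s, s + pmin(sample(100:1500, 4, TRUE), c(diff(s), 1e4)),
                 sample(1:30, 4, TRUE))
  }
  bundle <- list(mam_k4 = rand_set(), mam_k36 = rand_set(),
                 mam_k27 = rand_set(), liv_k4 = rand_set(),
                 liv_k36 = rand_set(), liv_k27 = rand_set())
  tab <- gene_chromatin_table(ann, bundle, eps = 1)
  for (i in 1:3) {
    mm <- bf_region_mass(list(bundle$mam_k4, bundle$mam_k36), "chr1",
                         ann$start[i], ann$end[i])
    ml <- bf_region_mass(list(bundle$liv_k4, bundle$liv_k36), "chr1",
                         ann$start[i], ann$end[i])
    sm <- bf_region_mass(bundle$mam_k27, "chr1", ann$start[i], ann$end[i])
    sl <- bf_region_mass(bundle$liv_k27, "chr1", ann$start[i], ann$end[i])
    expect_equal(tab$cadr[i], (mm + 1) / (ml + 1))
    expect_equal(tab$csdr[i], (sm + 1) / (sl + 1))
    expect_equal(tab$ds[i], log2(tab$cadr[i] + 1) - log2(tab$csdr[i] + 1))
  }
})

test_that("classify_gene applies the threshold quadrants", {
  expect_equal(as.character(classify_gene(9, 0)), "uniquely_active")
  expect_equal(as.character(classify_gene(0, 9)), "uniquely_silenced")
  expect_equal(as.character(classify_gene(0, 0)), "shared")
  expect_equal(as.character(classify_gene(9, 9)), "inconsistent")
  expect_equal(as.character(classify_gene(8, 8)), "shared")  # strict >
})

test_that("classify_pair covers the full rule table and is symmetric", {
  # all 9 state combinations, enumerated against the rule table
  states <- c(active = 3, neutral = 0, silent = -3)
  oracle <- function(a, b) {
    if (a == "active" && b == "active") return("active")
    if (a == "silent" && b == "silent") return("silent")
    if (sort(c(a, b))[1] == "active" && sort(c(a, b))[2] == "silent") {
      return("discordant")
    }
    "concordant"
  }
  for (a in names(states)) for (b in names(states)) {
    expect_equal(as.character(classify_pair(states[[a]], states[[b]])),
                 oracle(a, b),
                 info = paste(a, b))
    expect_equal(classify_pair(states[[a]], states[[b]]),
                 classify_pair(states[[b]], states[[a]]))
  }
  expect_equal(as.character(classify_pair(0, 3)), "concordant")
  expect_equal(as.character(classify_pair(2, 2)), "concordant")  # strict >
})

test_that("ds_summary and the active-gene partition bucket correctly", {
  expect_equal(ds_summary(rep(0, 10))$frac_within_band, 1)
  expect_error(ds_summary(numeric(0)), "no domain scores")
  s <- ds_summary(c(-5, -1, 0, 1, 5))
  expect_equal(s$min, -5); expect_equal(s$max, 5)
  expect_equal(s$frac_within_band, 3 / 5)

  part <- active_gene_partition(best_tns = rep(0, 5), ds = rep(3, 5))
  expect_equal(unname(part["not_in_neighborhoods"]), 5L)
  # boundary values at exactly tns_lo / tns_hi fall in the boundary bucket
  part2 <- active_gene_partition(c(0.01, 0.4, 0.2, 0.5, 0.001),
                                 ds = rep(3, 5))
  expect_equal(unname(part2["boundary"]), 2L)
  expect_equal(unname(part2["indeterminate"]), 1L)
  expect_equal(unname(part2["in_neighborhoods"]), 1L)
  expect_equal(unname(part2["not_in_neighborhoods"]), 1L)

  # random fixture vs a brute-force bucketer
  set.seed(54)
  tns_v <- round(runif(300), 2)
  ds_v <- runif(300, -6, 6)
  part3 <- active_gene_partition(tns_v, ds_v)
  act <- ds_v >= 2
  expect_equal(unname(part3["n_active"]), sum(act))
  expect_equal(unname(part3["in_neighborhoods"]), sum(tns_v[act] > 0.4))
  expect_equal(unname(part3["not_in_neighborhoods"]), sum(tns_v[act] < 0.01))
  expect_equal(sum(part3[1:4]), sum(act))
})

test_that("island files round-trip through the BED reader", {
  isl <- make_islands("chr2", c(0, 500), c(300, 900), c(2.5, 7))
  f <- tempfile()
  write_islands(isl, f)
  back <- read_islands(f, mark = "H3K27me3", tissue = "mammary")
  expect_equal(back$start, isl$start)
  expect_equal(back$height, isl$height)
  expect_equal(attr(back, "mark"), "H3K27me3")
})
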