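test_that("coverage files round-trip and malformed lines are reported", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t100\t50.000000\t1\t1",
               "chr1\t250\t250\t100.000000\t2\t0",
               "chr2\t10\t10\t0.000000\t0\t3"), f)
  cell <- read_coverage(f, cell_id = "c1")
  expect_equal(cell$n_cpgs_covered, 3L)
  expect_equal(cell$sites$pos, c(100L, 250L, 10L))
  expect_equal(sum(cell$sites$meth), 3L)
  expect_equal(sum(cell$sites$unmeth), 4L)

  f2 <- withr::local_tempfile(fileext = ".cov")
  write_coverage(cell, f2)
  expect_equal(read_coverage(f2, cell_id = "c1")$sites, cell$sites)

  writeLines(character(), f)
  expect_equal(read_coverage(f)$n_cpgs_covered, 0L)

  writeLines(c("chr1\t100\t100\t50.0\t1\t1", "chr1\t200\t50.0\t1\t1"), f)
  expect_error(read_coverage(f), "line 2")
})

test_that("BED regions convert to 1-based inclusive on read and back", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tr1\tCGI\t0", "chrX\t0\t50\tr2\tCGI\t1"), f)
  rs <- read_regions_bed(f)
  expect_equal(rs$start, c(100L, 1L))
  expect_equal(rs$end, c(200L, 50L))
  expect_equal(rs$x_chrom, c(FALSE, TRUE))
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(rs, f2)
  expect_equal(read_regions_bed(f2), rs)
})

test_that("tiling groups exactly 100 CpGs, drops the remainder, conserves sites", {
  map <- list(chr1 = as.integer(sort(sample.int(1e6, 250))))
  ts <- build_tiles(map)
  expect_equal(nrow(ts$tiles), 2L)
  expect_equal(ts$tiles$start, map$chr1[c(1, 101)])
  expect_equal(ts$tiles$end, map$chr1[c(100, 200)])

  expect_equal(nrow(build_tiles(list(chr1 = as.integer(1:99 * 7)))$tiles), 0L)
  one <- build_tiles(list(chr1 = as.integer(seq(10, 1000, length.out = 100))))
  expect_equal(one$tiles$start, 10L)
  expect_equal(one$tiles$end, 1000L)
  expect_error(build_tiles(list(chr1 = c(5L, 3L))), "not strictly increasing")

  # every CpG belongs to at most one tile; tile CpG totals are 100 x tiles
  counts <- table(oomics:::assign_tiles(ts, rep("chr1", 250), map$chr1))
  expect_equal(length(counts), 2L)
  expect_equal(unname(as.integer(counts)), c(100L, 100L))
})

test_that("tile quantification pools calls and respects the minimum-call rule", {
  ts <- toy_tileset(3)
  cell <- toy_tile_methylome(ts, meth = c(15L, 20L, 3L), unmeth = c(15L, 9L, 2L))
  q30 <- quantify_tiles(ts, cell, min_calls = 30)
  expect_equal(q30$pct, c(50, NA, NA))  # 29 calls miss the 30-call rule
  q5 <- quantify_tiles(ts, cell, min_calls = 5)
  expect_equal(q5$pct, c(50, 100 * 20 / 29, 60))
})

test_that("tile and region quantification match brute-force per-site summation", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 400L
    map <- list(chr1 = as.integer(sort(sample.int(50000, n))))
    ts <- build_tiles(map)
    covered <- sort(sample(map$chr1, 250))
    sites <- data.frame(chrom = "chr1", pos = covered,
                        meth = rbinom(250, 3, 0.4), unmeth = rbinom(250, 2, 0.5))
    sites <- sites[sites$meth + sites$unmeth > 0, ]
    cell <- cell_methylome("c", sites)
    q <- quantify_tiles(ts, cell, min_calls = 1)
    for (i in seq_len(nrow(ts$tiles))) {
      inside <- sites$pos >= ts$tiles$start[i] & sites$pos <= ts$tiles$end[i]
      expect_equal(q$meth[i], sum(sites$meth[inside]))
      expect_equal(q$calls[i], sum(sites$meth[inside] + sites$unmeth[inside]))
    }
    rs <- region_set("chr1", c(1L, 20000L), c(19999L, 50000L),
                     c("r1", "r2"), c("CGI", "gDMR"))
    qr <- quantify_regions(rs, cell, min_calls = 1)
    for (i in 1:2) {
      inside <- sites$pos >= rs$start[i] & sites$pos <= rs$end[i]
      expect_equal(qr$meth[i], sum(sites$meth[inside]))
      expect_equal(qr$calls[i], sum(sites$meth[inside] + sites$unmeth[inside]))
    }
  }
})

test_that("region quantification applies the 20-call floor and handles empty regions", {
  ts <- toy_tileset(2)
  cell <- toy_tile_methylome(ts, meth = c(10L, 9L), unmeth = c(10L, 10L))
  rs <- region_set("chr1", c(ts$tiles$start[1], ts$tiles$start[2], 90000L),
                   c(ts$tiles$end[1], ts$tiles$end[2], 95000L),
                   c("a", "b", "empty"), rep("gDMR", 3))
  q <- quantify_regions(rs, cell, min_calls = 20)
  expect_equal(q$pct, c(50, NA, NA))  # 19 calls and 0 calls are missing
  expect_equal(q$calls, c(20, 19, 0))
})

test_that("pseudo-bulk sums per-site counts across cells", {
  s1 <- data.frame(chrom = "chr1", pos = c(10L, 20L), meth = c(1L, 0L),
                   unmeth = c(0L, 1L))
  s2 <- data.frame(chrom = "chr1", pos = c(10L, 30L), meth = c(0L, 2L),
                   unmeth = c(1L, 0L))
  cells <- list(cell_methylome("a", s1, group = "WT"),
                cell_methylome("b", s2, group = "WT"))
  pb <- pseudobulk(cells, "WT")
  expect_equal(pb$sites$pos, c(10L, 20L, 30L))
  expect_equal(pb$sites$meth, c(1L, 0L, 2L))
  expect_equal(pb$sites$unmeth, c(1L, 1L, 0L))
  expect_equal(pseudobulk(cells[1])$sites, s1)
  expect_error(pseudobulk(cells, "KO"), "no cells")

  # 10-cell fixture: totals equal column sums
  set.seed(3)
  many <- lapply(1:10, function(i) {
    cell_methylome(paste0("c", i),
                   data.frame(chrom = "chr1", pos = c(5L, 15L),
                              meth = rbinom(2, 2, 0.5) + 1L, unmeth = rbinom(2, 2, 0.5)),
                   group = "G")
  })
  pb10 <- pseudobulk(many, "G")
  expect_equal(sum(pb10$sites$meth), sum(vapply(many, function(c) sum(c$sites$meth), 0L)))
  expect_equal(sum(pb10$sites$unmeth), sum(vapply(many, function(c) sum(c$sites$unmeth), 0L)))
})

test_that("domain segmentation merges closed-interval runs broken by mid tiles", {
  ts <- toy_tileset(4)
  q <- quantify_tiles(ts, toy_tile_methylome(ts, meth = c(1L, 2L, 8L, 9L),
                                             unmeth = c(9L, 8L, 2L, 1L)),
                      min_calls = 5)
  dom <- segment_domains(q)
  expect_equal(dom$class, c("hypo_domain", "hyper_domain"))
  expect_equal(dom$start, ts$tiles$start[c(1, 3)])
  expect_equal(dom$end, ts$tiles$end[c(2, 4)])

  ts3 <- toy_tileset(3)
  q3 <- quantify_tiles(ts3, toy_tile_methylome(ts3, meth = c(1L, 5L, 1L),
                                               unmeth = c(9L, 5L, 9L)), min_calls = 5)
  expect_equal(segment_domains(q3)$class, c("hypo_domain", "hypo_domain"))

  # exactly 25% belongs to the hypomethylated band (closed interval)
  q25 <- quantify_tiles(ts3, toy_tile_methylome(ts3, meth = c(5L, 5L, 15L),
                                                unmeth = c(15L, 15L, 5L)), min_calls = 5)
  expect_equal(segment_domains(q25)$class, c("hypo_domain", "hyper_domain"))
})

test_that("2x2 chi-square equals the closed form and df-1 tail probabilities", {
  expect_equal(chi_square_2x2(10, 10, 10, 10), list(chi2 = 0, p = 1))
  r <- chi_square_2x2(30, 10, 10, 30)
  expect_equal(r$chi2, 20)
  expect_equal(r$p, 7.7e-6, tolerance = 1e-2)
  expect_error(chi_square_2x2(0, 0, 1, 2), "degenerate margin")
  expect_error(chi_square_2x2(-1, 1, 1, 1), "non-negative")

  set.seed(21)
  for (i in 1:1000) {
    tab <- rpois(4, 20) + 1
    r <- chi_square_2x2(tab[1], tab[2], tab[3], tab[4])
    n <- sum(tab)
    closed <- n * (tab[1] * tab[4] - tab[2] * tab[3])^2 /
      ((tab[1] + tab[2]) * (tab[3] + tab[4]) * (tab[1] + tab[3]) * (tab[2] + tab[4]))
    expect_equal(r$chi2, closed)
  }
  # spot check against the standard library implementation, no correction
  ct <- suppressWarnings(chisq.test(matrix(c(12, 5, 7, 19), 2), correct = FALSE))
  r2 <- chi_square_2x2(12, 7, 5, 19)
  expect_equal(r2$chi2, unname(ct$statistic))
  expect_equal(r2$p, ct$p.value)
})

test_that("DMR calling enforces strict 25-point and adjusted-p cut-offs", {
  ts <- toy_tileset(3)
  a <- toy_tile_methylome(ts, meth = c(900L, 50L, 500L), unmeth = c(100L, 50L, 500L), group = "A")
  b <- toy_tile_methylome(ts, meth = c(500L, 50L, 250L), unmeth = c(500L, 50L, 750L), group = "B")
  res <- call_dmrs(ts, a, b)
  expect_equal(res$significant, c(TRUE, FALSE, FALSE))  # 40 pp, 0 pp, 25.0 pp exactly
  expect_equal(res$delta, c(-40, 0, -25))
  expect_true(res$chi2[1] > 300)
  expect_equal(res$q, p.adjust(res$p, "BH"))

  # minimum calls per group excludes tiles before testing
  a2 <- toy_tile_methylome(ts, meth = c(10L, 900L, 500L), unmeth = c(10L, 100L, 500L))
  res2 <- call_dmrs(ts, a2, b, min_calls = 30)
  expect_false("chr1:10-1000" %in% res2$tile_id)

  # domain filter restricts the tested family
  dom <- region_set("chr1", ts$tiles$start[1], ts$tiles$end[1], "d1", "hyper_domain")
  res3 <- call_dmrs(ts, a, b, domain_filter = dom)
  expect_equal(nrow(res3), 1L)
  expect_equal(res3$tile_id, ts$tiles$tile_id[1])
})

test_that("gDMR testing applies the calls-per-kb coverage filter", {
  ts <- toy_tileset(2)  # tiles are ~1 kb each (100 CpGs spaced 10 bp)
  gd <- region_set("chr1", ts$tiles$start, ts$tiles$end, c("g1", "g2"),
                   c("gDMR", "gDMR"))
  # g1 densely covered (~200 calls/kb), g2 sparsely (~60 calls/kb)
  a <- toy_tile_methylome(ts, meth = c(180L, 54L), unmeth = c(20L, 6L))
  b <- toy_tile_methylome(ts, meth = c(100L, 30L), unmeth = c(100L, 30L))
  res <- test_gdmrs(gd, a, b, min_density = 100)
  expect_equal(res$delta, c(-40, -40))
  expect_true(res$coverage_pass[1])
  expect_false(res$coverage_pass[2])
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  # either-group mode relaxes the filter only where one group is dense
  res_e <- test_gdmrs(gd, a, b, min_density = 150, density_mode = "either")
  expect_equal(res_e$coverage_pass, c(TRUE, FALSE))
})

test_that("40-point tile effects at 200 pooled calls are detected with high sensitivity", {
  set.seed(77)
  ts <- toy_tileset(200)
  n_effect <- 100L
  p_a <- c(rep(0.9, n_effect), rep(0.5, 100))
  p_b <- c(rep(0.5, n_effect), rep(0.5, 100))
  meth_a <- rbinom(200, 100, p_a); meth_b <- rbinom(200, 100, p_b)
  a <- toy_tile_methylome(ts, meth = meth_a, unmeth = 100L - meth_a, group = "A")
  b <- toy_tile_methylome(ts, meth = meth_b, unmeth = 100L - meth_b, group = "B")
  res <- call_dmrs(ts, a, b, min_calls = 30)
  sens <- mean(res$significant[seq_len(n_effect)])
  expect_gte(sens, 0.95)
  expect_equal(sum(res$significant[(n_effect + 1):200]), 0L)
})

test_that("hypermethylated CGI filter keeps islands above 75% in either group", {
  expect_equal(filter_hyper_cgis(c("a", "b", "c"), c(80, 70, 75), c(10, 70, 10)),
               "a")  # 75.0 is dropped, strict
  expect_equal(filter_hyper_cgis(c("a", "b"), c(10, NA), c(80, 90)), c("a", "b"))
})

test_that("read-count filter boundary is inclusive at the threshold", {
  mk <- function(n) {
    cell_methylome("c", data.frame(chrom = "chr1", pos = seq_len(max(n, 1)),
                                   meth = 1L, unmeth = 0L)[seq_len(n), , drop = FALSE])
  }
  expect_true(qc_read_filter(mk(600), min_cpgs = 600))
  expect_false(qc_read_filter(mk(599), min_cpgs = 600))
  expect_false(qc_read_filter(mk(0), min_cpgs = 600))
})

test_that("X-CGI criterion pools calls and treats 10% as passing (strict >)", {
  ts <- toy_tileset(1, chrom = "chrX")
  rs <- region_set("chrX", ts$tiles$start, ts$tiles$end, "xcgi", "CGI")
  ok <- toy_tile_methylome(ts, meth = 2L, unmeth = 96L)
  expect_equal(qc_x_cgi(ok, rs)$status, "pass")
  expect_equal(qc_x_cgi(ok, rs)$pct, 100 * 2 / 98)
  flagged <- toy_tile_methylome(ts, meth = 20L, unmeth = 80L)
  expect_equal(qc_x_cgi(flagged, rs)$status, "fail")
  boundary <- toy_tile_methylome(ts, meth = 10L, unmeth = 90L)
  expect_equal(qc_x_cgi(boundary, rs)$status, "pass")
  empty <- cell_methylome("e", data.frame(chrom = "chr1", pos = 1L,
                                          meth = 1L, unmeth = 0L))
  expect_equal(qc_x_cgi(empty, rs)$status, "untestable")
})

test_that("context criterion applies the three strict bounds", {
  mk <- function(cg, chg, chh) {
    cell_methylome("c", data.frame(chrom = "chr1", pos = 1L, meth = 1L, unmeth = 0L),
                   context = c(mCpG = cg, mCHG = chg, mCHH = chh))
  }
  expect_equal(qc_context(mk(38, 5, 6))$status, "pass")
  expect_equal(qc_context(mk(45, 5, 6))$status, "fail")
  expect_equal(qc_context(mk(38, 5, 3.9))$status, "fail")
  expect_equal(qc_context(mk(40, 5, 6))$status, "fail")  # boundary is strict
  no_ctx <- cell_methylome("c", data.frame(chrom = "chr1", pos = 1L,
                                           meth = 1L, unmeth = 0L))
  expect_equal(qc_context(no_ctx)$status, "untestable")
})

test_that("bimodality criterion separates bimodal from mid-heavy histograms", {
  ts <- toy_tileset(60)
  half <- rep(c(0L, 10L), each = 30)
  bimodal <- toy_tile_methylome(ts, meth = half, unmeth = rev(half))
  r <- qc_bimodality(bimodal, ts)
  expect_equal(r$status, "pass")
  expect_equal(r$mid, 0)
  flat <- toy_tile_methylome(ts, meth = rep(5L, 60), unmeth = rep(5L, 60))
  expect_equal(qc_bimodality(flat, ts)$status, "fail")
  few <- toy_tile_methylome(toy_tileset(10), meth = rep(5L, 10), unmeth = rep(5L, 10))
  expect_equal(qc_bimodality(few, toy_tileset(10))$status, "untestable")
})

test_that("global methylation averages informative tiles and compares groups", {
  ts <- toy_tileset(2)
  c1 <- toy_tile_methylome(ts, meth = c(0L, 10L), unmeth = c(10L, 0L),
                           cell_id = "c1", group = "A")
  expect_equal(global_methylation(list(c1, c1, c1, c1), ts,
                                  groups = c("A", "A"))$median_difference, 0)
  cells <- list(c1,
                toy_tile_methylome(ts, meth = c(0L, 10L), unmeth = c(10L, 0L),
                                   cell_id = "c2", group = "A"),
                toy_tile_methylome(ts, meth = c(2L, 10L), unmeth = c(8L, 0L),
                                   cell_id = "c3", group = "B"),
                toy_tile_methylome(ts, meth = c(2L, 10L), unmeth = c(8L, 0L),
                                   cell_id = "c4", group = "B"))
  gm <- global_methylation(cells, ts, groups = c("A", "B"))
  expect_equal(gm$per_cell$mean_pct[1], 50)
  expect_equal(gm$median_difference, 10)
})
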