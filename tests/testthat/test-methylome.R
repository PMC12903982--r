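# Window methylation, the exact window test, DMR/AMR/DML calling and
# metagene profiles.

test_that("tile_windows tiles chromosomes and keeps the terminal partial window", {
  w <- tile_windows(tiny_layout(c(c1 = 2500)), 1000)
  expect_equal(w$start, c(0, 1000, 2000))
  expect_equal(w$end, c(1000, 2000, 2500))

  w2 <- tile_windows(tiny_layout(c(c1 = 1000)), 100)
  expect_equal(nrow(w2), 10)
  expect_equal(sum(w2$end - w2$start), 1000)

  w3 <- tile_windows(tiny_layout(c(c1 = 2000)), 1000, step = 500)
  expect_equal(w3$start, c(0, 500, 1000, 1500))

  expect_error(tile_windows(tiny_layout(), 0), "size")
})

test_that("non-overlapping tiling is a partition of the genome", {
  layout <- tiny_layout(c(a = 12345, b = 777))
  for (size in c(100, 1000, 5000)) {
    w <- tile_windows(layout, size)
    expect_true(all(w$start < w$end))
    for (ch in layout$chrom) {
      x <- w[w$chrom == ch, ]
      expect_equal(x$start[-1], x$end[-nrow(x)])   # adjacent, disjoint
      expect_equal(min(x$start), 0)
      expect_equal(max(x$end), chrom_length <- layout$length[layout$chrom == ch])
    }
  }
})

test_that("pool_window_methylation pools counts across sites, strands and replicates", {
  windows <- tile_windows(tiny_layout(c(c1 = 2000)), 1000)
  calls <- data.frame(chrom = "c1", pos = c(100, 800), strand = c("+", "-"),
                      meth = c(3, 27), unmeth = c(7, 63), context = "CG",
                      tri = "NNN", stringsAsFactors = FALSE)
  pooled <- pool_window_methylation(calls, windows, "CG")
  expect_equal(pooled$meth[1], 30)
  expect_equal(pooled$total[1], 100)
  expect_equal(pooled$freqC[1], 0.30)
  expect_true(pooled$no_data[2])
  expect_true(is.na(pooled$freqC[2]))

  # replicate order invariance
  r1 <- calls[1, , drop = FALSE]
  r2 <- calls[2, , drop = FALSE]
  expect_equal(pool_window_methylation(list(r1, r2), windows, "CG"),
               pool_window_methylation(list(r2, r1), windows, "CG"))
  expect_error(pool_window_methylation(calls, windows, "XX"),
               "unknown context")
})

test_that("fisher_window_test reproduces hand-enumerated two-sided probabilities", {
  # all tables with margins (3,3 | 3,3): observed and mirror each 1/20
  expect_equal(fisher_window_test(3, 3, 0, 3), 0.10, tolerance = 1e-12)
  expect_equal(fisher_window_test(5, 10, 5, 10), 1.0)
  expect_equal(fisher_window_test(8, 10, 2, 10),
               fisher_oracle(8, 10, 2, 10), tolerance = 1e-12)
  expect_lt(fisher_window_test(8, 10, 2, 10), 0.05)
  expect_error(fisher_window_test(0, 0, 0, 0), "zero")
})

test_that("fisher_window_test equals enumeration and fisher.test on random tables", {
  set.seed(42)
  n <- 300
  totalA <- sample(1:200, n, replace = TRUE)
  totalB <- sample(1:200, n, replace = TRUE)
  methA <- vapply(totalA, function(t) sample(0:t, 1), numeric(1))
  methB <- vapply(totalB, function(t) sample(0:t, 1), numeric(1))
  mine <- fisher_window_test(methA, totalA, methB, totalB)
  oracle <- vapply(seq_len(n), function(i) {
    fisher_oracle(methA[i], totalA[i], methB[i], totalB[i])
  }, numeric(1))
  expect_equal(mine, oracle, tolerance = 1e-12)
  # independent cross-check against the reference implementation
  ref <- vapply(seq_len(n), function(i) {
    stats::fisher.test(matrix(c(methA[i], totalA[i] - methA[i],
                                methB[i], totalB[i] - methB[i]), 2))$p.value
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("call_dmrs applies the per-context effect-size and q thresholds", {
  # window 1: CG delta 0.19 (hugely significant): fails the >= 20% rule
  # window 2: delta 0.5: passes
  wA <- make_windows("c1", c(0, 1000), c(1000, 2000),
                     meth = c(500, 100), total = c(1000, 1000))
  wB <- make_windows("c1", c(0, 1000), c(1000, 2000),
                     meth = c(690, 600), total = c(1000, 1000))
  d <- call_dmrs(wA, wB, "CG")
  expect_equal(d$delta, c(0.19, 0.5))
  expect_lt(d$q[1], 0.001)
  expect_equal(d$dmr, c(FALSE, TRUE))
  expect_equal(d$direction, c("hyper-in-B", "hyper-in-B"))

  # CHH: delta 0.12 with q < 0.01 is a DMR (>= 10% rule)
  wA2 <- make_windows("c1", 0, 1000, meth = 100, total = 1000,
                      context = "CHH")
  wB2 <- make_windows("c1", 0, 1000, meth = 220, total = 1000,
                      context = "CHH")
  d2 <- call_dmrs(wA2, wB2, "CHH")
  expect_equal(d2$delta, 0.12)
  expect_lt(d2$q, 0.01)
  expect_true(d2$dmr)
  # the same window is not a CHG DMR (>= 15% rule)
  wA2$context <- wB2$context <- "CHG"
  expect_false(call_dmrs(wA2, wB2, "CHG")$dmr)

  # identical conditions: no DMRs; q >= p under BH
  d3 <- call_dmrs(wA, wA, "CG")
  expect_equal(sum(d3$dmr), 0)
  expect_true(all(d3$q >= d3$p))

  expect_error(call_dmrs(wA, wA2[, names(wA)], "CG"), "not identical")
})

test_that("no-data windows are excluded from testing and multiplicity", {
  wA <- make_windows("c1", c(0, 1000), c(1000, 2000),
                     meth = c(10, 0), total = c(50, 0))
  wB <- make_windows("c1", c(0, 1000), c(1000, 2000),
                     meth = c(40, 10), total = c(50, 50))
  d <- call_dmrs(wA, wB, "CG")
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 0)
})

test_that("call_amrs requires methylation above threshold and >=90% SV overlap", {
  del <- make_sv("sv1", "c1", 10000, 11000, "DEL")
  w <- make_windows("c1", c(10200, 10950, 10400), c(10300, 11050, 10500),
                    meth = c(55, 60, 15), total = c(100, 100, 100))
  amr <- call_amrs(w, del)
  # full containment + freqC 0.55 -> AMR; 50% overlap -> no; freqC 0.15 -> no
  expect_equal(nrow(amr), 1)
  expect_equal(amr$start, 10200)
  expect_equal(amr$sv_id, "sv1")
  expect_equal(amr$overlap, 1.0)

  inv <- make_sv("sv2", "c1", 10000, 11000, "INV")
  expect_error(call_amrs(w, inv), "inversions")

  # insertions reach windows only in carrier-frame mode
  ins <- make_sv("sv3", "c1", 10200, 10201, "INS", length = 700)
  expect_equal(nrow(call_amrs(w, ins)), 0)
  expect_equal(nrow(call_amrs(w, ins, expand_insertions = TRUE)), 1)
})

test_that("call_amrs is monotone in both thresholds and satisfies its invariants", {
  set.seed(5)
  layout <- tiny_layout(c(c1 = 50000))
  w <- tile_windows(layout, 100)
  w <- make_windows(w$chrom, w$start, w$end,
                    meth = rbinom(nrow(w), 100, runif(nrow(w))),
                    total = 100)
  svs <- make_sv(sprintf("d%d", 1:8), "c1",
                 seq(1000, 43000, by = 6000),
                 seq(1000, 43000, by = 6000) + sample(150:900, 8, TRUE),
                 "DEL")
  base <- call_amrs(w, svs, freqc_min = 0.2, overlap_min = 0.9)
  for (fc in c(0.3, 0.5)) {
    for (ov in c(0.95, 1)) {
      sub <- call_amrs(w, svs, freqc_min = fc, overlap_min = ov)
      expect_true(all(sub$start %in% base$start))
      expect_true(all(sub$freqC > fc))
      expect_true(all(sub$overlap >= ov))
    }
  }
  expect_true(all(base$freqC > 0.2))
  expect_true(all(base$overlap >= 0.9))
})

test_that("call_dmls matches sites by key and applies the 20%/q<0.05 rule", {
  mk <- function(mod, cov, pos = seq_along(mod), type = "m6A") {
    data.frame(transcript = "t1", position = pos, type = type,
               modified = mod, coverage = cov, fraction = mod / cov,
               stringsAsFactors = FALSE)
  }
  a <- mk(c(45, 22, 10), c(50, 40, 50))
  b <- mk(c(5, 16, 30), c(50, 40, 50))
  d <- call_dmls(a, b)
  expect_equal(d$delta, b$fraction - a$fraction)
  expect_true(d$dml[1])                    # 0.9 vs 0.1 at coverage 50/50
  expect_false(d$dml[2])                   # delta 0.15 < 0.20
  expect_equal(sum(call_dmls(a, a)$dml), 0)

  # unmatched keys are skipped and counted
  b2 <- b
  b2$position[3] <- 99
  d2 <- call_dmls(a, b2)
  expect_equal(nrow(d2), 2)
  expect_equal(attr(d2, "n_unmatched"), 2)
})

test_that("metagene_profile is flat under uniform methylation and strand-aware", {
  layout <- tiny_layout(c(c1 = 20000))
  calls <- data.frame(chrom = "c1", pos = seq(0, 19999, by = 20),
                      strand = "+", meth = 1, unmeth = 1, context = "CG",
                      tri = "NNN", stringsAsFactors = FALSE)
  feats <- data.frame(chrom = "c1", start = c(5000, 11000),
                      end = c(8000, 14000), strand = "+",
                      stringsAsFactors = FALSE)
  prof <- metagene_profile(calls, feats, flank = 1000, flank_bin = 100,
                           body_bins = 10)
  expect_equal(nrow(prof), 30)
  expect_true(all(abs(prof$level - 0.5) < 1e-9))
  expect_equal(as.character(unique(prof$zone)),
               c("upstream", "body", "downstream"))

  # a gradient reverses for a minus-strand feature
  calls$meth <- ifelse(calls$pos < 6500, 9, 1)
  calls$unmeth <- 10 - calls$meth
  plus <- metagene_profile(calls, feats[1, ], flank = 1000,
                           flank_bin = 100, body_bins = 10)
  feats$strand <- "-"
  minus <- metagene_profile(calls, feats[1, ], flank = 1000,
                            flank_bin = 100, body_bins = 10)
  expect_equal(minus$level, rev(plus$level))

  short <- data.frame(chrom = "c1", start = 100, end = 105, strand = "+")
  expect_warning(metagene_profile(calls, short, body_bins = 30), "skipped")
})

test_that("hand-placed sites yield hand-computed bin means", {
  # one feature [1000, 1200), 2 body bins of 100 bp, no informative flanks
  calls <- data.frame(chrom = "c1", pos = c(1010, 1050, 1150),
                      strand = "+", meth = c(2, 6, 5),
                      unmeth = c(8, 4, 5), context = "CG", tri = "NNN",
                      stringsAsFactors = FALSE)
  feat <- data.frame(chrom = "c1", start = 1000, end = 1200, strand = "+")
  prof <- metagene_profile(calls, feat, flank = 100, flank_bin = 100,
                           body_bins = 2)
  body <- prof[prof$zone == "body", ]
  expect_equal(body$level, c((2 + 6) / (10 + 10), 5 / 10))
})
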