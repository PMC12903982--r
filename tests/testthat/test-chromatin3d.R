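# Compartment assignment/switching, TAD comparison and SV co-occurrence
# statistics.

bins_frame <- function(values, chrom = "c1", bin = 40000) {
  n <- length(values)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin,
             end = seq_len(n) * bin, value = values,
             stringsAsFactors = FALSE)
}

test_that("assign_compartments orients PC1 by gene density and labels by sign", {
  pc1 <- bins_frame(c(1.2, 0.8, -0.5, -1.0, 0))
  gd <- c(10, 8, 1, 0, 3)
  comp <- assign_compartments(pc1, gd)
  expect_equal(comp$label, c("A", "A", "B", "B", NA))
  # global sign flips leave labels unchanged
  flipped <- pc1
  flipped$value <- -flipped$value
  expect_equal(assign_compartments(flipped, gd)$label, comp$label)
  # all-zero PC1: NA labels with a warning
  zero <- bins_frame(rep(0, 4))
  expect_warning(cz <- assign_compartments(zero, 1:4), "all-zero")
  expect_true(all(is.na(cz$label)))
})

test_that("switch segments need >= 2 consecutive changed bins", {
  gd <- c(9, 9, 9, 9)
  a <- assign_compartments(bins_frame(c(1, 1, 1, 1)), gd)
  b <- assign_compartments(bins_frame(c(1, -1, -1, 1)), gd)
  segs <- detect_switch_segments(a, b)
  sw <- segs[segs$class == "A2B", ]
  expect_equal(nrow(sw), 1)
  expect_equal(sw$start, 40000)
  expect_equal(sw$end, 120000)
  expect_equal(sw$n_bins, 2)

  # single-bin flip is not a switch
  b1 <- assign_compartments(bins_frame(c(1, -1, 1, 1)), gd)
  s1 <- detect_switch_segments(a, b1)
  expect_equal(sum(s1$class %in% c("A2B", "B2A")), 0)

  # identical tracks: no switches; segment classes partition the bins
  s2 <- detect_switch_segments(a, a)
  expect_equal(sum(s2$class %in% c("A2B", "B2A")), 0)
  expect_equal(sum(s2$n_bins), 4)
  expect_error(detect_switch_segments(a, a[1:3, ]), "not identical")
})

test_that("segment classes partition the labelled genome and never fall below 2 bins", {
  set.seed(31)
  for (rep_i in 1:5) {
    v1 <- rnorm(60)
    v2 <- ifelse(runif(60) < 0.3, -v1, v1)
    gd <- pmax(0, v1 * 3 + rnorm(60))
    a <- assign_compartments(bins_frame(v1), gd)
    b <- assign_compartments(bins_frame(v2), gd)
    segs <- detect_switch_segments(a, b)
    expect_true(all(segs$n_bins[segs$class %in% c("A2B", "B2A")] >= 2))
    ok <- !is.na(a$label) & !is.na(b$label)
    expect_equal(sum(segs$n_bins), sum(ok))
  }
})

test_that("match_tads classifies by boundary tolerance and is symmetric", {
  tA <- data.frame(chrom = "c1", start = c(0, 5e5), end = c(5e5, 1e6))
  # identical sets: all conserved
  mt <- match_tads(tA, tA)
  expect_true(all(mt$comparisons$label == "conserved"))
  expect_equal(nrow(mt$differential_regions), 0)

  # a domain split in the partner set is differential
  tB <- data.frame(chrom = "c1", start = c(0, 3e5, 5e5),
                   end = c(3e5, 5e5, 1e6))
  mt2 <- match_tads(tA, tB)
  lab <- mt2$comparisons
  expect_equal(lab$label[lab$condition == "A"], c("differential", "conserved"))
  expect_equal(lab$label[lab$condition == "B"],
               c("differential", "differential", "conserved"))

  # 10-kb boundary shift at 20-kb tolerance: conserved
  tC <- data.frame(chrom = "c1", start = c(10000, 51e4),
                   end = c(51e4, 1e6 + 10000))
  expect_true(all(match_tads(tA, tC)$comparisons$label == "conserved"))
  expect_true(all(match_tads(tA, tC, tolerance = 5000)$comparisons$label ==
                    "differential"))
})

test_that("match_tads conserved pairing is symmetric and labels exhaustive", {
  set.seed(8)
  rand_domains <- function() {
    bp <- sort(sample(seq(0, 2e6, by = 2e4), 25))
    bp <- unique(c(0, bp, 2e6))
    data.frame(chrom = "c1", start = bp[-length(bp)], end = bp[-1])
  }
  for (i in 1:5) {
    a <- rand_domains(); b <- rand_domains()
    ab <- match_tads(a, b); ba <- match_tads(b, a)
    expect_equal(ab$comparisons$label[ab$comparisons$condition == "A"],
                 ba$comparisons$label[ba$comparisons$condition == "B"])
    expect_equal(sum(ab$counts$conserved + ab$counts$differential),
                 nrow(a) + nrow(b))
  }
})

test_that("sv_counts_per_tad reports counts and a Welch test", {
  dom <- data.frame(chrom = "c1", start = c(0, 1e5, 2e5, 3e5),
                    end = c(1e5, 2e5, 3e5, 4e5),
                    label = c("conserved", "conserved", "differential",
                              "differential"))
  # one SV in each domain: equal counts, t = 0, p = 1
  svs <- make_sv(sprintf("s%d", 1:4), "c1", c(1, 1e5 + 1, 2e5 + 1, 3e5 + 1),
                 c(50, 1e5 + 50, 2e5 + 50, 3e5 + 50), "DEL")
  eq <- sv_counts_per_tad(svs, dom)
  expect_equal(eq$per_domain$n_sv, rep(1, 4))
  expect_equal(eq$test$p, 1)

  # hand-built groups match the closed-form Welch statistic
  dom8 <- data.frame(chrom = "c1", start = seq(0, 7e5, 1e5),
                     end = seq(1e5, 8e5, 1e5),
                     label = rep(c("conserved", "differential"), each = 4))
  counts <- c(1, 2, 1, 0, 5, 7, 6, 8)
  pos <- unlist(lapply(seq_len(8), function(i) {
    if (counts[i] > 0) dom8$start[i] + seq_len(counts[i]) * 10 else numeric(0)
  }))
  svs8 <- make_sv(sprintf("x%d", seq_along(pos)), "c1", pos, pos + 1, "INS",
                  length = 100)
  res <- sv_counts_per_tad(svs8, dom8)
  oracle <- welch_oracle(c(5, 7, 6, 8), c(1, 2, 1, 0))
  expect_equal(res$test$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$test$p, oracle$p, tolerance = 1e-12)
  expect_lt(res$test$p, 0.01)
})

test_that("planted SV enrichment in differential domains is detected", {
  set.seed(99)
  n_dom <- 60
  dom <- data.frame(chrom = "c1", start = (seq_len(n_dom) - 1) * 1e5,
                    end = seq_len(n_dom) * 1e5,
                    label = rep(c("conserved", "differential"), n_dom / 2))
  lambda <- ifelse(dom$label == "differential", 6, 2)   # 3x enrichment
  counts <- rpois(n_dom, lambda)
  pos <- unlist(lapply(seq_len(n_dom), function(i) {
    dom$start[i] + sample.int(99999, counts[i])
  }))
  svs <- make_sv(sprintf("e%d", seq_along(pos)), "c1", pos, pos + 1, "INS",
                 length = 50)
  res <- sv_counts_per_tad(svs, dom)
  expect_gt(res$test$mean_differential, res$test$mean_conserved)
  expect_lt(res$test$p, 0.01)
})

test_that("sv_density_profile peaks where the SVs are", {
  dom <- data.frame(chrom = "c1", start = c(1e5, 5e5), end = c(2e5, 6e5),
                    label = "differential")
  centers <- (dom$start + dom$end) / 2
  svs <- make_sv(c("a", "b"), "c1", centers, centers + 1, "INS", 10)
  prof <- sv_density_profile(svs, dom, body_bins = 10, flank_frac = 0.5)
  expect_equal(nrow(prof), 20)
  peak <- which(prof$differential == max(prof$differential))
  expect_true(all(peak %in% c(10, 11)))   # central body bins
  expect_true(all(prof$differential[prof$zone != "body"] == 0))
  expect_true(all(is.na(prof$conserved)))

  # two-domain toy with hand-placed SVs: counts land in the expected bins
  svs2 <- make_sv(c("a", "b", "c"), "c1",
                  c(1e5 + 5000, 1e5 + 95000, 5e5 + 5000),
                  c(1e5 + 5001, 1e5 + 95001, 5e5 + 5001), "INS", 10)
  prof2 <- sv_density_profile(svs2, dom, body_bins = 10, flank_frac = 0.5)
  # first body bin: one SV per domain -> mean 1 per bin, bin = 10 kb
  expect_equal(prof2$differential[6], mean(c(1, 1)) / 0.01)
  expect_equal(prof2$differential[15], mean(c(1, 0)) / 0.01)
})

test_that("fraction_svs_in_regions counts >=1 bp overlaps", {
  regions <- data.frame(chrom = "c1", start = c(0, 5000), end = c(1000, 6000))
  inside <- make_sv(sprintf("i%d", 1:3), "c1", c(10, 900, 5500),
                    c(20, 1100, 5600), "DEL")
  expect_equal(fraction_svs_in_regions(inside, regions), 1.0)
  outside <- make_sv(c("o1", "o2"), "c1", c(2000, 3000), c(2100, 3100),
                     "DEL")
  expect_equal(fraction_svs_in_regions(outside, regions), 0.0)
  mixed <- rbind(inside, outside,
                 make_sv(sprintf("m%d", 1:10), "c1",
                         seq(10000, 19000, by = 1000),
                         seq(10000, 19000, by = 1000) + 50, "DEL"))
  regions2 <- rbind(regions,
                    data.frame(chrom = "c1", start = 9000, end = 20000))
  expect_equal(fraction_svs_in_regions(mixed, regions2), 13 / 15)
  expect_error(fraction_svs_in_regions(inside[0, ], regions), "empty")
})

test_that("boundary_sv_window_stats averages per-window boundary proportions", {
  layout <- tiny_layout(c(c1 = 3e7))
  # one domain per 10-Mb window; boundaries at the domain edges
  dom <- data.frame(chrom = "c1",
                    start = c(1e6, 11e6, 21e6), end = c(2e6, 12e6, 22e6))
  # window 1: SVs at both edges (1.0); window 2: one edge (0.5);
  # window 3: none (0.0)
  svs <- make_sv(sprintf("b%d", 1:3), "c1",
                 c(1e6 - 100, 2e6 + 50, 11e6 - 100),
                 c(1e6 + 100, 2e6 + 150, 11e6 + 100), "DEL")
  st <- boundary_sv_window_stats(dom, svs, layout)
  expect_equal(nrow(st$per_window), 3)
  expect_equal(st$per_window$n_boundaries, c(2, 2, 2))
  expect_equal(st$per_window$proportion, c(1.0, 0.5, 0.0))
  expect_equal(st$mean_proportion, 0.5)

  # no SVs anywhere: mean 0
  st0 <- boundary_sv_window_stats(dom, svs[0, ], layout)
  expect_equal(st0$mean_proportion, 0.0)
  expect_error(boundary_sv_window_stats(dom, svs, layout, window = 0),
               "window")
})
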