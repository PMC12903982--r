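# Differential expression stand-in and RNA-modification summaries.

expr_pair <- function(tpmA, tpmB, reps = 3) {
  list(A = matrix(rep(tpmA, reps), ncol = reps,
                  dimnames = list(names(tpmA), NULL)),
       B = matrix(rep(tpmB, reps), ncol = reps,
                  dimnames = list(names(tpmA), NULL)))
}

test_that("compute_degs fold changes use the +1 pseudocount and mark not_expressed", {
  set.seed(2)
  tpmA <- c(g1 = 40, g2 = 10, g3 = 0)
  tpmB <- c(g1 = 40, g2 = 40, g3 = 0)
  e <- expr_pair(tpmA, tpmB)
  # add replicate noise so the t-test is defined
  eA <- e$A * 2^matrix(rnorm(9, 0, 0.05), 3)
  eB <- e$B * 2^matrix(rnorm(9, 0, 0.05), 3)
  eA["g3", ] <- 0; eB["g3", ] <- 0
  d <- compute_degs(eA, eB)
  expect_equal(d$log2FC[2], log2((mean(eB[2, ]) + 1) / (mean(eA[2, ]) + 1)))
  expect_equal(d$log2FC[2], 1.898, tolerance = 0.1)  # log2(41/11) idealised
  expect_equal(d$status[3], "not_expressed")
  expect_true(is.na(d$q[3]))
  expect_error(compute_degs(eA[, 1, drop = FALSE], eB), ">= 2 replicates")
})

test_that("identical conditions yield no up/down calls and log2FC is antisymmetric", {
  set.seed(3)
  tpm <- matrix(2^rnorm(60, 5, 2), 20)
  rownames(tpm) <- sprintf("g%d", 1:20)
  noise <- function() tpm * 2^matrix(rnorm(60, 0, 0.2), 20)
  a <- noise(); b <- noise()
  same <- compute_degs(a, a)
  expect_equal(sum(same$status %in% c("up", "down")), 0)
  ab <- compute_degs(a, b)
  ba <- compute_degs(b, a)
  expect_equal(ab$log2FC, -ba$log2FC)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("DEG percentages are truncated to two decimals as reported", {
  # 801 expressed genes in the region set, 78 of them DEGs
  genes <- make_gene(sprintf("g%d", 1:900), "c1",
                     (0:899) * 1000, (0:899) * 1000 + 500)
  regions <- data.frame(chrom = "c1", start = 0, end = 801 * 1000 - 500)
  status <- rep("ns", 900)
  status[1:78] <- "up"
  status[802:900] <- "not_expressed"
  degs <- data.frame(gene_id = genes$gene_id, log2FC = 0, status = status,
                     stringsAsFactors = FALSE)
  out <- deg_proportion_in_regions(genes, regions, degs)
  expect_equal(out$n_expressed[1], 801)
  expect_equal(out$n_deg[1], 78)
  expect_equal(out$percent[1], 9.73)            # truncated, not 9.74
  expect_equal(out$percent_full[1], 100 * 78 / 801)

  all_deg <- degs; all_deg$status <- "up"
  expect_equal(deg_proportion_in_regions(genes, regions, all_deg)$percent[1],
               100)
  none <- degs; none$status <- "ns"
  expect_equal(deg_proportion_in_regions(genes, regions, none)$percent[1], 0)
  empty <- degs; empty$status <- "not_expressed"
  expect_warning(out0 <- deg_proportion_in_regions(genes, regions, empty),
                 "undefined")
  expect_true(is.na(out0$percent[1]))
})

test_that("modification histograms use lower-inclusive fraction bins", {
  sites <- data.frame(transcript = c("t1", "t1", "t2", "t3"),
                      position = 1:4, type = "m6A",
                      modified = c(5, 9, 10, 2), coverage = 10,
                      fraction = c(0.5, 0.9, 1.0, 0.2),
                      stringsAsFactors = FALSE)
  h <- summarize_mod_sites(sites, fraction_bins = c(0, 0.5, 1))
  sf <- h$m6A$site_fraction
  expect_equal(sf$n_sites[sf$bin == "[0.5,1)"], 3)  # 0.5 and 1.0 upper bin
  expect_equal(sum(sf$n_sites), 4)
  ts <- h$m6A$transcript_sites
  expect_equal(ts$n_transcripts[ts$bin == "[1,3)"], 3)  # all have < 3 sites
  expect_equal(sum(ts$n_transcripts), 3)
})

test_that("transcripts group by maximal modification fraction", {
  sites <- data.frame(transcript = c("t1", "t1", "t2"), position = 1:3,
                      type = "m6A", modified = c(6, 2, 2), coverage = 10,
                      fraction = c(0.6, 0.2, 0.2), stringsAsFactors = FALSE)
  expr <- c(t1 = 10, t2 = 5, t3 = 2)
  cl <- classify_transcript_mod_level(sites, expr)
  expect_equal(cl$groups$group, c("High", "Low", "Non"))
  # boundary: maximum fraction exactly 0.5 is High
  sites$fraction[1] <- 0.5
  sites$modified[1] <- 5
  expect_equal(classify_transcript_mod_level(sites, expr)$groups$group[1],
               "High")
})

test_that("planted fraction-expression link raises expression of modified transcripts", {
  set.seed(21)
  n <- 300
  frac <- ifelse(runif(n) < 0.5, NA, rbeta(n, 2, 2))
  base <- 2^rnorm(n, 5, 0.8)
  tpm <- base * exp(ifelse(is.na(frac), 0, 1.2 * frac))
  names(tpm) <- sprintf("t%d", 1:n)
  has <- which(!is.na(frac))
  sites <- data.frame(transcript = names(tpm)[has], position = 1,
                      type = "m6A", modified = round(frac[has] * 100),
                      coverage = 100,
                      fraction = round(frac[has] * 100) / 100,
                      stringsAsFactors = FALSE)
  cl <- classify_transcript_mod_level(sites, tpm)
  s <- cl$summary
  expect_gt(s$mean_log2_tpm[s$group == "High"],
            s$mean_log2_tpm[s$group == "Non"])
  expect_lt(cl$tests$p[cl$tests$group1 == "High" &
                         cl$tests$group2 == "Non"], 0.01)
})

test_that("co-modification sets partition transcripts and report overlaps", {
  expr <- stats::setNames(rep(1, 10), sprintf("t%d", 1:10))
  full <- co_modification_sets(names(expr), names(expr), expr)
  expect_equal(full$overlap$pct_m6a_also_m5c, 100)
  expect_equal(full$overlap$pct_m5c_also_m6a, 100)

  disjoint <- co_modification_sets(sprintf("t%d", 1:5),
                                   sprintf("t%d", 6:10), expr)
  expect_equal(sum(disjoint$groups$group == "Both"), 0)
  expect_equal(disjoint$overlap$pct_m6a_also_m5c, 0)

  part <- co_modification_sets(sprintf("t%d", 1:10),
                               sprintf("t%d", 1:9), expr)
  expect_equal(part$overlap$pct_m6a_also_m5c, 90)
  expect_equal(part$overlap$pct_m5c_also_m6a, 100)
  expect_equal(sum(table(part$groups$group)), 10)
})

test_that("permuted replicate labels keep the DEG false-discovery rate controlled", {
  set.seed(77)
  fracs <- replicate(12, {
    tpm <- matrix(2^rnorm(300 * 6, 5, 1.2), 300)   # one null population
    rownames(tpm) <- sprintf("g%d", 1:300)
    d <- compute_degs(tpm[, 1:3], tpm[, 4:6])
    mean(d$q < 0.05, na.rm = TRUE)
  })
  mc_se <- sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.05 + 3 * max(mc_se, 1e-3))
})
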