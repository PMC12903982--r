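# Independent oracles and tiny fixture builders used across the suite.

# Two-sided exact test by full enumeration over all 2x2 tables with the
# observed margins; probabilities from log-binomial coefficients. Kept
# deliberately separate from the package implementation.
fisher_oracle <- function(methA, totalA, methB, totalB) {
  m <- methA + methB
  n <- (totalA - methA) + (totalB - methB)
  k <- totalA
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[match(methA, support)]
  sum(p[p <= obs * (1 + 1e-7)])
}

# >= 1 bp overlap between two interval frames by exhaustive comparison
brute_any_overlap <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          query$start[i] < subject$end)
  }, logical(1))
}

# closed-form Welch t statistic and two-sided p
welch_oracle <- function(a, b) {
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((stats::var(a) / length(a))^2 / (length(a) - 1) +
                   (stats::var(b) / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

tiny_layout <- function(lengths = c(chrT = 100000)) {
  genome_layout(names(lengths), unname(lengths))
}

# pooled-window frame as produced by pool_window_methylation, built
# directly from counts
make_windows <- function(chrom, start, end, meth, total, context = "CG") {
  out <- data.frame(chrom = chrom, start = start, end = end,
                    window_id = sprintf("%s:%d-%d", chrom, start, end),
                    context = context, meth = meth, total = total,
                    stringsAsFactors = FALSE)
  out$freqC <- ifelse(out$total > 0, out$meth / out$total, NA_real_)
  out$no_data <- out$total == 0
  out
}

make_sv <- function(id, chrom, start, end, type, length = NULL) {
  if (is.null(length)) length <- end - start
  data.frame(id = id, chrom = chrom, start = start, end = end, type = type,
             length = length, source = ".", stringsAsFactors = FALSE)
}

make_gene <- function(gene_id, chrom, start, end, strand = "+") {
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand,
             tss = ifelse(strand == "+", start, end - 1),
             stringsAsFactors = FALSE)
}

# a small synthetic bundle shared by pipeline-level tests (cached per run)
small_config <- function(seed = 11) {
  synth_config(
    seed = seed,
    chrom_names = c("chr1", "chr2"), chrom_lengths = c(2e6, 2e6),
    n_genes = 240, n_svs = 140,
    n_dmr_random = c(CG = 30, CHG = 20, CHH = 20),
    n_dmg_genes = 25, n_indel_dmg_genes = 25, n_amg_genes = 18,
    n_switch_segments = 3)
}

small_bundle_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "svcascade_small_bundle")
      unlink(d, recursive = TRUE)
      simulate_multiomics(small_config(), d)
      cache <<- d
    }
    cache
  }
})
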