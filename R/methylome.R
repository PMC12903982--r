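# Window methylation summarisation, DMR/DML calling and InDel-AMR
# detection.
#
# The DMR caller pools cytosine counts across replicates and strands per
# window, tests each window with a two-sided exact test on the pooled
# 2x2 contingency table and adjusts across all tested windows of a context
# with Benjamini-Hochberg. Per-context significance thresholds:
#   CG  : |delta| >= 0.20, q < 0.05
#   CHG : |delta| >= 0.15, q < 0.01
#   CHH : |delta| >= 0.10, q < 0.01

#' Default per-context DMR thresholds
#'
#' @return `data.frame` with columns `context`, `min_delta`, `max_q`.
#' @export
dmr_thresholds <- function() {
  data.frame(context = c("CG", "CHG", "CHH"),
             min_delta = c(0.20, 0.15, 0.10),
             max_q = c(0.05, 0.01, 0.01),
             stringsAsFactors = FALSE)
}

#' Pool cytosine calls into window methylation levels
#'
#' Sums methylated and total read counts over all calls (across strands and
#' any number of replicate call sets) falling in each window, for one
#' context. Windows with zero total coverage are flagged `no_data` and are
#' excluded from downstream testing.
#'
#' @param calls One `data.frame` of cytosine calls
#'   ([read_cytosine_report()]) or a list of them (replicates).
#' @param windows Interval `data.frame`, e.g. from [tile_windows()].
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return `data.frame`: windows plus `context`, `meth`, `total`, `freqC`
#'   (NA when `no_data`), `no_data`.
#' @export
pool_window_methylation <- function(calls, windows, context) {
  if (!context %in% CONTEXTS) stop("unknown context: ", context)
  if (is.data.frame(calls)) calls <- list(calls)
  calls <- lapply(calls, function(x) {
    bad <- setdiff(unique(x$context), CONTEXTS)
    if (length(bad)) stop("calls carry unknown context: ", bad[1])
    x[x$context == context, , drop = FALSE]
  })
  all_calls <- do.call(rbind, calls)
  meth <- numeric(nrow(windows))
  total <- numeric(nrow(windows))
  if (nrow(all_calls)) {
    site <- data.frame(chrom = all_calls$chrom, start = all_calls$pos,
                       end = all_calls$pos + 1)
    hits <- overlap_hits(site, windows)
    if (nrow(hits)) {
      meth <- as.numeric(tapply(all_calls$meth[hits$query], hits$subject, sum)[
        as.character(seq_len(nrow(windows)))])
      total <- as.numeric(
        tapply(all_calls$meth[hits$query] + all_calls$unmeth[hits$query],
               hits$subject, sum)[as.character(seq_len(nrow(windows)))])
      meth[is.na(meth)] <- 0
      total[is.na(total)] <- 0
    }
  }
  out <- windows
  out$context <- context
  out$meth <- meth
  out$total <- total
  out$freqC <- ifelse(total > 0, meth / total, NA_real_)
  out$no_data <- total == 0
  out
}

#' Two-sided exact test on a pooled 2x2 methylation table
#'
#' Tests whether the methylated proportion differs between two conditions
#' for one window, conditioning on both margins. The two-sided p-value sums
#' all hypergeometric point masses not exceeding the observed table's mass
#' (the conventional two-sided rule, with a `1 + 1e-7` relative tolerance
#' for ties at the observed mass).
#'
#' @param methA,totalA Methylated and total counts in condition A.
#' @param methB,totalB Counts in condition B. All vectorised.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_window_test <- function(methA, totalA, methB, totalB) {
  n <- length(methA)
  stopifnot(length(totalA) == n, length(methB) == n, length(totalB) == n)
  if (any(methA < 0 | methB < 0 | methA > totalA | methB > totalB)) {
    stop("counts must satisfy 0 <= meth <= total")
  }
  if (any(totalA == 0 & totalB == 0)) stop("both totals are zero")
  vapply(seq_len(n), function(i) {
    m <- methA[i] + methB[i]          # total methylated (white balls)
    nn <- (totalA[i] - methA[i]) + (totalB[i] - methB[i])
    k <- totalA[i]                    # draws = condition A column margin
    support <- max(0, k - nn):min(k, m)
    mass <- stats::dhyper(support, m, nn, k)
    obs <- stats::dhyper(methA[i], m, nn, k)
    sum(mass[mass <= obs * (1 + 1e-7)])
  }, numeric(1))
}

#' Call differentially methylated regions between two conditions
#'
#' Both conditions must be summarised on the identical window set
#' ([pool_window_methylation()]). Windows lacking coverage in either
#' condition are excluded from testing and from the multiplicity
#' correction. `delta = freqC(B) - freqC(A)`; a window is a DMR when it
#' passes both the per-context effect-size and BH q-value thresholds.
#'
#' @param windowsA,windowsB Pooled window `data.frame`s for conditions A/B.
#' @param context Methylation context; also selects the thresholds.
#' @param thresholds Optional override, `data.frame` as [dmr_thresholds()].
#' @return `data.frame` of all tested windows with `delta`, `p`, `q`,
#'   `direction` (`hyper-in-B`/`hypo-in-B`) and logical `dmr`.
#' @export
call_dmrs <- function(windowsA, windowsB, context, thresholds = dmr_thresholds()) {
  th <- thresholds[thresholds$context == context, ]
  if (nrow(th) != 1) stop("no thresholds for context ", context)
  if (nrow(windowsA) != nrow(windowsB) ||
      !all(windowsA$chrom == windowsB$chrom &
           windowsA$start == windowsB$start &
           windowsA$end == windowsB$end)) {
    stop("window sets of the two conditions are not identical")
  }
  testable <- !windowsA$no_data & !windowsB$no_data
  out <- windowsA[testable, c("chrom", "start", "end")]
  out$context <- context
  out$methA <- windowsA$meth[testable]
  out$totalA <- windowsA$total[testable]
  out$methB <- windowsB$meth[testable]
  out$totalB <- windowsB$total[testable]
  out$freqA <- out$methA / out$totalA
  out$freqB <- out$methB / out$totalB
  out$delta <- out$freqB - out$freqA
  out$p <- if (nrow(out)) fisher_window_test(out$methA, out$totalA,
                                             out$methB, out$totalB) else numeric(0)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$delta >= 0, "hyper-in-B", "hypo-in-B")
  out$dmr <- abs(out$delta) >= th$min_delta & out$q < th$max_q
  rownames(out) <- NULL
  out
}

#' Detect InDel-acquired methylation regions (InDel-AMRs)
#'
#' Scans 100-bp methylation windows of the carrier methylome and reports
#' those that are (i) methylated above `freqc_min` (strict) and (ii)
#' covered by a single InDel for at least `overlap_min` of the window
#' length. Each AMR is linked to the InDel achieving the maximal overlap.
#' Inversions are rejected: acquired methylation is defined for InDels.
#'
#' For insertions the reported 1-bp reference anchor cannot host a 100-bp
#' window; when the windows are expressed on the carrier-genome frame, set
#' `expand_insertions = TRUE` to let each INS occupy
#' `[start, start + length)` on that frame.
#'
#' @param windows100 Pooled `data.frame` from [pool_window_methylation()]
#'   on 100-bp tiles of the carrier methylome.
#' @param svs SV `data.frame` restricted to `INS`/`DEL`.
#' @param freqc_min Minimum window methylation level (strict `>`).
#' @param overlap_min Minimum fraction of the window covered by the SV
#'   (`>=`).
#' @param expand_insertions Treat INS intervals as `[start, start+length)`.
#' @return `data.frame` of AMR windows with `freqC`, `sv_id`, `overlap`.
#' @export
call_amrs <- function(windows100, svs, freqc_min = 0.2, overlap_min = 0.9,
                      expand_insertions = FALSE) {
  if (any(svs$type == "INV")) {
    stop("InDel-AMR detection is defined for InDels; remove inversions")
  }
  sv_iv <- svs
  if (expand_insertions) {
    ins <- sv_iv$type == "INS"
    sv_iv$end[ins] <- sv_iv$start[ins] + sv_iv$length[ins]
  }
  cand <- which(!windows100$no_data & windows100$freqC > freqc_min)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), context = character(0),
                      freqC = numeric(0), sv_id = character(0),
                      overlap = numeric(0))
  if (!length(cand) || nrow(sv_iv) == 0) return(empty)
  w <- windows100[cand, , drop = FALSE]
  hits <- overlap_hits(w, sv_iv)
  if (!nrow(hits)) return(empty)
  hits$frac <- hits$width / (w$end[hits$query] - w$start[hits$query])
  # keep, per window, the SV with maximal overlap fraction
  best <- hits[order(hits$query, -hits$frac), ]
  best <- best[!duplicated(best$query), ]
  best <- best[best$frac >= overlap_min, , drop = FALSE]
  if (!nrow(best)) return(empty)
  out <- w[best$query, c("chrom", "start", "end", "context", "freqC")]
  out$sv_id <- sv_iv$id[best$subject]
  out$overlap <- best$frac
  rownames(out) <- NULL
  out
}

#' Call differentially methylated RNA loci (DMLs)
#'
#' Matches m6A/m5C site tables between two conditions by
#' (transcript, position, type), tests each matched site with the exact
#' test on (modified, unmodified) counts, adjusts with BH per modification
#' type, and flags sites with `|delta| >= min_delta` and `q < max_q`.
#' Unmatched site keys are skipped (their count is reported as the
#' `n_unmatched` attribute).
#'
#' @param sitesA,sitesB Site `data.frame`s ([read_rnamod_table()]).
#' @param min_delta Minimum modification-fraction difference (default 0.20).
#' @param max_q BH q-value cutoff (default 0.05).
#' @return `data.frame` of matched sites with `fracA`, `fracB`, `delta`,
#'   `p`, `q`, logical `dml`; attribute `n_unmatched`.
#' @export
call_dmls <- function(sitesA, sitesB, min_delta = 0.20, max_q = 0.05) {
  keyA <- paste(sitesA$transcript, sitesA$position, sitesA$type, sep = "|")
  keyB <- paste(sitesB$transcript, sitesB$position, sitesB$type, sep = "|")
  i <- match(keyA, keyB)
  matched <- which(!is.na(i))
  n_unmatched <- sum(is.na(i)) + sum(!keyB %in% keyA)
  a <- sitesA[matched, , drop = FALSE]
  b <- sitesB[i[matched], , drop = FALSE]
  ok <- a$coverage > 0 & b$coverage > 0
  a <- a[ok, ]; b <- b[ok, ]
  out <- data.frame(transcript = a$transcript, position = a$position,
                    type = a$type,
                    fracA = a$fraction, fracB = b$fraction,
                    delta = b$fraction - a$fraction,
                    stringsAsFactors = FALSE)
  out$p <- if (nrow(out)) fisher_window_test(a$modified, a$coverage,
                                             b$modified, b$coverage) else numeric(0)
  out$q <- NA_real_
  for (ty in unique(out$type)) {
    sel <- out$type == ty
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$dml <- abs(out$delta) >= min_delta & out$q < max_q
  attr(out, "n_unmatched") <- n_unmatched
  rownames(out) <- NULL
  out
}

#' Strand-aware metagene methylation profile
#'
#' Averages a per-site methylation track over the upstream flank, scaled
#' body and downstream flank of a feature set, oriented 5' to 3'. Flank
#' bins are fixed-width (`flank_bin` bp); the body is split into
#' `body_bins` equal fractions. Features shorter than `body_bins` bp are
#' skipped with a warning.
#'
#' @param calls Cytosine-call `data.frame` (one context) or any
#'   `data.frame` with `chrom`, `pos`, `meth`, `unmeth`.
#' @param features `data.frame` with `chrom`, `start`, `end`, `strand`.
#' @param flank Flank width in bp each side (default 3000).
#' @param flank_bin Flank bin width in bp (default 100).
#' @param body_bins Number of body bins (default 30).
#' @return `data.frame` with `bin` (1..n), `zone`
#'   (upstream/body/downstream) and `level` (mean methylated fraction,
#'   weighted by coverage within each feature bin, averaged over features).
#' @export
metagene_profile <- function(calls, features, flank = 3000, flank_bin = 100,
                             body_bins = 30) {
  n_flank <- as.integer(flank / flank_bin)
  n_bins <- 2L * n_flank + body_bins
  acc <- matrix(0, nrow = 0, ncol = n_bins)
  short <- features$end - features$start < body_bins
  if (any(short)) {
    warning(sum(short), " feature(s) shorter than body_bins bp skipped")
    features <- features[!short, , drop = FALSE]
  }
  lvl <- matrix(NA_real_, nrow = nrow(features), ncol = n_bins)
  for (f in seq_len(nrow(features))) {
    fe <- features[f, ]
    sel <- calls$chrom == fe$chrom & calls$pos >= fe$start - flank &
      calls$pos < fe$end + flank
    cc <- calls[sel, , drop = FALSE]
    if (!nrow(cc)) next
    rel <- cc$pos - fe$start
    len <- fe$end - fe$start
    bin <- integer(nrow(cc))
    up <- rel < 0
    dn <- rel >= len
    body <- !up & !dn
    bin[up] <- n_flank + 1 + floor(rel[up] / flank_bin)       # rel in [-flank,0)
    bin[body] <- n_flank + 1 + floor(rel[body] / len * body_bins)
    bin[dn] <- n_flank + body_bins + 1 + floor((rel[dn] - len) / flank_bin)
    keep <- bin >= 1 & bin <= n_bins
    bin <- bin[keep]; cc <- cc[keep, , drop = FALSE]
    if (fe$strand == "-") bin <- n_bins + 1L - bin
    m <- tapply(cc$meth, bin, sum)
    t <- tapply(cc$meth + cc$unmeth, bin, sum)
    lvl[f, as.integer(names(m))] <- as.numeric(m) / as.numeric(t)
  }
  level <- colMeans(lvl, na.rm = TRUE)
  level[is.nan(level)] <- NA_real_
  data.frame(bin = seq_len(n_bins),
             zone = rep(c("upstream", "body", "downstream"),
                        c(n_flank, body_bins, n_flank)),
             level = level)
}
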