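# Expression comparison and RNA-modification summaries.
#
# Differential expression uses a Welch two-tailed t-test on log2(TPM + 1)
# across replicates with BH adjustment; the cascade logic downstream is
# agnostic to the DE engine, so an externally computed DEG table with the
# same columns can be substituted.

#' Differential expression between two replicate groups
#'
#' `log2FC = log2((mean TPM_B + 1) / (mean TPM_A + 1))`; p-values from a
#' Welch two-tailed t-test on `log2(TPM + 1)` across replicates, BH
#' adjusted over tested genes. Genes below `min_tpm` in every sample of
#' both conditions are `not_expressed` and excluded from testing and from
#' the multiplicity correction. Status `up`/`down` requires
#' `|log2FC| >= min_lfc` and `q < max_q`.
#'
#' @param exprA,exprB Numeric gene x replicate TPM matrices with matching
#'   row order (>= 2 replicates each).
#' @param min_tpm Expression floor defining "expressed" (default 1).
#' @param min_lfc Absolute log2 fold-change cutoff (default 1).
#' @param max_q FDR cutoff (default 0.05).
#' @return `data.frame`: `gene_id`, `meanA`, `meanB`, `log2FC`, `p`, `q`,
#'   `status` in `{up, down, ns, not_expressed}`.
#' @export
compute_degs <- function(exprA, exprB, min_tpm = 1.0, min_lfc = 1.0,
                         max_q = 0.05) {
  if (ncol(exprA) < 2 || ncol(exprB) < 2) {
    stop("need >= 2 replicates per condition")
  }
  stopifnot(nrow(exprA) == nrow(exprB))
  meanA <- rowMeans(exprA)
  meanB <- rowMeans(exprB)
  lfc <- log2((meanB + 1) / (meanA + 1))
  expressed <- apply(cbind(exprA, exprB) >= min_tpm, 1, any)
  la <- log2(exprA + 1)
  lb <- log2(exprB + 1)
  p <- rep(NA_real_, nrow(exprA))
  idx <- which(expressed)
  p[idx] <- vapply(idx, function(i) {
    a <- la[i, ]; b <- lb[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(b, a)$p.value
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[idx] <- stats::p.adjust(p[idx], method = "BH")
  status <- rep("ns", length(p))
  status[!expressed] <- "not_expressed"
  sig <- expressed & abs(lfc) >= min_lfc & !is.na(q) & q < max_q
  status[sig & lfc > 0] <- "up"
  status[sig & lfc < 0] <- "down"
  data.frame(gene_id = rownames(exprA), meanA = meanA, meanB = meanB,
             log2FC = lfc, p = p, q = q, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportion of DEGs among expressed genes in a region set
#'
#' Assigns genes to the region set by >= 1 bp overlap of the gene
#' interval, and reports expressed gene and DEG counts plus the DEG
#' percentage for the region set and genome-wide. Percentages are
#' truncated (not rounded) to two decimals, alongside full precision.
#'
#' @param genes Gene `data.frame` (`gene_id`, `chrom`, `start`, `end`).
#' @param regions Interval `data.frame`.
#' @param degs DEG table from [compute_degs()].
#' @return `data.frame` with rows `regions` and `genome`: `n_expressed`,
#'   `n_deg`, `percent` (truncated), `percent_full`.
#' @export
deg_proportion_in_regions <- function(genes, regions, degs) {
  in_reg <- rep(FALSE, nrow(genes))
  in_reg[overlaps_any_idx(genes, regions)] <- TRUE
  st <- degs$status[match(genes$gene_id, degs$gene_id)]
  expressed <- !is.na(st) & st != "not_expressed"
  deg <- st %in% c("up", "down")
  row_for <- function(sel, scope) {
    n_exp <- sum(expressed & sel)
    n_deg <- sum(deg & sel)
    pct <- if (n_exp > 0) 100 * n_deg / n_exp else NA_real_
    data.frame(scope = scope, n_expressed = n_exp, n_deg = n_deg,
               percent = if (is.na(pct)) NA_real_ else trunc(pct * 100) / 100,
               percent_full = pct, stringsAsFactors = FALSE)
  }
  out <- rbind(row_for(in_reg, "regions"), row_for(rep(TRUE, nrow(genes)),
                                                   "genome"))
  if (out$n_expressed[1] == 0) {
    warning("no expressed genes in the region set; percentage undefined")
  }
  out
}

#' Histogram summaries of RNA-modification sites
#'
#' Per modification type: site counts per fraction bin and transcript
#' counts per number-of-sites bin. Fraction bins are lower-inclusive
#' (`[a, b)`), with the final bin closed at 1.
#'
#' @param sites Site `data.frame` ([read_rnamod_table()]).
#' @param fraction_bins Fraction bin edges (default
#'   `seq(0, 1, by = 0.25)`).
#' @param count_bins Site-count bin edges, right-open (default
#'   `c(1, 3, 6, 11, 51, Inf)`: 1-2, 3-5, 6-10, 11-50, >50).
#' @return List of per-type `data.frame`s: `site_fraction` and
#'   `transcript_sites`.
#' @export
summarize_mod_sites <- function(sites, fraction_bins = seq(0, 1, by = 0.25),
                                count_bins = c(1, 3, 6, 11, 51, Inf)) {
  out <- list()
  for (ty in unique(sites$type)) {
    s <- sites[sites$type == ty, , drop = FALSE]
    fb <- cut(s$fraction, breaks = fraction_bins, right = FALSE,
              include.lowest = FALSE)
    fb[s$fraction >= fraction_bins[length(fraction_bins)]] <-
      levels(fb)[length(levels(fb))]
    site_fraction <- as.data.frame(table(bin = fb), stringsAsFactors = FALSE)
    names(site_fraction)[2] <- "n_sites"
    per_tx <- table(s$transcript)
    cb <- cut(as.numeric(per_tx), breaks = count_bins, right = FALSE)
    transcript_sites <- as.data.frame(table(bin = cb),
                                      stringsAsFactors = FALSE)
    names(transcript_sites)[2] <- "n_transcripts"
    out[[ty]] <- list(site_fraction = site_fraction,
                      transcript_sites = transcript_sites)
  }
  out
}

welch_pair_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b)$p.value
}

#' Group transcripts by maximal modification fraction and compare
#' expression
#'
#' `High`: maximal site fraction in `[0.5, 1]`; `Low`: in `(0, 0.5)`;
#' `Non`: no site of that type. Pairwise Welch two-tailed t-tests on
#' `log2(TPM + 1)` (mean TPM is also reported per group).
#'
#' @param sites Site `data.frame` for one modification type (or filtered
#'   internally via `type`).
#' @param expression Named numeric vector of TPM per transcript (the
#'   transcript universe).
#' @param type Modification type to use when `sites` carries several.
#' @return List: `groups` (`transcript`, `group`, `tpm`), `summary`
#'   (per-group n, mean TPM, mean log2 TPM), `tests` (pairwise Welch
#'   p-values on log2(TPM+1)).
#' @export
classify_transcript_mod_level <- function(sites, expression, type = NULL) {
  if (!is.null(type)) sites <- sites[sites$type == type, , drop = FALSE]
  max_frac <- tapply(sites$fraction, sites$transcript, max)
  tx <- names(expression)
  mf <- as.numeric(max_frac[tx])
  group <- ifelse(is.na(mf), "Non", ifelse(mf >= 0.5, "High", "Low"))
  groups <- data.frame(transcript = tx, group = group,
                       tpm = as.numeric(expression),
                       stringsAsFactors = FALSE)
  ltpm <- log2(groups$tpm + 1)
  summary <- do.call(rbind, lapply(c("High", "Low", "Non"), function(gp) {
    sel <- groups$group == gp
    data.frame(group = gp, n = sum(sel), mean_tpm = mean(groups$tpm[sel]),
               mean_log2_tpm = mean(ltpm[sel]))
  }))
  pairs <- utils::combn(c("High", "Low", "Non"), 2)
  tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      p = apply(pairs, 2, function(pr) {
                        welch_pair_test(ltpm[groups$group == pr[1]],
                                        ltpm[groups$group == pr[2]])
                      }))
  list(groups = groups, summary = summary, tests = tests)
}

#' Co-modification sets and expression comparison
#'
#' Partitions the transcript universe into `Both`, `m6A-only`,
#' `m5C-only`, `none`; reports the percentage of m6A-modified transcripts
#' also carrying m5C (and vice versa) and pairwise Welch tests on
#' `log2(TPM + 1)` between the four groups.
#'
#' @param m6a_tx,m5c_tx Character vectors of modified transcript ids.
#' @param expression Named numeric vector of TPM over the transcript
#'   universe.
#' @return List: `groups`, `overlap` (`pct_m6a_also_m5c`,
#'   `pct_m5c_also_m6a`), `summary`, `tests`.
#' @export
co_modification_sets <- function(m6a_tx, m5c_tx, expression) {
  tx <- names(expression)
  has6 <- tx %in% m6a_tx
  has5 <- tx %in% m5c_tx
  group <- ifelse(has6 & has5, "Both",
                  ifelse(has6, "m6A-only", ifelse(has5, "m5C-only", "none")))
  groups <- data.frame(transcript = tx, group = group,
                       tpm = as.numeric(expression),
                       stringsAsFactors = FALSE)
  overlap <- data.frame(
    pct_m6a_also_m5c = if (any(has6)) 100 * sum(has6 & has5) / sum(has6)
      else NA_real_,
    pct_m5c_also_m6a = if (any(has5)) 100 * sum(has6 & has5) / sum(has5)
      else NA_real_)
  ltpm <- log2(groups$tpm + 1)
  lvls <- c("Both", "m6A-only", "m5C-only", "none")
  summary <- do.call(rbind, lapply(lvls, function(gp) {
    sel <- groups$group == gp
    data.frame(group = gp, n = sum(sel),
               mean_tpm = if (any(sel)) mean(groups$tpm[sel]) else NA_real_,
               mean_log2_tpm = if (any(sel)) mean(ltpm[sel]) else NA_real_)
  }))
  pairs <- utils::combn(lvls, 2)
  tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      p = apply(pairs, 2, function(pr) {
                        welch_pair_test(ltpm[groups$group == pr[1]],
                                        ltpm[groups$group == pr[2]])
                      }))
  list(groups = groups, overlap = overlap, summary = summary, tests = tests)
}
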