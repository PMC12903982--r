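# A/B compartment assignment and switch segmentation; TAD
# conserved/differential classification from domain calls; SV-TAD
# co-occurrence statistics.
#
# Differential TADs are classified by boundary matching between the two
# conditions' domain calls: a domain is conserved iff the other condition
# has a domain with both boundaries within `tolerance` bp (default one
# 20-kb calling bin). This operates on domain calls only, not on contact
# matrices.

#' Assign A/B compartment labels from a PC1 track
#'
#' The sign of the Hi-C first principal component is arbitrary per
#' chromosome; it is oriented so that the Pearson correlation of PC1 with
#' gene density is positive (the gene-dense, lowly methylated state is the
#' A compartment). After orientation, bins with PC1 > 0 are `A`,
#' PC1 < 0 are `B`, PC1 == 0 (or missing) are `NA`.
#'
#' @param pc1 bedGraph-style `data.frame` (`chrom`, `start`, `end`,
#'   `value`).
#' @param gene_density Numeric vector of gene counts/density per bin,
#'   aligned with `pc1` rows.
#' @param methylation Optional per-bin methylation level, used only as a
#'   tie-breaker when gene density is constant on a chromosome (orient so
#'   correlation with methylation is negative).
#' @return `pc1` with `pc1_oriented` and `label` (`A`/`B`/`NA`) columns.
#' @export
assign_compartments <- function(pc1, gene_density, methylation = NULL) {
  stopifnot(length(gene_density) == nrow(pc1))
  out <- pc1
  out$pc1_oriented <- out$value
  for (ch in unique(out$chrom)) {
    sel <- out$chrom == ch
    v <- out$value[sel]
    if (all(v == 0)) {
      warning("all-zero PC1 on ", ch, ": labels set to NA")
      next
    }
    g <- gene_density[sel]
    flip <- 1
    if (stats::sd(g) > 0 && stats::sd(v) > 0) {
      if (stats::cor(v, g) < 0) flip <- -1
    } else if (!is.null(methylation) && stats::sd(methylation[sel]) > 0 &&
               stats::sd(v) > 0) {
      if (stats::cor(v, methylation[sel]) > 0) flip <- -1
    }
    out$pc1_oriented[sel] <- flip * v
  }
  out$label <- ifelse(out$pc1_oriented > 0, "A",
                      ifelse(out$pc1_oriented < 0, "B", NA_character_))
  out
}

#' Detect A/B compartment switch segments between two conditions
#'
#' Finds maximal runs of bins whose label changes between the two
#' conditions. A run of at least two consecutive bins going A -> B is an
#' `A2B` segment (and symmetrically `B2A`); single-bin flips and unchanged
#' bins are reported as stable; bins with an NA label in either condition
#' break runs and belong to no segment.
#'
#' @param binsA,binsB Labelled bin `data.frame`s from
#'   [assign_compartments()], on identical binning.
#' @return `data.frame` of segments: `chrom`, `start`, `end`, `from`,
#'   `to`, `n_bins`, `class` (`A2B`, `B2A`, `stableA`, `stableB`).
#' @export
detect_switch_segments <- function(binsA, binsB) {
  if (nrow(binsA) != nrow(binsB) ||
      !all(binsA$chrom == binsB$chrom & binsA$start == binsB$start &
           binsA$end == binsB$end)) {
    stop("compartment bin sets are not identical")
  }
  state <- rep(NA_character_, nrow(binsA))
  ok <- !is.na(binsA$label) & !is.na(binsB$label)
  state[ok] <- paste0(binsA$label[ok], binsB$label[ok])  # AA AB BA BB
  segs <- list()
  r <- rle(paste(binsA$chrom, state, sep = "|"))
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  for (j in seq_along(r$values)) {
    st <- state[idx_start[j]]
    if (is.na(st)) next
    n <- r$lengths[j]
    cls <- switch(st,
                  AA = "stableA", BB = "stableB",
                  AB = if (n >= 2) "A2B" else NA_character_,
                  BA = if (n >= 2) "B2A" else NA_character_)
    if (is.na(cls)) cls <- paste0("stable", substr(st, 1, 1))  # 1-bin flip
    segs[[length(segs) + 1]] <- data.frame(
      chrom = binsA$chrom[idx_start[j]],
      start = binsA$start[idx_start[j]],
      end = binsA$end[idx_end[j]],
      from = substr(st, 1, 1), to = substr(st, 2, 2),
      n_bins = n, class = cls, stringsAsFactors = FALSE)
  }
  if (!length(segs)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), from = character(0),
                      to = character(0), n_bins = integer(0),
                      class = character(0)))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Classify TADs as conserved or differential by boundary matching
#'
#' A domain of one condition is conserved iff the other condition contains
#' a domain on the same chromosome with `|start - start'| <= tolerance`
#' and `|end - end'| <= tolerance`; otherwise it is differential. The
#' relation is symmetric in the two inputs. The differential-region set is
#' the merged union of the differential domains of both conditions.
#'
#' @param tadsA,tadsB Domain `data.frame`s (`chrom`, `start`, `end`,
#'   optionally `name`).
#' @param tolerance Boundary-matching tolerance in bp (default 20000, one
#'   calling bin).
#' @return List: `comparisons` (domains of both conditions with
#'   `condition`, `label`, `partner`), `differential_regions` (merged
#'   intervals), `counts` (per-condition conserved/differential tallies).
#' @export
match_tads <- function(tadsA, tadsB, tolerance = 20000) {
  label_one <- function(x, other, cond) {
    if (nrow(x) == 0) {
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), name = character(0),
                        condition = character(0), label = character(0),
                        partner = character(0)))
    }
    x <- x[order(x$chrom, x$start), , drop = FALSE]
    if (!"name" %in% names(x)) {
      x$name <- sprintf("%s_tad_%d", cond, seq_len(nrow(x)))
    }
    x$condition <- cond
    x$label <- "differential"
    x$partner <- NA_character_
    if (nrow(other)) {
      if (!"name" %in% names(other)) {
        other$name <- sprintf("partner_%d", seq_len(nrow(other)))
      }
      for (i in seq_len(nrow(x))) {
        cand <- which(other$chrom == x$chrom[i] &
                        abs(other$start - x$start[i]) <= tolerance &
                        abs(other$end - x$end[i]) <= tolerance)
        if (length(cand)) {
          # nearest partner by total boundary displacement
          d <- abs(other$start[cand] - x$start[i]) +
            abs(other$end[cand] - x$end[i])
          x$label[i] <- "conserved"
          x$partner[i] <- other$name[cand[which.min(d)]]
        }
      }
    }
    x
  }
  compA <- label_one(tadsA, tadsB, "A")
  compB <- label_one(tadsB, tadsA, "B")
  comparisons <- rbind(compA, compB)
  rownames(comparisons) <- NULL
  diff <- comparisons[comparisons$label == "differential", , drop = FALSE]
  list(comparisons = comparisons,
       differential_regions = merge_intervals(diff),
       counts = data.frame(
         condition = c("A", "B"),
         conserved = c(sum(compA$label == "conserved"),
                       sum(compB$label == "conserved")),
         differential = c(sum(compA$label == "differential"),
                          sum(compB$label == "differential"))))
}

#' SV counts per TAD with a conserved-vs-differential group test
#'
#' Counts SVs whose reference interval overlaps each domain (insertions
#' count through their 1-bp anchor) and compares the count distributions
#' of conserved and differential domains with a Welch two-tailed t-test.
#'
#' @param svs SV `data.frame`.
#' @param comparisons Labelled domain `data.frame`
#'   ([match_tads()]`$comparisons`, or any domains with a `label` column).
#' @return List: `per_domain` (domains plus `n_sv`), `test` (`data.frame`
#'   with group means, `t`, `df`, `p`; `t`/`p` NA when a group is empty).
#' @export
sv_counts_per_tad <- function(svs, comparisons) {
  comparisons$n_sv <- count_overlaps_in(comparisons, svs)
  cons <- comparisons$n_sv[comparisons$label == "conserved"]
  diff <- comparisons$n_sv[comparisons$label == "differential"]
  test <- data.frame(mean_conserved = mean(cons), mean_differential = mean(diff),
                     t = NA_real_, df = NA_real_, p = NA_real_)
  if (length(cons) >= 2 && length(diff) >= 2 &&
      (stats::sd(cons) > 0 || stats::sd(diff) > 0)) {
    tt <- stats::t.test(diff, cons)
    test$t <- unname(tt$statistic)
    test$df <- unname(tt$parameter)
    test$p <- tt$p.value
  } else if (length(cons) && length(diff) &&
             isTRUE(all.equal(mean(cons), mean(diff)))) {
    test$t <- 0; test$p <- 1
  }
  list(per_domain = comparisons, test = test)
}

#' SV density profile around scaled domains
#'
#' Each domain body is scaled to `body_bins` bins, with flanks of
#' `flank_frac` times the domain length each side, split into
#' `body_bins * flank_frac` bins of the same relative width. SV midpoints
#' are accumulated per bin; mean density per bin per Mb is reported
#' separately for conserved and differential domains.
#'
#' @param svs SV `data.frame`.
#' @param domains Labelled domain `data.frame` (needs `label`).
#' @param body_bins Bins across the domain body (default 50).
#' @param flank_frac Flank size as a fraction of domain length (default
#'   0.5).
#' @return `data.frame` with `bin`, `rel_pos` (-flank_frac..1+flank_frac),
#'   `zone`, and per-label mean density columns.
#' @export
sv_density_profile <- function(svs, domains, body_bins = 50,
                               flank_frac = 0.5) {
  n_flank <- round(body_bins * flank_frac)
  n_bins <- body_bins + 2L * n_flank
  mid <- (svs$start + svs$end) / 2
  profile_for <- function(dom) {
    if (!nrow(dom)) return(rep(NA_real_, n_bins))
    dens <- matrix(0, nrow(dom), n_bins)
    for (i in seq_len(nrow(dom))) {
      len <- dom$end[i] - dom$start[i]
      lo <- dom$start[i] - flank_frac * len
      rel <- (mid[svs$chrom == dom$chrom[i]] - lo) / (len / body_bins)
      rel <- rel[rel >= 0 & rel < n_bins]
      if (length(rel)) {
        tb <- table(floor(rel) + 1)
        dens[i, as.integer(names(tb))] <- as.numeric(tb)
      }
      dens[i, ] <- dens[i, ] / ((len / body_bins) / 1e6)  # per Mb
    }
    colMeans(dens)
  }
  data.frame(bin = seq_len(n_bins),
             rel_pos = (seq_len(n_bins) - 0.5) / body_bins - flank_frac,
             zone = rep(c("upstream", "body", "downstream"),
                        c(n_flank, body_bins, n_flank)),
             conserved = profile_for(domains[domains$label == "conserved", ]),
             differential = profile_for(
               domains[domains$label == "differential", ]))
}

#' Fraction of SVs overlapping a region set
#'
#' @param svs SV `data.frame` (non-empty).
#' @param regions Interval `data.frame`; merged internally.
#' @return Fraction in `[0, 1]` of SVs whose reference interval overlaps
#'   the region set by at least 1 bp.
#' @export
fraction_svs_in_regions <- function(svs, regions) {
  if (nrow(svs) == 0) stop("empty SV set")
  regions <- merge_intervals(regions)
  length(overlaps_any_idx(svs, regions)) / nrow(svs)
}

#' Per-window proportion of SV-associated TAD boundaries
#'
#' Materialises each domain edge as an interval of `boundary_width` bp
#' centred on the edge, tiles the genome into non-overlapping windows of
#' `window` bp, and computes per window the proportion of boundaries
#' (assigned by their centre) that overlap at least one SV. Windows
#' containing no boundary are excluded from the unweighted mean.
#'
#' @param comparisons Domain `data.frame` (any condition labels).
#' @param svs SV `data.frame`.
#' @param layout [genome_layout()] used for the window tiling.
#' @param window Window size in bp (default 10 Mb).
#' @param boundary_width Boundary interval width in bp (default 20 kb).
#' @return List: `per_window` (`chrom`, `start`, `end`, `n_boundaries`,
#'   `n_sv_boundaries`, `proportion`), `mean_proportion`.
#' @export
boundary_sv_window_stats <- function(comparisons, svs, layout,
                                     window = 1e7, boundary_width = 20000) {
  if (window <= 0) stop("window must be > 0")
  edges <- unique(data.frame(
    chrom = rep(comparisons$chrom, 2),
    pos = c(comparisons$start, comparisons$end)))
  half <- boundary_width / 2
  bounds <- data.frame(chrom = edges$chrom,
                       start = pmax(0, edges$pos - half),
                       end = edges$pos + half)
  if (nrow(bounds)) {
    bounds$end <- pmin(bounds$end, chrom_length(layout, bounds$chrom))
    bounds$center <- edges$pos
    bounds$has_sv <- FALSE
    if (nrow(svs)) {
      bounds$has_sv[overlaps_any_idx(bounds, svs)] <- TRUE
    }
  }
  wins <- tile_windows(layout, window)
  wins$n_boundaries <- 0L
  wins$n_sv_boundaries <- 0L
  if (nrow(bounds)) {
    centers <- data.frame(chrom = bounds$chrom, start = bounds$center,
                          end = bounds$center + 1)
    hits <- overlap_hits(centers, wins)
    tab_all <- table(hits$subject)
    tab_sv <- table(hits$subject[bounds$has_sv[hits$query]])
    wins$n_boundaries[as.integer(names(tab_all))] <- as.integer(tab_all)
    wins$n_sv_boundaries[as.integer(names(tab_sv))] <- as.integer(tab_sv)
  }
  wins$proportion <- ifelse(wins$n_boundaries > 0,
                            wins$n_sv_boundaries / wins$n_boundaries,
                            NA_real_)
  list(per_window = wins,
       mean_proportion = mean(wins$proportion, na.rm = TRUE))
}
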