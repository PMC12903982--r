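# Gene-level integration of SVs, DMRs and AMRs into cascade categories
# and the expression-impact statistics.
#
# Categories (priority order): InDel-AMG > InDel-DMG > DMG > SV-gene >
# genome-wide. A gene's footprint is its body plus a strand-aware
# upstream flank (default 2 kb, harmonised with the DPG promoter
# window); a body-only mode is available.

# strand-aware upstream window (TSS - width, TSS], clipped at 0
upstream_window <- function(genes, width) {
  plus <- genes$strand == "+"
  data.frame(chrom = genes$chrom,
             start = ifelse(plus, pmax(0, genes$start - width), genes$end),
             end = ifelse(plus, genes$start, genes$end + width),
             gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

gene_footprint <- function(genes, flank, mode = c("footprint", "body")) {
  mode <- match.arg(mode)
  fp <- genes[, c("chrom", "start", "end")]
  if (mode == "footprint" && flank > 0) {
    plus <- genes$strand == "+"
    fp$start <- ifelse(plus, pmax(0, genes$start - flank), genes$start)
    fp$end <- ifelse(plus, genes$end, genes$end + flank)
  }
  fp$gene_id <- genes$gene_id
  fp
}

#' Find DMR-associated proximal genes (DPGs)
#'
#' A gene is a DPG when any DMR overlaps its 2-kb (strand-aware)
#' upstream promoter window.
#'
#' @param dmrs DMR `data.frame` (rows with `dmr == TRUE` are used when the
#'   column is present; otherwise all rows count).
#' @param genes Gene `data.frame` with `strand`.
#' @param upstream Promoter window width in bp (default 2000).
#' @return Character vector of DPG gene ids.
#' @export
find_dpgs <- function(dmrs, genes, upstream = 2000) {
  if ("dmr" %in% names(dmrs)) dmrs <- dmrs[dmrs$dmr, , drop = FALSE]
  prom <- upstream_window(genes, upstream)
  prom <- prom[prom$start < prom$end, , drop = FALSE]
  hit <- overlaps_any_idx(prom, dmrs)
  sort(unique(prom$gene_id[hit]))
}

#' Classify genes into SV/methylation cascade categories
#'
#' Flags per gene: `sv_gene` (footprint overlaps any SV), `dmg`
#' (footprint overlaps a DMR), `indel_dmg` (footprint overlaps both a
#' DMR and an InDel), `indel_amg` (footprint overlaps an InDel-AMR
#' window), `dpg` (DMR within the 2-kb promoter window). The resolved
#' category takes the highest-priority applicable label.
#'
#' @param genes Gene `data.frame` with `strand`.
#' @param svs SV `data.frame` (all types; InDel-specific flags use
#'   INS/DEL only).
#' @param dmrs DMR `data.frame` (rows with `dmr == TRUE` used when
#'   present).
#' @param amrs AMR `data.frame` from [call_amrs()] (may be empty).
#' @param footprint_flank Upstream flank of the gene footprint in bp
#'   (default 2000).
#' @param mode `"footprint"` (body + upstream flank) or `"body"`.
#' @return `data.frame`: one row per gene with logical flags and
#'   `category` in `{genome-wide, SV-gene, DMG, InDel-DMG, InDel-AMG}`.
#' @export
classify_genes <- function(genes, svs, dmrs, amrs,
                           footprint_flank = 2000,
                           mode = c("footprint", "body")) {
  mode <- match.arg(mode)
  if ("dmr" %in% names(dmrs)) dmrs <- dmrs[dmrs$dmr, , drop = FALSE]
  fp <- gene_footprint(genes, footprint_flank, mode)
  flag <- function(track) {
    res <- rep(FALSE, nrow(fp))
    if (!is.null(track) && nrow(track)) {
      res[overlaps_any_idx(fp, track)] <- TRUE
    }
    res
  }
  indels <- svs[svs$type %in% c("INS", "DEL"), , drop = FALSE]
  out <- data.frame(gene_id = genes$gene_id,
                    sv_gene = flag(svs),
                    indel_gene = flag(indels),
                    dmg = flag(dmrs),
                    indel_amg = flag(amrs),
                    stringsAsFactors = FALSE)
  out$indel_dmg <- out$indel_gene & out$dmg
  out$dpg <- genes$gene_id %in% find_dpgs(dmrs, genes, upstream = footprint_flank)
  out$category <- "genome-wide"
  out$category[out$sv_gene] <- "SV-gene"
  out$category[out$dmg] <- "DMG"
  out$category[out$indel_dmg] <- "InDel-DMG"
  out$category[out$indel_amg] <- "InDel-AMG"
  out$category <- factor(out$category,
                         levels = c("genome-wide", "SV-gene", "DMG",
                                    "InDel-DMG", "InDel-AMG"))
  out
}

#' Expression impact by cascade category
#'
#' Summarises the distribution of absolute log2 fold-changes per cascade
#' category and runs all pairwise Welch two-tailed t-tests on |log2FC|,
#' BH-adjusted. `not_expressed` genes are excluded; categories with
#' fewer than two members are reported descriptively but excluded from
#' testing.
#'
#' @param labels Output of [classify_genes()].
#' @param degs DEG table from [compute_degs()] (or compatible).
#' @return List: `summary` (per category n, mean, median |log2FC|),
#'   `tests` (pairwise Welch with `p` and BH `q`), `values` (per-gene
#'   category and |log2FC|).
#' @export
expression_impact_by_category <- function(labels, degs) {
  m <- match(labels$gene_id, degs$gene_id)
  values <- data.frame(gene_id = labels$gene_id,
                       category = labels$category,
                       abs_lfc = abs(degs$log2FC[m]),
                       status = degs$status[m],
                       stringsAsFactors = FALSE)
  values <- values[!is.na(values$status) & values$status != "not_expressed", ]
  lvls <- levels(labels$category)
  summary <- do.call(rbind, lapply(lvls, function(cat) {
    v <- values$abs_lfc[values$category == cat]
    data.frame(category = cat, n = length(v),
               mean_abs_lfc = if (length(v)) mean(v) else NA_real_,
               median_abs_lfc = if (length(v)) stats::median(v) else NA_real_)
  }))
  testable <- summary$category[summary$n >= 2]
  tests <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(as.character(testable), 2)
    tests <- data.frame(
      category1 = pairs[1, ], category2 = pairs[2, ],
      p = apply(pairs, 2, function(pr) {
        welch_pair_test(values$abs_lfc[values$category == pr[1]],
                        values$abs_lfc[values$category == pr[2]])
      }), stringsAsFactors = FALSE)
    tests$q <- stats::p.adjust(tests$p, method = "BH")
  }
  list(summary = summary, tests = tests, values = values)
}
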