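# Type-aware SV merging across callsets and gene-context annotation.

#' Merge structural variants across callsets
#'
#' Clusters records of the same type (per chromosome) whose start
#' positions chain within `max_dist` bp (transitive within a cluster) and
#' keeps one representative per cluster: the leftmost start with the
#' longest member length. Different SV types never merge. Inversions
#' additionally require reciprocal overlap of at least `inv_reciprocal`
#' with the first member of the open cluster, so that distant breakpoints
#' with incidental anchor proximity stay separate. Source callsets are
#' concatenated into the representative's `source`.
#'
#' @param callsets A single SV `data.frame` or a list of them.
#' @param max_dist Start-position clustering distance in bp (default
#'   1000).
#' @param inv_reciprocal Minimum reciprocal overlap for INV merging
#'   (default 0.5).
#' @return Non-redundant SV `data.frame` with `n_support` (cluster size).
#' @export
merge_svs <- function(callsets, max_dist = 1000, inv_reciprocal = 0.5) {
  if (is.data.frame(callsets)) callsets <- list(callsets)
  all_svs <- do.call(rbind, lapply(seq_along(callsets), function(i) {
    x <- callsets[[i]]
    if (!"source" %in% names(x) || all(x$source == ".")) {
      x$source <- sprintf("callset%d", i)
    }
    x
  }))
  if (nrow(all_svs) == 0) return(all_svs)
  all_svs <- all_svs[order(all_svs$chrom, all_svs$type, all_svs$start,
                           -all_svs$length), , drop = FALSE]
  grp <- paste(all_svs$chrom, all_svs$type)
  # transitive start-distance chaining, vectorised per (chrom, type)
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gap <- c(Inf, diff(all_svs$start))
  new_cluster <- new_grp | gap > max_dist
  # inversions additionally need reciprocal overlap with the cluster seed
  inv_idx <- which(all_svs$type == "INV")
  if (length(inv_idx)) {
    seed <- NA_integer_
    for (i in inv_idx) {
      if (new_cluster[i]) { seed <- i; next }
      ov <- max(0, min(all_svs$end[i], all_svs$end[seed]) -
                  max(all_svs$start[i], all_svs$start[seed]))
      ok <- ov / (all_svs$end[i] - all_svs$start[i]) >= inv_reciprocal &&
        ov / (all_svs$end[seed] - all_svs$start[seed]) >= inv_reciprocal
      if (!ok) { new_cluster[i] <- TRUE; seed <- i }
    }
  }
  cl <- cumsum(new_cluster)
  first <- !duplicated(cl)   # leftmost start (longest on ties) per cluster
  res <- all_svs[first, , drop = FALSE]
  idx <- as.character(cl[first])
  res$length <- as.numeric(tapply(all_svs$length, cl, max)[idx])
  res$n_support <- as.integer(tapply(cl, cl, length)[idx])
  res$source <- as.character(tapply(all_svs$source, cl, function(s) {
    paste(sort(unique(unlist(strsplit(s, ",")))), collapse = ",")
  })[idx])
  res$end <- ifelse(res$type == "INS", res$start + 1, res$start + res$length)
  res <- res[, c("id", "chrom", "start", "end", "type", "length", "source",
                 "n_support")]
  res <- res[order(res$chrom, res$start, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate the gene context of each SV
#'
#' Assigns one category per SV with priority
#' exon > intron > upstream > downstream > intergenic. Upstream and
#' downstream are strand-aware flank intervals of width `flank` adjacent
#' to the gene ends; introns are the gene body minus its exons. Genes
#' without exon records are treated as fully exonic (with a warning).
#' When an SV touches several genes, the category highest in the priority
#' list wins; among genes tied at that category the one with the nearest
#' TSS is reported.
#'
#' @param svs SV `data.frame`.
#' @param genes List with `genes` and `exons` as from
#'   [read_gff3_genes()].
#' @param flank Flank width in bp (default 1000).
#' @return `svs` with `category` and `gene_id` columns.
#' @export
annotate_sv_context <- function(svs, genes, flank = 1000) {
  g <- genes$genes
  e <- genes$exons
  no_exon <- setdiff(g$gene_id, e$gene_id)
  if (length(no_exon)) {
    warning(length(no_exon),
            " gene(s) without exons treated as fully exonic")
    e <- rbind(e, data.frame(gene_id = no_exon,
                             chrom = g$chrom[match(no_exon, g$gene_id)],
                             start = g$start[match(no_exon, g$gene_id)],
                             end = g$end[match(no_exon, g$gene_id)]))
  }
  # introns: per-gene body minus exons
  introns <- do.call(rbind, lapply(split(e, e$gene_id), function(ex) {
    gi <- g[g$gene_id == ex$gene_id[1], ]
    body <- as_granges(gi)
    inr <- GenomicRanges::setdiff(body, as_granges(ex))
    if (!length(inr)) return(NULL)
    cbind(from_granges(inr), gene_id = ex$gene_id[1])
  }))
  plus <- g$strand == "+"
  up <- data.frame(chrom = g$chrom,
                   start = ifelse(plus, pmax(0, g$start - flank), g$end),
                   end = ifelse(plus, g$start, g$end + flank),
                   gene_id = g$gene_id)
  dn <- data.frame(chrom = g$chrom,
                   start = ifelse(plus, g$end, pmax(0, g$start - flank)),
                   end = ifelse(plus, g$end + flank, g$start),
                   gene_id = g$gene_id)
  up <- up[up$start < up$end, , drop = FALSE]
  dn <- dn[dn$start < dn$end, , drop = FALSE]

  tiers <- list(exon = e, intron = introns, upstream = up, downstream = dn)
  cat <- rep("intergenic", nrow(svs))
  gene_hit <- rep(NA_character_, nrow(svs))
  unassigned <- seq_len(nrow(svs))
  for (tier in names(tiers)) {
    iv <- tiers[[tier]]
    if (is.null(iv) || !nrow(iv) || !length(unassigned)) next
    hits <- overlap_hits(svs[unassigned, , drop = FALSE], iv)
    if (!nrow(hits)) next
    # tie-break among genes in the same tier: nearest TSS to the SV midpoint
    sv_idx <- unassigned[hits$query]
    mid <- (svs$start[sv_idx] + svs$end[sv_idx]) / 2
    tss <- g$tss[match(iv$gene_id[hits$subject], g$gene_id)]
    hits$dist <- abs(mid - tss)
    hits <- hits[order(hits$query, hits$dist), ]
    hits <- hits[!duplicated(hits$query), ]
    sel <- unassigned[hits$query]
    cat[sel] <- tier
    gene_hit[sel] <- iv$gene_id[hits$subject]
    unassigned <- setdiff(unassigned, sel)
  }
  svs$category <- factor(cat, levels = c("exon", "intron", "upstream",
                                         "downstream", "intergenic"))
  svs$gene_id <- gene_hit
  svs
}
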