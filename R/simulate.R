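# Synthetic two-accession multi-omics generator with planted ground
# truth.
#
# Emulates a wild ("wild") vs cultivar ("cultivar") comparison on one
# shared reference frame: planted SVs whose co-location with differential
# TADs follows p_link; window-level methylomes with planted DMRs and with
# deletion-carried acquired methylation (AMRs: the deleted sequence is
# methylated in the wild accession and absent from the cultivar);
# condition-specific TAD calls; PC1 tracks consistent with gene density;
# replicate expression with methylation-linked suppression; and m6A/m5C
# site tables with expression-linked fractions. Methylation is simulated
# at the window level (binomial counts distributed over synthetic
# cytosine positions), not per read.

#' Default configuration for the synthetic multi-omics generator
#'
#' Desk-scale defaults: 2 chromosomes x 10 Mb, 1,000 genes, 500 SVs,
#' TADs of ~100 kb on a 20-kb grid. `p_link = 0.866` emulates the
#' observed co-location of SVs with differential-TAD regions. Pooled
#' window coverage is ~90 per context (3 sites/window x 3 replicates x
#' ~10 reads/site), a desk-scale stand-in for deep replicated bisulfite
#' coverage.
#'
#' @param ... Named overrides of any default field.
#' @return A `synth_config` list.
#' @export
synth_config <- function(...) {
  cfg <- list(
    seed = 1L,
    conditions = c("wild", "cultivar"),
    chrom_names = c("chr1", "chr2"),
    chrom_lengths = c(1e7, 1e7),
    # genes
    n_genes = 1000,
    gene_mean_len = 3000,
    # SVs
    n_svs = 500,
    sv_type_probs = c(INS = 0.48, DEL = 0.505, INV = 0.015),
    sv_len_meanlog = log(800),
    sv_len_sdlog = 0.7,
    inv_len_range = c(5e4, 5e5),
    p_link = 0.866,
    # TADs
    tad_bin = 2e4,
    tad_mean_bins = 5,
    diff_frac = 0.4,
    stage = "10DPA",
    # methylome
    dmr_window = 1000,
    sites_per_window = 3,          # per context
    site_coverage_mean = 10,
    n_reps_meth = 3,
    meth_baseline = c(CG = 0.65, CHG = 0.45, CHH = 0.08),
    meth_block_frac = 0.3,         # fraction of genome in methylated blocks
    meth_block_level = c(CG = 0.85, CHG = 0.65, CHH = 0.25),
    meth_open_level = c(CG = 0.08, CHG = 0.05, CHH = 0.03),
    n_dmr_random = c(CG = 100, CHG = 80, CHH = 80),
    dmr_delta = 0.4,
    # cascade plants
    n_dmg_genes = 80,              # promoter hyper-DMR only
    n_indel_dmg_genes = 80,        # promoter hyper-DMR + body InDel
    n_amg_genes = 60,              # promoter deletion carrying methylation
    amr_del_len = 600,
    amr_freqc = 0.8,
    dmg_lfc = -1.2,
    indel_dmg_lfc = -2.2,
    amg_lfc = 2.2,
    # expression
    n_reps_expr = 3,
    expr_mean_log2 = 4,
    expr_sd_log2 = 1.5,
    frac_not_expressed = 0.08,
    rep_sd_log2 = 0.25,
    bg_lfc_sd = 0.35,
    bg_deg_rate = 0.05,
    bg_deg_lfc = 1.8,
    # compartments
    pc1_bin = 4e4,
    pc1_noise_sd = 0.3,
    n_switch_segments = 4,
    switch_len_bins = c(2, 4),
    # RNA modifications
    m6a_rate = 1.2,
    m5c_rate = 2.8,
    frac_beta = c(2, 2),
    dml_frac = 0.2,
    dml_delta = 0.3,
    mod_coverage_mean = 30,
    mod_expr_link = 0.8
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (length(cfg$chrom_names) != length(cfg$chrom_lengths)) {
    stop("chrom_names and chrom_lengths lengths differ")
  }
  if (cfg$p_link < 0 || cfg$p_link > 1) stop("p_link must be in [0, 1]")
  if (any(unlist(cfg[c("n_genes", "n_svs")]) < 0)) stop("counts must be >= 0")
  n_windows <- sum(floor(cfg$chrom_lengths / cfg$dmr_window))
  n_planted <- sum(cfg$n_dmr_random) + cfg$n_dmg_genes +
    cfg$n_indel_dmg_genes
  if (n_planted > n_windows) {
    stop("infeasible config: more planted DMRs (", n_planted,
         ") than windows (", n_windows, ")")
  }
  n_designated <- cfg$n_dmg_genes + cfg$n_indel_dmg_genes + cfg$n_amg_genes
  if (n_designated > cfg$n_genes) {
    stop("infeasible config: more designated effect genes than genes")
  }
  invisible(cfg)
}

# round positions down to a grid
snap <- function(x, grid) floor(x / grid) * grid

#' Generate a synthetic multi-omics bundle
#'
#' Writes the full bundle to `outdir` and returns the planted truth plus
#' the in-memory objects. All randomness flows from `config$seed`; the
#' same configuration yields a byte-identical bundle.
#'
#' Files written: `layout.tsv`, `genes.gff3`, `svs.tsv` (truth-merged
#' set), `svs_callset1.tsv`/`svs_callset2.tsv` (jittered duplicates for
#' exercising the merger), `cytosine_<cond>_rep<i>.txt.gz`,
#' `tads_<cond>.bed`, `pc1_<cond>.bedGraph`, `expression.tsv`,
#' `samples.tsv`, `rnamod_<cond>.tsv`, `truth.json`.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, a list with `dir`, `paths`, `truth`, `layout`,
#'   `genes`, `svs`, `tads`, `diff_regions`.
#' @export
simulate_multiomics <- function(config = synth_config(), outdir) {
  cfg <- validate_synth_config(config)
  set.seed(cfg$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  layout <- genome_layout(cfg$chrom_names, cfg$chrom_lengths)

  ## ---- genes -------------------------------------------------------
  n_per_chrom <- round(cfg$n_genes * layout$length / sum(layout$length))
  n_per_chrom[length(n_per_chrom)] <- cfg$n_genes - sum(n_per_chrom[-length(n_per_chrom)])
  # gene-dense arms, gene-poor interior: the density gradient that makes
  # A/B compartment orientation (and its gene-density correlate) realistic
  genes <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    n <- n_per_chrom[i]
    L <- layout$length[i]
    nb <- ceiling(L / cfg$pc1_bin)
    relpos <- (seq_len(nb) - 0.5) / nb
    w <- ifelse(relpos < 0.35 | relpos > 0.65, 3, 0.4)
    n_cand <- round(n * 1.4)
    len <- pmax(500, round(stats::rexp(n_cand, 1 / cfg$gene_mean_len)))
    bin_pick <- sample.int(nb, n_cand, replace = TRUE, prob = w)
    start <- (bin_pick - 1) * cfg$pc1_bin +
      floor(stats::runif(n_cand) * cfg$pc1_bin)
    ord <- order(start)
    start <- start[ord]; len <- len[ord]
    keep_start <- numeric(0); keep_len <- numeric(0)
    last_end <- 2500   # leave promoter room before the first gene
    for (j in seq_len(n_cand)) {
      if (start[j] >= last_end + 500 && start[j] + len[j] <= L - 100) {
        keep_start <- c(keep_start, start[j])
        keep_len <- c(keep_len, len[j])
        last_end <- start[j] + len[j]
        if (length(keep_start) == n) break
      }
    }
    data.frame(chrom = layout$chrom[i], start = keep_start,
               end = keep_start + keep_len,
               strand = sample(c("+", "-"), length(keep_start),
                               replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[genes$end - genes$start >= 200, , drop = FALSE]
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  # two exons per gene, split around a central intron
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    len <- g$end - g$start
    if (len < 600) {
      return(data.frame(gene_id = g$gene_id, chrom = g$chrom,
                        start = g$start, end = g$end))
    }
    e1 <- round(len * 0.4)
    i1 <- round(len * 0.2)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = c(g$start, g$start + e1 + i1),
               end = c(g$start + e1, g$end))
  }))
  gene_models <- list(genes = genes[, c("gene_id", "chrom", "start", "end",
                                        "strand", "tss")],
                      exons = exons)

  ## ---- TADs and differential regions -------------------------------
  make_domains <- function() {
    do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
      n_bins <- floor(layout$length[i] / cfg$tad_bin)
      sizes <- pmax(2, stats::rgeom(2 * n_bins, 1 / cfg$tad_mean_bins) + 1)
      sizes <- sizes[cumsum(sizes) <= n_bins]
      if (sum(sizes) < n_bins) sizes <- c(sizes, n_bins - sum(sizes))
      bp <- c(0, cumsum(sizes)) * cfg$tad_bin
      data.frame(chrom = layout$chrom[i], start = bp[-length(bp)],
                 end = bp[-1], stringsAsFactors = FALSE)
    }))
  }
  tadsA <- make_domains()
  eligible <- (tadsA$end - tadsA$start) >= 4 * cfg$tad_bin
  tadsA$differential <- eligible & stats::runif(nrow(tadsA)) < cfg$diff_frac
  diff_regions <- merge_intervals(tadsA[tadsA$differential, , drop = FALSE])
  # condition B: conserved domains copied; each differential run
  # re-partitioned with interior breakpoints shifted by two bins
  tadsB <- list()
  for (ch in unique(tadsA$chrom)) {
    x <- tadsA[tadsA$chrom == ch, ]
    r <- rle(x$differential)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      run <- x[starts[j]:ends[j], , drop = FALSE]
      if (!r$values[j]) {
        tadsB[[length(tadsB) + 1]] <- run[, c("chrom", "start", "end")]
      } else {
        span <- c(run$start[1], run$end[nrow(run)])
        inner <- run$start[-1]
        bp <- unique(c(span[1],
                       pmin(inner + 2 * cfg$tad_bin, span[2] - cfg$tad_bin),
                       if (nrow(run) == 1)
                         span[1] + 2 * cfg$tad_bin else NULL,
                       span[2]))
        bp <- sort(bp)
        tadsB[[length(tadsB) + 1]] <- data.frame(
          chrom = ch, start = bp[-length(bp)], end = bp[-1])
      }
    }
  }
  tadsB <- do.call(rbind, tadsB)
  tadsA$name <- sprintf("%s_%s_A_%d", tadsA$chrom, cfg$stage,
                        seq_len(nrow(tadsA)))
  tadsB$name <- sprintf("%s_%s_B_%d", tadsB$chrom, cfg$stage,
                        seq_len(nrow(tadsB)))

  in_regions <- function(pos, chrom, regions) {
    if (!nrow(regions)) return(rep(FALSE, length(pos)))
    hit <- overlaps_any_idx(data.frame(chrom = chrom, start = pos,
                                       end = pos + 1), regions)
    out <- rep(FALSE, length(pos)); out[hit] <- TRUE
    out
  }

  ## ---- designated effect genes -------------------------------------
  gmid <- (genes$start + genes$end) / 2
  g_in_diff <- in_regions(gmid, genes$chrom, diff_regions)
  n_designated <- cfg$n_dmg_genes + cfg$n_indel_dmg_genes + cfg$n_amg_genes
  # sample designated genes so their (promoter) SVs follow the p_link rule
  n_sv_genes <- cfg$n_indel_dmg_genes + cfg$n_amg_genes
  linked <- stats::runif(n_sv_genes) < cfg$p_link
  pool_diff <- which(g_in_diff & genes$start > 3000)
  pool_cons <- which(!g_in_diff & genes$start > 3000)
  take <- function(pool, n) {
    if (length(pool) < n) stop("not enough genes to designate effects")
    pool[sample.int(length(pool), n)]
  }
  sv_gene_idx <- integer(n_sv_genes)
  idx_d <- take(pool_diff, sum(linked))
  idx_c <- take(pool_cons, sum(!linked))
  sv_gene_idx[linked] <- idx_d
  sv_gene_idx[!linked] <- idx_c
  indel_dmg_idx <- sv_gene_idx[seq_len(cfg$n_indel_dmg_genes)]
  amg_idx <- sv_gene_idx[cfg$n_indel_dmg_genes + seq_len(cfg$n_amg_genes)]
  remaining <- setdiff(seq_len(nrow(genes)), sv_gene_idx)
  dmg_idx <- take(remaining, cfg$n_dmg_genes)

  # promoter anchor: a point ~500 bp upstream of the TSS, strand-aware
  prom_point <- function(idx, offset = 500) {
    ifelse(genes$strand[idx] == "+", genes$tss[idx] - offset,
           genes$tss[idx] + offset)
  }

  ## ---- SVs ----------------------------------------------------------
  svs <- list()
  # InDel-DMG genes: insertion anchored mid-body
  body_pos <- round((genes$start[indel_dmg_idx] + genes$end[indel_dmg_idx]) / 2)
  svs$indel_dmg <- data.frame(
    chrom = genes$chrom[indel_dmg_idx], start = body_pos,
    end = body_pos + 1, type = "INS",
    length = round(stats::rlnorm(length(body_pos), cfg$sv_len_meanlog,
                                 cfg$sv_len_sdlog)))
  # InDel-AMG genes: promoter deletion (grid-aligned) carrying methylation
  amr_start <- snap(prom_point(amg_idx, offset = 500 + cfg$amr_del_len / 2),
                    100)
  amr_start <- pmax(0, amr_start)
  svs$amg <- data.frame(
    chrom = genes$chrom[amg_idx], start = amr_start,
    end = amr_start + cfg$amr_del_len, type = "DEL",
    length = cfg$amr_del_len)
  # random SVs following the p_link rule
  n_rand <- max(0, cfg$n_svs - nrow(svs$indel_dmg) - nrow(svs$amg))
  type <- sample(names(cfg$sv_type_probs), n_rand, replace = TRUE,
                 prob = cfg$sv_type_probs)
  len <- round(stats::rlnorm(n_rand, cfg$sv_len_meanlog, cfg$sv_len_sdlog))
  len[type == "INV"] <- round(stats::runif(sum(type == "INV"),
                                           cfg$inv_len_range[1],
                                           cfg$inv_len_range[2]))
  rand_linked <- stats::runif(n_rand) < cfg$p_link
  sample_point_in <- function(regions, n) {
    if (!nrow(regions) || n == 0) {
      return(data.frame(chrom = character(0), pos = numeric(0)))
    }
    w <- regions$end - regions$start
    pick <- sample.int(nrow(regions), n, replace = TRUE, prob = w)
    data.frame(chrom = regions$chrom[pick],
               pos = floor(regions$start[pick] + stats::runif(n) * w[pick]),
               stringsAsFactors = FALSE)
  }
  comp_regions <- local({
    g <- as_granges(data.frame(chrom = layout$chrom, start = 0,
                               end = layout$length))
    d <- if (nrow(diff_regions)) as_granges(diff_regions) else
      GenomicRanges::GRanges()
    from_granges(GenomicRanges::setdiff(g, d))
  })
  pt_chrom <- character(n_rand)
  pt_pos <- numeric(n_rand)
  pd <- sample_point_in(diff_regions, sum(rand_linked))
  pc <- sample_point_in(comp_regions, sum(!rand_linked))
  pt_chrom[rand_linked] <- pd$chrom; pt_pos[rand_linked] <- pd$pos
  pt_chrom[!rand_linked] <- pc$chrom; pt_pos[!rand_linked] <- pc$pos
  # DEL/INV intervals are centred on the drawn point so the placed
  # midpoint respects the p_link rule
  start <- ifelse(type == "INS", pt_pos, pt_pos - floor(len / 2))
  start <- pmax(0, pmin(start, chrom_length(layout, pt_chrom) -
                          ifelse(type == "INS", 1, len)))
  svs$random <- data.frame(
    chrom = pt_chrom, start = start,
    end = ifelse(type == "INS", start + 1, start + len),
    type = type, length = len, stringsAsFactors = FALSE)
  sv_all <- rbind(cbind(svs$indel_dmg, role = "indel_dmg",
                        gene = genes$gene_id[indel_dmg_idx],
                        linked_draw = linked[seq_len(cfg$n_indel_dmg_genes)]),
                  cbind(svs$amg, role = "amr_carrier",
                        gene = genes$gene_id[amg_idx],
                        linked_draw = linked[cfg$n_indel_dmg_genes +
                                               seq_len(cfg$n_amg_genes)]),
                  cbind(svs$random, role = "random", gene = NA_character_,
                        linked_draw = rand_linked))
  sv_all <- sv_all[order(sv_all$chrom, sv_all$start), , drop = FALSE]
  sv_all$id <- sprintf("SV%04d", seq_len(nrow(sv_all)))
  sv_all$source <- "truth"
  rownames(sv_all) <- NULL
  svs_out <- sv_all[, c("id", "chrom", "start", "end", "type", "length",
                        "source")]
  del_regions <- merge_intervals(svs_out[svs_out$type == "DEL", ])
  amr_carriers <- sv_all[sv_all$role == "amr_carrier", , drop = FALSE]

  ## ---- planted DMRs -------------------------------------------------
  windows <- tile_windows(layout, cfg$dmr_window)
  win_in_del <- rep(FALSE, nrow(windows))
  win_in_del[overlaps_any_idx(windows, del_regions)] <- TRUE
  # promoter windows of designated DMG / InDel-DMG genes (CG, hyper in B)
  prom_idx <- c(dmg_idx, indel_dmg_idx)
  prom_win <- snap(pmax(0, prom_point(prom_idx)), cfg$dmr_window)
  prom_win <- pmin(prom_win,
                   chrom_length(layout, genes$chrom[prom_idx]) - cfg$dmr_window)
  prom_dmr <- data.frame(chrom = genes$chrom[prom_idx], start = prom_win,
                         end = prom_win + cfg$dmr_window, context = "CG",
                         delta = cfg$dmr_delta,
                         role = rep(c("dmg", "indel_dmg"),
                                    c(length(dmg_idx), length(indel_dmg_idx))),
                         gene = genes$gene_id[prom_idx],
                         stringsAsFactors = FALSE)
  # random DMRs per context, away from deletions and promoter plants
  taken <- paste(prom_dmr$chrom, prom_dmr$start)
  free <- which(!win_in_del &
                  !paste(windows$chrom, windows$start) %in% taken)
  rand_dmr <- do.call(rbind, lapply(names(cfg$n_dmr_random), function(ctx) {
    n <- cfg$n_dmr_random[[ctx]]
    pick <- free[sample.int(length(free), n)]
    free <<- setdiff(free, pick)
    data.frame(chrom = windows$chrom[pick], start = windows$start[pick],
               end = windows$end[pick], context = ctx,
               delta = cfg$dmr_delta *
                 (if (ctx == "CHH") 1 else sample(c(-1, 1), n, replace = TRUE)),
               role = "random", gene = NA_character_,
               stringsAsFactors = FALSE)
  }))
  planted_dmrs <- rbind(prom_dmr, rand_dmr)

  ## ---- methylome emission -------------------------------------------
  contexts <- names(cfg$meth_baseline)
  # block structure: methylated vs open chromatin, shared across contexts
  n_win <- nrow(windows)
  block <- stats::runif(n_win) < cfg$meth_block_frac
  base_p <- sapply(contexts, function(ctx) {
    p <- ifelse(block, cfg$meth_block_level[[ctx]],
                cfg$meth_open_level[[ctx]])
    pmin(0.98, pmax(0.02, p + stats::rnorm(n_win, 0, 0.03)))
  })
  colnames(base_p) <- contexts
  pA <- base_p
  pB <- base_p
  key <- paste(windows$chrom, windows$start)
  planted_dmrs$freqA <- NA_real_
  for (k in seq_len(nrow(planted_dmrs))) {
    wi <- match(paste(planted_dmrs$chrom[k], planted_dmrs$start[k]), key)
    ctx <- planted_dmrs$context[k]
    d <- planted_dmrs$delta[k]
    base <- if (d > 0) stats::runif(1, 0.1, 0.5) else stats::runif(1, 0.5, 0.9)
    base <- min(0.98 - max(0, d), max(0.02 - min(0, d), base))
    pA[wi, ctx] <- base
    pB[wi, ctx] <- base + d
    planted_dmrs$freqA[k] <- base
  }

  # site positions: sites_per_window per context, fixed across reps and
  # conditions; extra dense CG sites inside AMR-carrier deletions
  site_list <- lapply(contexts, function(ctx) {
    off <- round(seq(50, cfg$dmr_window - 50,
                     length.out = cfg$sites_per_window) +
                   match(ctx, contexts) * 7)
    data.frame(chrom = rep(windows$chrom, each = length(off)),
               pos = rep(windows$start, each = length(off)) +
                 rep(off, times = n_win),
               context = ctx,
               win = rep(seq_len(n_win), each = length(off)),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  sites$pA <- pA[cbind(sites$win, match(sites$context, contexts))]
  sites$pB <- pB[cbind(sites$win, match(sites$context, contexts))]
  # AMR sites: one CG site per 100-bp tile of each carrier deletion,
  # highly methylated in the wild (A) accession; absent in cultivar
  if (nrow(amr_carriers)) {
    amr_sites <- do.call(rbind, lapply(seq_len(nrow(amr_carriers)),
                                       function(i) {
      s <- amr_carriers[i, ]
      pos <- seq(s$start + 50, s$end - 50, by = 100)
      data.frame(chrom = s$chrom, pos = pos, context = "CG",
                 win = NA_integer_, pA = cfg$amr_freqc, pB = NA_real_,
                 stringsAsFactors = FALSE)
    }))
    sites <- rbind(sites, amr_sites)
  }
  sites <- sites[sites$pos < chrom_length(layout, sites$chrom), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  # cultivar (B) has no reads inside deleted sequence
  site_in_del <- rep(FALSE, nrow(sites))
  site_in_del[overlaps_any_idx(
    data.frame(chrom = sites$chrom, start = sites$pos,
               end = sites$pos + 1), del_regions)] <- TRUE

  conds <- cfg$conditions
  meth_paths <- c()
  for (ci in c(1, 2)) {
    p <- if (ci == 1) sites$pA else sites$pB
    keep <- if (ci == 1) rep(TRUE, nrow(sites)) else !site_in_del
    for (rep_i in seq_len(cfg$n_reps_meth)) {
      cov <- stats::rpois(nrow(sites), cfg$site_coverage_mean)
      meth <- stats::rbinom(nrow(sites), cov, ifelse(is.na(p), 0, p))
      rows <- keep & cov > 0
      rpt <- data.frame(chrom = sites$chrom[rows],
                        pos = sites$pos[rows],
                        strand = "+",
                        meth = meth[rows],
                        unmeth = cov[rows] - meth[rows],
                        context = sites$context[rows],
                        tri = "NNN")
      path <- file.path(outdir, sprintf("cytosine_%s_rep%d.txt.gz",
                                        conds[ci], rep_i))
      write_cytosine_report(rpt, path)
      meth_paths <- c(meth_paths, path)
    }
  }

  ## ---- PC1 tracks ---------------------------------------------------
  bins <- tile_windows(layout, cfg$pc1_bin)
  gd <- count_overlaps_in(bins, genes)
  # compartment signal: smoothed gene density (megabase-scale structure),
  # so PC1 has the spatial autocorrelation of real eigenvector tracks
  smooth_by_chrom <- function(v, chrom, k = 11) {
    out <- v
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      x <- v[sel]
      sm <- stats::filter(x, rep(1 / k, k), sides = 2)
      sm[is.na(sm)] <- mean(x)
      out[sel] <- as.numeric(sm)
    }
    out
  }
  gd_smooth <- smooth_by_chrom(gd, bins$chrom)
  pc1_raw <- as.numeric(scale(gd_smooth)) +
    stats::rnorm(nrow(bins), 0, cfg$pc1_noise_sd)
  pc1_raw[pc1_raw == 0] <- 1e-6
  flipA <- sample(c(1, -1), nrow(layout), replace = TRUE)
  flipB <- sample(c(1, -1), nrow(layout), replace = TRUE)
  chri <- match(bins$chrom, layout$chrom)
  pc1A <- data.frame(bins[, c("chrom", "start", "end")],
                     value = pc1_raw * flipA[chri])
  valB <- pc1_raw
  # planted switch segments: invert the underlying state for short runs
  switches <- list()
  eligible_bins <- which(abs(pc1_raw) > 0.2)
  attempts <- 0
  while (length(switches) < cfg$n_switch_segments && attempts < 200) {
    attempts <- attempts + 1
    lens <- seq(cfg$switch_len_bins[1], cfg$switch_len_bins[2])
    n_b <- lens[sample.int(length(lens), 1)]
    cand <- eligible_bins[eligible_bins <= nrow(bins) - n_b]
    if (!length(cand)) break
    anchor <- cand[sample.int(length(cand), 1)]
    run <- anchor:(anchor + n_b - 1)
    if (length(unique(bins$chrom[run])) > 1 ||
        !all(sign(pc1_raw[run]) == sign(pc1_raw[anchor])) ||
        any(abs(pc1_raw[run]) <= 0.05)) next
    valB[run] <- -abs(pc1_raw[run]) * sign(pc1_raw[anchor])
    switches[[length(switches) + 1]] <- data.frame(
      chrom = bins$chrom[anchor], start = bins$start[run[1]],
      end = bins$end[run[length(run)]], n_bins = n_b,
      from = ifelse(sign(pc1_raw[anchor]) > 0, "A", "B"),
      to = ifelse(sign(pc1_raw[anchor]) > 0, "B", "A"))
    eligible_bins <- setdiff(eligible_bins, (anchor - 5):(anchor + n_b + 4))
  }
  pc1B <- data.frame(bins[, c("chrom", "start", "end")],
                     value = valB * flipB[chri])
  planted_switches <- if (length(switches)) do.call(rbind, switches) else
    data.frame()

  ## ---- RNA modifications --------------------------------------------
  tx_len <- genes$end - genes$start
  mod_sites <- function(rate) {
    n <- stats::rpois(nrow(genes), rate)
    idx <- rep(seq_len(nrow(genes)), n)
    data.frame(transcript = genes$gene_id[idx],
               position = floor(stats::runif(length(idx)) * tx_len[idx]) + 1,
               stringsAsFactors = FALSE)
  }
  rna <- rbind(cbind(mod_sites(cfg$m6a_rate), type = "m6A"),
               cbind(mod_sites(cfg$m5c_rate), type = "m5C"))
  rna <- rna[!duplicated(rna[, c("transcript", "position", "type")]), ]
  rna <- rna[order(rna$type, rna$transcript, rna$position), ]
  fracA <- stats::rbeta(nrow(rna), cfg$frac_beta[1], cfg$frac_beta[2])
  is_dml <- stats::runif(nrow(rna)) < cfg$dml_frac
  shift <- ifelse(fracA < 0.5, cfg$dml_delta, -cfg$dml_delta)
  fracB <- ifelse(is_dml, pmin(0.98, pmax(0.02, fracA + shift)), fracA)
  emit_rna <- function(frac, path) {
    cov <- stats::rpois(nrow(rna), cfg$mod_coverage_mean) + 10
    m <- stats::rbinom(nrow(rna), cov, frac)
    out <- data.frame(transcript = rna$transcript, position = rna$position,
                      type = rna$type, modified = m, coverage = cov,
                      fraction = m / cov)
    write_rnamod_table(out, path)
    out
  }
  rnaA <- emit_rna(fracA, file.path(outdir, sprintf("rnamod_%s.tsv", conds[1])))
  rnaB <- emit_rna(fracB, file.path(outdir, sprintf("rnamod_%s.tsv", conds[2])))
  max_frac <- function(tab, ty) {
    mf <- tapply(tab$fraction[tab$type == ty], tab$transcript[tab$type == ty],
                 max)
    out <- rep(0, nrow(genes)); names(out) <- genes$gene_id
    out[names(mf)] <- mf
    out
  }
  mod_mult <- exp(cfg$mod_expr_link *
                    (max_frac(rnaA, "m6A") + max_frac(rnaA, "m5C")))

  ## ---- expression ----------------------------------------------------
  base_log2 <- stats::rnorm(nrow(genes), cfg$expr_mean_log2, cfg$expr_sd_log2)
  designated <- c(dmg_idx, indel_dmg_idx, amg_idx)
  base_log2[designated] <- pmax(base_log2[designated], 3)
  silent_pool <- setdiff(seq_len(nrow(genes)), designated)
  silent <- sample(silent_pool, round(cfg$frac_not_expressed * nrow(genes)))
  base_tpm <- 2^base_log2 * mod_mult
  base_tpm[silent] <- 0
  lfc <- stats::rnorm(nrow(genes), 0, cfg$bg_lfc_sd)
  bg_deg <- sample(setdiff(silent_pool, silent),
                   round(cfg$bg_deg_rate * nrow(genes)))
  lfc[bg_deg] <- lfc[bg_deg] +
    sample(c(-1, 1), length(bg_deg), replace = TRUE) * cfg$bg_deg_lfc
  lfc[dmg_idx] <- lfc[dmg_idx] + cfg$dmg_lfc
  lfc[indel_dmg_idx] <- lfc[indel_dmg_idx] + cfg$indel_dmg_lfc
  lfc[amg_idx] <- lfc[amg_idx] + cfg$amg_lfc
  meanA <- base_tpm
  meanB <- base_tpm * 2^lfc
  n_rep <- cfg$n_reps_expr
  rep_mat <- function(mu) {
    m <- sapply(seq_len(n_rep), function(r) {
      round(mu * 2^stats::rnorm(length(mu), 0, cfg$rep_sd_log2), 3)
    })
    m
  }
  tpm <- cbind(rep_mat(meanA), rep_mat(meanB))
  colnames(tpm) <- c(sprintf("%s_rep%d", conds[1], seq_len(n_rep)),
                     sprintf("%s_rep%d", conds[2], seq_len(n_rep)))
  rownames(tpm) <- genes$gene_id
  samples <- data.frame(sample = colnames(tpm),
                        accession = rep(conds, each = n_rep),
                        tissue = "fiber", replicate = rep(seq_len(n_rep), 2))

  ## ---- write remaining files ---------------------------------------
  paths <- list(
    layout = file.path(outdir, "layout.tsv"),
    genes = file.path(outdir, "genes.gff3"),
    svs = file.path(outdir, "svs.tsv"),
    callset1 = file.path(outdir, "svs_callset1.tsv"),
    callset2 = file.path(outdir, "svs_callset2.tsv"),
    tadsA = file.path(outdir, sprintf("tads_%s.bed", conds[1])),
    tadsB = file.path(outdir, sprintf("tads_%s.bed", conds[2])),
    pc1A = file.path(outdir, sprintf("pc1_%s.bedGraph", conds[1])),
    pc1B = file.path(outdir, sprintf("pc1_%s.bedGraph", conds[2])),
    expression = file.path(outdir, "expression.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    rnamodA = file.path(outdir, sprintf("rnamod_%s.tsv", conds[1])),
    rnamodB = file.path(outdir, sprintf("rnamod_%s.tsv", conds[2])),
    truth = file.path(outdir, "truth.json"))
  data.table::fwrite(layout, paths$layout, sep = "\t", quote = FALSE)
  write_gff3_genes(gene_models, paths$genes)
  write_sv_table(svs_out, paths$svs)
  write_sv_table(svs_out, paths$callset1)
  jitter <- svs_out
  shift2 <- sample(-50:50, nrow(jitter), replace = TRUE)
  jitter$start <- pmax(0, jitter$start + shift2)
  jitter$end <- ifelse(jitter$type == "INS", jitter$start + 1,
                       jitter$start + jitter$length)
  jitter$id <- paste0(jitter$id, "b")
  jitter$source <- "caller2"
  write_sv_table(jitter, paths$callset2)
  write_intervals(tadsA[, c("chrom", "start", "end", "name")], paths$tadsA,
                  "domainBED")
  write_intervals(tadsB[, c("chrom", "start", "end", "name")], paths$tadsB,
                  "domainBED")
  write_intervals(pc1A, paths$pc1A, "bedGraph")
  write_intervals(pc1B, paths$pc1B, "bedGraph")
  write_expression_table(tpm, paths$expression)
  data.table::fwrite(samples, paths$samples, sep = "\t", quote = FALSE)

  truth <- list(
    config = unclass(cfg),
    planted_dmrs = planted_dmrs,
    amr_carriers = data.frame(
      sv_id = amr_carriers$id, gene = amr_carriers$gene,
      chrom = amr_carriers$chrom, start = amr_carriers$start,
      end = amr_carriers$end),
    differential_regions = diff_regions,
    sv_links = data.frame(sv_id = svs_out$id,
                          linked_draw = sv_all$linked_draw,
                          in_differential = in_regions(
                            floor((svs_out$start + svs_out$end) / 2),
                            svs_out$chrom, diff_regions)),
    effect_genes = data.frame(
      gene_id = genes$gene_id[c(dmg_idx, indel_dmg_idx, amg_idx)],
      role = rep(c("dmg", "indel_dmg", "amg"),
                 c(length(dmg_idx), length(indel_dmg_idx), length(amg_idx))),
      planted_lfc = c(rep(cfg$dmg_lfc, length(dmg_idx)),
                      rep(cfg$indel_dmg_lfc, length(indel_dmg_idx)),
                      rep(cfg$amg_lfc, length(amg_idx)))),
    planted_switches = planted_switches,
    planted_dmls = data.frame(transcript = rna$transcript[is_dml],
                              position = rna$position[is_dml],
                              type = rna$type[is_dml]))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")

  invisible(list(dir = outdir, paths = paths, truth = truth,
                 layout = layout, genes = gene_models, svs = svs_out,
                 tads = list(A = tadsA, B = tadsB),
                 diff_regions = diff_regions))
}
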