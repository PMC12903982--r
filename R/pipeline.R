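# Pipeline orchestration: runs the cascade stages over a bundle of input
# files and emits per-stage TSVs plus a summary report (Markdown + JSON).
# Every number in the summary is recomputable from the emitted per-stage
# tables.

#' Default pipeline configuration
#'
#' @param inputs Named list of input paths: `layout`, `genes`, `svs`,
#'   `tads_a`, `tads_b`, `pc1_a`, `pc1_b`, `expression`, `samples`,
#'   `rnamod_a`, `rnamod_b`, `cytosine_a` (character vector of replicate
#'   reports), `cytosine_b`. A bundle directory from
#'   [simulate_multiomics()] can be turned into this list with
#'   [bundle_inputs()].
#' @param ... Parameter overrides (see defaults in the returned list).
#' @return A `run_config` list.
#' @export
run_config <- function(inputs = list(), ...) {
  cfg <- list(
    inputs = inputs,
    seed = 1L,
    min_coverage = 5,
    dmr_window = 1000,
    amr_window = 100,
    freqc_min = 0.2,
    overlap_min = 0.9,
    amr_carrier = "A",
    tad_tolerance = 20000,
    boundary_width = 20000,
    genome_window = 1e7,
    sv_flank = 1000,
    footprint_flank = 2000,
    min_tpm = 1.0,
    deg_min_lfc = 1.0,
    deg_max_q = 0.05,
    dml_min_delta = 0.20,
    dml_max_q = 0.05,
    stages = c("dmr", "amr", "tads", "compartments", "annotate", "degs",
               "cascade"))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown run_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with `inputs` and optional parameter overrides.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  inputs <- y$inputs
  y$inputs <- NULL
  do.call(run_config, c(list(inputs = inputs), y))
}

#' Input list for a synthetic bundle directory
#' @param dir Directory written by [simulate_multiomics()].
#' @param conditions The two accession names (order = A, B).
#' @return Named list of paths suitable for [run_config()].
#' @export
bundle_inputs <- function(dir, conditions = c("wild", "cultivar")) {
  f <- function(...) file.path(dir, sprintf(...))
  list(layout = f("layout.tsv"), genes = f("genes.gff3"), svs = f("svs.tsv"),
       tads_a = f("tads_%s.bed", conditions[1]),
       tads_b = f("tads_%s.bed", conditions[2]),
       pc1_a = f("pc1_%s.bedGraph", conditions[1]),
       pc1_b = f("pc1_%s.bedGraph", conditions[2]),
       expression = f("expression.tsv"), samples = f("samples.tsv"),
       rnamod_a = f("rnamod_%s.tsv", conditions[1]),
       rnamod_b = f("rnamod_%s.tsv", conditions[2]),
       cytosine_a = Sys.glob(f("cytosine_%s_rep*.txt.gz", conditions[1])),
       cytosine_b = Sys.glob(f("cytosine_%s_rep*.txt.gz", conditions[2])))
}

check_inputs <- function(cfg, needed, stage) {
  for (k in needed) {
    p <- cfg$inputs[[k]]
    if (is.null(p) || !all(file.exists(p))) {
      stop(sprintf("stage '%s': missing input '%s' (%s)", stage, k,
                   paste(if (is.null(p)) "unset" else p, collapse = ", ")))
    }
  }
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full cascade pipeline
#'
#' Executes the enabled stages over the configured inputs and writes
#' per-stage TSVs plus `report.md` and `report.json` to `outdir`.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, a list with all stage results and the `summary`
#'   list that the report serialises.
#' @export
run_pipeline <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  summary <- list()
  check_inputs(cfg, c("layout", "genes", "svs"), "setup")
  layout_df <- data.table::fread(cfg$inputs$layout, data.table = FALSE)
  layout <- genome_layout(layout_df$chrom, layout_df$length)
  genes <- read_gff3_genes(cfg$inputs$genes, layout)
  svs <- read_sv_table(cfg$inputs$svs, layout)
  stage_log("setup", "%d chromosomes, %d genes, %d SVs",
            nrow(layout), nrow(genes$genes), nrow(svs))
  summary$sv_counts <- as.list(table(svs$type))

  read_meth <- function(paths) {
    lapply(paths, read_cytosine_report, min_coverage = cfg$min_coverage)
  }
  callsA <- NULL; callsB <- NULL
  if (any(c("dmr", "amr") %in% cfg$stages)) {
    check_inputs(cfg, c("cytosine_a", "cytosine_b"), "dmr/amr")
    callsA <- read_meth(cfg$inputs$cytosine_a)
    callsB <- read_meth(cfg$inputs$cytosine_b)
  }

  ## ---- DMR stage ----------------------------------------------------
  if ("dmr" %in% cfg$stages) {
    windows <- tile_windows(layout, cfg$dmr_window)
    dmrs <- do.call(rbind, lapply(CONTEXTS, function(ctx) {
      wa <- pool_window_methylation(callsA, windows, ctx)
      wb <- pool_window_methylation(callsB, windows, ctx)
      call_dmrs(wa, wb, ctx)
    }))
    res$dmrs <- dmrs
    data.table::fwrite(dmrs, file.path(outdir, "dmrs.tsv"), sep = "\t")
    summary$dmr_counts <- lapply(split(dmrs$dmr, dmrs$context), sum)
    summary$windows_tested <- lapply(split(dmrs$dmr, dmrs$context), length)
    stage_log("dmr", "%d windows tested, %d DMRs",
              nrow(dmrs), sum(dmrs$dmr))
  }

  ## ---- AMR stage ----------------------------------------------------
  if ("amr" %in% cfg$stages) {
    win100 <- tile_windows(layout, cfg$amr_window)
    carrier_calls <- if (cfg$amr_carrier == "A") callsA else callsB
    w100 <- pool_window_methylation(carrier_calls, win100, "CG")
    indels <- svs[svs$type %in% c("INS", "DEL"), , drop = FALSE]
    amrs <- call_amrs(w100, indels, freqc_min = cfg$freqc_min,
                      overlap_min = cfg$overlap_min)
    res$amrs <- amrs
    data.table::fwrite(amrs, file.path(outdir, "amrs.tsv"), sep = "\t")
    summary$amr_count <- nrow(amrs)
    stage_log("amr", "%d InDel-AMR windows (carrier %s)", nrow(amrs),
              cfg$amr_carrier)
  }

  ## ---- TAD stage ----------------------------------------------------
  if ("tads" %in% cfg$stages) {
    check_inputs(cfg, c("tads_a", "tads_b"), "tads")
    tadsA <- read_intervals(cfg$inputs$tads_a, "domainBED", layout)
    tadsB <- read_intervals(cfg$inputs$tads_b, "domainBED", layout)
    mt <- match_tads(tadsA, tadsB, tolerance = cfg$tad_tolerance)
    enr <- sv_counts_per_tad(svs, mt$comparisons)
    frac <- fraction_svs_in_regions(svs, mt$differential_regions)
    bstats <- boundary_sv_window_stats(mt$comparisons, svs, layout,
                                       window = cfg$genome_window,
                                       boundary_width = cfg$boundary_width)
    res$tads <- list(match = mt, enrichment = enr, fraction = frac,
                     boundary = bstats)
    data.table::fwrite(enr$per_domain, file.path(outdir, "tad_comparison.tsv"),
                       sep = "\t")
    data.table::fwrite(bstats$per_window,
                       file.path(outdir, "boundary_windows.tsv"), sep = "\t")
    summary$tad_counts <- mt$counts
    summary$sv_enrichment <- enr$test
    summary$frac_svs_in_differential <- frac
    summary$mean_boundary_sv_proportion <- bstats$mean_proportion
    stage_log("tads", "conserved/differential A: %d/%d; SV fraction %.3f",
              mt$counts$conserved[1], mt$counts$differential[1], frac)
  }

  ## ---- compartments --------------------------------------------------
  if ("compartments" %in% cfg$stages) {
    check_inputs(cfg, c("pc1_a", "pc1_b"), "compartments")
    pc1A <- read_intervals(cfg$inputs$pc1_a, "bedGraph", layout)
    pc1B <- read_intervals(cfg$inputs$pc1_b, "bedGraph", layout)
    gd <- count_overlaps_in(pc1A, genes$genes)
    compA <- assign_compartments(pc1A, gd)
    compB <- assign_compartments(pc1B, gd)
    segs <- detect_switch_segments(compA, compB)
    res$compartments <- list(A = compA, B = compB, segments = segs)
    data.table::fwrite(segs, file.path(outdir, "compartment_segments.tsv"),
                       sep = "\t")
    summary$switch_counts <- as.list(table(segs$class))
    stage_log("compartments", "%d A2B, %d B2A segments",
              sum(segs$class == "A2B"), sum(segs$class == "B2A"))
  }

  ## ---- SV annotation -------------------------------------------------
  if ("annotate" %in% cfg$stages) {
    ann <- annotate_sv_context(svs, genes, flank = cfg$sv_flank)
    res$sv_annotation <- ann
    data.table::fwrite(ann, file.path(outdir, "sv_annotation.tsv"),
                       sep = "\t")
    summary$sv_context <- as.list(table(ann$category))
    stage_log("annotate", "%s",
              paste(names(table(ann$category)), table(ann$category),
                    collapse = ", "))
  }

  ## ---- DEGs ----------------------------------------------------------
  degs <- NULL
  if ("degs" %in% cfg$stages) {
    check_inputs(cfg, c("expression", "samples"), "degs")
    expr <- read_expression_table(cfg$inputs$expression, cfg$inputs$samples)
    acc <- unique(expr$samples$accession)
    if (length(acc) != 2) stop("expected exactly 2 accessions, got ",
                               length(acc))
    exprA <- expr$tpm[, expr$samples$sample[expr$samples$accession == acc[1]],
                      drop = FALSE]
    exprB <- expr$tpm[, expr$samples$sample[expr$samples$accession == acc[2]],
                      drop = FALSE]
    degs <- compute_degs(exprA, exprB, min_tpm = cfg$min_tpm,
                         min_lfc = cfg$deg_min_lfc, max_q = cfg$deg_max_q)
    res$degs <- degs
    data.table::fwrite(degs, file.path(outdir, "degs.tsv"), sep = "\t")
    summary$deg_counts <- as.list(table(degs$status))
    inv <- svs[svs$type == "INV", , drop = FALSE]
    if (nrow(inv)) {
      invp <- deg_proportion_in_regions(genes$genes, inv, degs)
      res$inversion_deg <- invp
      data.table::fwrite(invp, file.path(outdir, "inversion_deg.tsv"),
                         sep = "\t")
      summary$inversion_deg_percent <- invp$percent[1]
      summary$genome_deg_percent <- invp$percent[2]
    }
    # RNA modification comparison when tables are provided
    if (!is.null(cfg$inputs$rnamod_a) && !is.null(cfg$inputs$rnamod_b) &&
        all(file.exists(c(cfg$inputs$rnamod_a, cfg$inputs$rnamod_b)))) {
      rnaA <- read_rnamod_table(cfg$inputs$rnamod_a)
      rnaB <- read_rnamod_table(cfg$inputs$rnamod_b)
      dmls <- call_dmls(rnaA, rnaB, min_delta = cfg$dml_min_delta,
                        max_q = cfg$dml_max_q)
      res$dmls <- dmls
      data.table::fwrite(dmls, file.path(outdir, "dmls.tsv"), sep = "\t")
      summary$dml_counts <- lapply(split(dmls$dml, dmls$type), sum)
      tpm_mean <- rowMeans(expr$tpm)
      com <- co_modification_sets(
        unique(rnaA$transcript[rnaA$type == "m6A"]),
        unique(rnaA$transcript[rnaA$type == "m5C"]), tpm_mean)
      res$co_modification <- com
      summary$pct_m6a_also_m5c <- com$overlap$pct_m6a_also_m5c
      summary$pct_m5c_also_m6a <- com$overlap$pct_m5c_also_m6a
    }
    stage_log("degs", "%d up, %d down of %d genes",
              sum(degs$status == "up"), sum(degs$status == "down"),
              nrow(degs))
  }

  ## ---- cascade -------------------------------------------------------
  if ("cascade" %in% cfg$stages) {
    if (is.null(res$dmrs) || is.null(degs)) {
      stop("stage 'cascade': requires the dmr and degs stages")
    }
    amrs <- if (!is.null(res$amrs)) res$amrs else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    labels <- classify_genes(genes$genes, svs, res$dmrs, amrs,
                             footprint_flank = cfg$footprint_flank)
    impact <- expression_impact_by_category(labels, degs)
    res$labels <- labels
    res$impact <- impact
    data.table::fwrite(labels, file.path(outdir, "gene_cascade_labels.tsv"),
                       sep = "\t")
    data.table::fwrite(impact$summary,
                       file.path(outdir, "category_impact.tsv"), sep = "\t")
    if (!is.null(impact$tests)) {
      data.table::fwrite(impact$tests,
                         file.path(outdir, "category_tests.tsv"), sep = "\t")
    }
    summary$cascade_counts <- list(
      sv_gene = sum(labels$sv_gene), dmg = sum(labels$dmg),
      dpg = sum(labels$dpg), indel_dmg = sum(labels$indel_dmg),
      indel_amg = sum(labels$indel_amg))
    summary$category_impact <- impact$summary
    stage_log("cascade", "DMG %d, InDel-DMG %d, InDel-AMG %d",
              sum(labels$dmg), sum(labels$indel_dmg),
              sum(labels$indel_amg))
  }

  write_report(summary, outdir)
  invisible(c(res, list(summary = summary)))
}

write_report <- function(summary, outdir) {
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE, na = "null")
  fmt_list <- function(x) paste(sprintf("%s: %s", names(x),
                                        vapply(x, function(v)
                                          paste(format(v), collapse = " "),
                                          character(1))),
                                collapse = "; ")
  lines <- c("# Cascade pipeline summary", "")
  for (nm in names(summary)) {
    v <- summary[[nm]]
    lines <- c(lines, paste0("## ", nm), "")
    if (is.data.frame(v)) {
      lines <- c(lines,
                 paste(names(v), collapse = " | "),
                 paste(rep("---", ncol(v)), collapse = " | "),
                 apply(v, 1, function(r) paste(format(r), collapse = " | ")),
                 "")
    } else if (is.list(v)) {
      lines <- c(lines, fmt_list(v), "")
    } else {
      lines <- c(lines, paste(format(v), collapse = " "), "")
    }
  }
  writeLines(lines, file.path(outdir, "report.md"))
  invisible(NULL)
}
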