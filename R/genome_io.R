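# Readers and writers for the plain-text formats the pipeline touches.
#
# File conventions supported:
#   * Bismark-style cytosine report: 1-based positions, tab-separated
#   * BED / domainBED / bedGraph: 0-based half-open
#   * GFF3: 1-based inclusive
#   * SV / expression / RNA-modification tables: tab-separated with header
# Everything is converted to the internal 0-based half-open convention on
# read and back on write. Gzip input is handled transparently; lines
# starting with '#' are ignored in all tab-separated formats.

CONTEXTS <- c("CG", "CHG", "CHH")
MOD_TYPES <- c("m6A", "m5C")
SV_TYPES <- c("INS", "DEL", "INV")

# fread via a base connection for gzip input (file() auto-detects
# compression on read)
fread_txt <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    data.table::fread(text = readLines(path), ...)
  } else {
    data.table::fread(path, ...)
  }
}

#' Convert intervals between 0-based half-open and 1-based closed
#'
#' @param x Interval `data.frame` with `start` and `end` columns.
#' @return `x` with coordinates shifted to the other convention.
#' @export
to_one_based <- function(x) { x$start <- x$start + 1; x }

#' @rdname to_one_based
#' @export
to_zero_based <- function(x) { x$start <- x$start - 1; x }

#' Read a Bismark-style cytosine report
#'
#' Expects seven tab-separated columns: chromosome, 1-based position,
#' strand, methylated count, unmethylated count, context, trinucleotide.
#' Sites must be covered by more than `min_coverage` reads to be retained
#' (strictly greater, so the default keeps sites with >= 6 reads).
#'
#' @param path Report file (plain or gzip).
#' @param min_coverage Coverage cutoff; sites with
#'   `methylated + unmethylated <= min_coverage` are dropped.
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `strand`,
#'   `meth`, `unmeth`, `context`, `tri`.
#' @export
read_cytosine_report <- function(path, min_coverage = 5) {
  x <- fread_txt(path, sep = "\t", header = FALSE, data.table = FALSE,
                 showProgress = FALSE,
                 colClasses = list(character = c(1, 3, 6, 7)))
  if (ncol(x) != 7) stop("cytosine report must have 7 columns, found ", ncol(x))
  names(x) <- c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri")
  for (col in c("pos", "meth", "unmeth")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed cytosine report line %d: non-numeric '%s'",
                   bad[1], col))
    }
    x[[col]] <- v
  }
  unknown <- which(!x$context %in% CONTEXTS)
  if (length(unknown)) {
    stop(sprintf("unknown methylation context '%s' at line %d",
                 x$context[unknown[1]], unknown[1]))
  }
  if (any(x$pos < 1)) stop("cytosine report positions must be 1-based (>= 1)")
  x$pos <- x$pos - 1
  x <- x[x$meth + x$unmeth > min_coverage, , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Write a Bismark-style cytosine report
#' @param calls `data.frame` as returned by [read_cytosine_report()].
#' @param path Output path (`.gz` supported).
#' @export
write_cytosine_report <- function(calls, path) {
  out <- data.frame(calls$chrom, calls$pos + 1, calls$strand, calls$meth,
                    calls$unmeth, calls$context, calls$tri)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read BED-family interval files
#'
#' `BED` reads BED3/BED6 (name/score/strand kept when present);
#' `domainBED` is BED with a domain identifier in column 4; `bedGraph`
#' carries a numeric value (e.g. a PC1 eigenvector) in column 4.
#'
#' @param path File path; 0-based half-open coordinates.
#' @param dialect One of `"BED"`, `"domainBED"`, `"bedGraph"`.
#' @param layout Optional [genome_layout()] to validate against.
#' @return Interval `data.frame`; `bedGraph` adds a `value` column,
#'   `domainBED` a `name` column.
#' @export
read_intervals <- function(path, dialect = c("BED", "domainBED", "bedGraph"),
                           layout = NULL) {
  dialect <- match.arg(dialect)
  x <- tryCatch(
    suppressWarnings(
      data.table::fread(path, sep = "\t", header = FALSE,
                        data.table = FALSE, showProgress = FALSE)),
    error = function(e) data.frame())
  if (nrow(x) == 0) {
    warning("empty interval file: ", path)
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
    if (dialect == "bedGraph") out$value <- numeric(0)
    if (dialect == "domainBED") out$name <- character(0)
    return(out)
  }
  if (ncol(x) < 3) stop("BED-family file needs >= 3 columns: ", path)
  out <- data.frame(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
                    end = as.numeric(x[[3]]), stringsAsFactors = FALSE)
  if (dialect == "bedGraph") {
    if (ncol(x) < 4) stop("bedGraph needs a value column: ", path)
    out$value <- as.numeric(x[[4]])
  } else if (dialect == "domainBED") {
    out$name <- if (ncol(x) >= 4) as.character(x[[4]]) else
      sprintf("domain_%d", seq_len(nrow(out)))
  } else if (ncol(x) >= 6) {
    out$name <- as.character(x[[4]])
    out$score <- x[[5]]
    out$strand <- as.character(x[[6]])
  }
  validate_intervals(out, layout, what = basename(path))
  out
}

#' Write intervals as BED/domainBED/bedGraph
#' @param x Interval `data.frame` (needs `value` for bedGraph).
#' @param path Output path.
#' @param dialect Output dialect, as in [read_intervals()].
#' @export
write_intervals <- function(x, path,
                            dialect = c("BED", "domainBED", "bedGraph")) {
  dialect <- match.arg(dialect)
  cols <- switch(dialect,
    BED = {
      # BED columns are positional: keep optional columns only while the
      # preceding ones are present
      opt <- c("name", "score", "strand")
      n_opt <- 0
      for (i in seq_along(opt)) {
        if (!opt[i] %in% names(x)) break
        n_opt <- i
      }
      x[, c("chrom", "start", "end", opt[seq_len(n_opt)]), drop = FALSE]
    },
    domainBED = x[, c("chrom", "start", "end", "name")],
    bedGraph = x[, c("chrom", "start", "end", "value")])
  data.table::fwrite(cols, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     scipen = 50)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features; exons are attached to their gene via
#' the `Parent`/`ID` attribute chain (a `Parent` may point at an mRNA whose
#' own `Parent` is the gene). Coordinates are converted from 1-based
#' inclusive to 0-based half-open. The TSS is derived per strand: `start`
#' on `+`, `end - 1` on `-`.
#'
#' @param path GFF3 file.
#' @param layout Optional [genome_layout()].
#' @return List with `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`) and `exons` (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gff3_genes <- function(path, layout = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no features in ", path)
  x <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                         data.table = FALSE, showProgress = FALSE,
                         col.names = c("chrom", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attr"))
  ids <- sub(".*ID=([^;]+).*", "\\1", x$attr)
  ids[!grepl("ID=", x$attr)] <- NA
  parents <- sub(".*Parent=([^;]+).*", "\\1", x$attr)
  parents[!grepl("Parent=", x$attr)] <- NA

  is_gene <- x$type == "gene"
  genes <- data.frame(gene_id = ids[is_gene],
                      chrom = x$chrom[is_gene],
                      start = x$start[is_gene] - 1,
                      end = x$end[is_gene],
                      strand = x$strand[is_gene],
                      stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id)) stop("gene feature without ID attribute in ", path)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ids in ", path, ": ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)

  # map transcript-level ids back to their gene
  id2gene <- stats::setNames(genes$gene_id, genes$gene_id)
  is_tx <- !is_gene & !is.na(ids) & !is.na(parents) & parents %in% genes$gene_id
  id2gene <- c(id2gene, stats::setNames(parents[is_tx], ids[is_tx]))

  is_exon <- x$type == "exon"
  exon_gene <- id2gene[parents[is_exon]]
  exons <- data.frame(gene_id = unname(exon_gene),
                      chrom = x$chrom[is_exon],
                      start = x$start[is_exon] - 1,
                      end = x$end[is_exon],
                      stringsAsFactors = FALSE)
  exons <- exons[!is.na(exons$gene_id), , drop = FALSE]
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  validate_intervals(genes, layout, what = "gene")
  validate_intervals(exons, layout, what = "exon")
  list(genes = genes, exons = exons)
}

#' Write gene models as GFF3
#' @param models List as returned by [read_gff3_genes()].
#' @param path Output path.
#' @export
write_gff3_genes <- function(models, path) {
  g <- models$genes
  e <- models$exons
  lines <- c("##gff-version 3",
             sprintf("%s\tsvcascade\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start + 1, g$end, g$strand, g$gene_id))
  if (nrow(e)) {
    strand <- g$strand[match(e$gene_id, g$gene_id)]
    lines <- c(lines,
               sprintf("%s\tsvcascade\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       e$chrom, e$start + 1, e$end, strand, e$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a structural-variant table
#'
#' Tab-separated with header columns `id`, `chrom`, `start`, `end`, `type`,
#' `length` and optionally `source`. Coordinates are 0-based half-open;
#' insertions are anchored as `[pos, pos + 1)` with `length` holding the
#' inserted-sequence length.
#'
#' @param path SV TSV file.
#' @param layout Optional [genome_layout()].
#' @return `data.frame` of SV records.
#' @export
read_sv_table <- function(path, layout = NULL) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         showProgress = FALSE)
  need <- c("id", "chrom", "start", "end", "type", "length")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("SV table missing columns: ", paste(miss, collapse = ", "))
  if (!all(x$type %in% SV_TYPES)) {
    stop("unknown SV type: ", paste(setdiff(unique(x$type), SV_TYPES),
                                    collapse = ", "))
  }
  if (any(x$length <= 0)) stop("SV length must be > 0")
  bad <- x$type %in% c("DEL", "INV") & (x$end - x$start) != x$length
  if (any(bad)) stop("DEL/INV length must equal interval length (row ",
                     which(bad)[1], ")")
  if (!"source" %in% names(x)) x$source <- "."
  validate_intervals(x, layout, what = "SV")
  x
}

#' Write a structural-variant table
#' @param svs SV `data.frame`.
#' @param path Output path.
#' @export
write_sv_table <- function(svs, path) {
  keep <- intersect(c("id", "chrom", "start", "end", "type", "length",
                      "source"), names(svs))
  data.table::fwrite(svs[, keep, drop = FALSE], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an expression table with its sample sheet
#'
#' The expression file is gene x sample TPM, tab-separated, first column
#' `gene_id`. The sample sheet maps column names to accession, tissue/stage
#' and replicate.
#'
#' @param path Expression TSV.
#' @param sample_sheet Path to a TSV with columns `sample`, `accession`,
#'   `tissue`, `replicate`, or an equivalent `data.frame`.
#' @return List with `tpm` (numeric matrix, genes x samples) and `samples`.
#' @export
read_expression_table <- function(path, sample_sheet) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         showProgress = FALSE)
  if (names(x)[1] != "gene_id") stop("expression table must start with gene_id")
  if (anyDuplicated(x$gene_id)) stop("duplicate gene ids in expression table")
  tpm <- as.matrix(x[, -1, drop = FALSE])
  rownames(tpm) <- x$gene_id
  if (any(tpm < 0)) stop("negative TPM values")
  sheet <- if (is.character(sample_sheet)) {
    data.table::fread(sample_sheet, sep = "\t", header = TRUE,
                      data.table = FALSE, showProgress = FALSE)
  } else as.data.frame(sample_sheet)
  need <- c("sample", "accession", "tissue", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing: ", paste(miss, collapse = ", "))
  miss_col <- setdiff(sheet$sample, colnames(tpm))
  if (length(miss_col)) stop("sample sheet refers to missing columns: ",
                             paste(miss_col, collapse = ", "))
  list(tpm = tpm[, sheet$sample, drop = FALSE], samples = sheet)
}

#' Write an expression table
#' @param tpm Numeric gene x sample matrix.
#' @param path Output path.
#' @export
write_expression_table <- function(tpm, path) {
  out <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an RNA-modification site table
#'
#' Tab-separated with header `transcript`, `position`, `type` (m6A/m5C),
#' `modified`, `coverage`, `fraction`. When both counts are present the
#' fraction is recomputed as modified/coverage and must agree with the
#' stated fraction to within 1e-6.
#'
#' @param path Site TSV file.
#' @return `data.frame` of site records.
#' @export
read_rnamod_table <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         showProgress = FALSE)
  need <- c("transcript", "position", "type", "modified", "coverage",
            "fraction")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("rnamod table missing: ", paste(miss, collapse = ", "))
  if (!all(x$type %in% MOD_TYPES)) {
    stop("unknown RNA modification type: ",
         paste(setdiff(unique(x$type), MOD_TYPES), collapse = ", "))
  }
  if (any(x$fraction < 0 | x$fraction > 1)) stop("fraction outside [0, 1]")
  if (any(x$modified > x$coverage)) stop("modified reads exceed coverage")
  has_counts <- x$coverage > 0
  recomputed <- x$modified[has_counts] / x$coverage[has_counts]
  off <- which(abs(recomputed - x$fraction[has_counts]) > 1e-6)
  if (length(off)) {
    i <- which(has_counts)[off[1]]
    stop(sprintf(
      "inconsistent fraction at row %d: stated %.6f but %d/%d = %.6f",
      i, x$fraction[i], x$modified[i], x$coverage[i], x$modified[i] / x$coverage[i]))
  }
  x
}

#' Write an RNA-modification site table
#' @param sites `data.frame` as returned by [read_rnamod_table()].
#' @param path Output path.
#' @export
write_rnamod_table <- function(sites, path) {
  data.table::fwrite(sites[, c("transcript", "position", "type", "modified",
                               "coverage", "fraction")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
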