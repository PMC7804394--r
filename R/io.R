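#' @importFrom rtracklayer import export
NULL

# cheap structural pre-scan so format errors carry a line number
.scan_tsv <- function(path, min_fields, what = "record") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (length(nf) && any(nf < min_fields)) {
    ln <- which(keep)[which(nf < min_fields)[1L]]
    stop("malformed ", what, " at line ", ln, " of ", path,
         ": expected >= ", min_fields, " tab-separated fields, found ",
         nf[which(nf < min_fields)[1L]])
  }
  invisible(sum(keep))
}

#' Read / write BED interval files
#'
#' BED3/BED6 (tab-separated, 0-based half-open). Malformed records are
#' rejected with their line number, never silently repaired.
#'
#' @param path File path.
#' @param gn Optional `genome` for coordinate validation.
#' @return `read_bed` returns a sorted `GRanges`.
#' @export
read_bed <- function(path, gn = NULL) {
  .scan_tsv(path, 3L, "BED record")
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gn)) gr <- bind_genome(gr, gn)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname read_bed
#' @param gr A `GRanges`.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write MACS2 narrowPeak files
#'
#' BED6+4 dialect. Field 9 (\eqn{-\log_{10}} q-value) is converted to a
#' linear `qvalue` metadata column; a sentinel of -1 becomes `NA`.
#'
#' @param path File path.
#' @param gn Optional `genome` for coordinate validation.
#' @return A sorted `GRanges` with `name`, `score`, `signalValue`, `pValue`,
#'   `qvalue` (linear) and `peak` columns.
#' @export
read_narrowpeak <- function(path, gn = NULL) {
  .scan_tsv(path, 10L, "narrowPeak record")
  gr <- rtracklayer::import(
    path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  q10 <- gr$qValue
  gr$qvalue <- ifelse(q10 < 0, NA_real_, 10^(-q10))
  gr$qValue <- NULL
  if (!is.null(gn)) gr <- bind_genome(gr, gn)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname read_narrowpeak
#' @param gr A `GRanges` as returned by `read_narrowpeak` (missing columns
#'   are filled with narrowPeak sentinels).
#' @export
write_narrowpeak <- function(gr, path) {
  n <- length(gr)
  grab <- function(col, default) {
    v <- S4Vectors::mcols(gr)[[col]]
    if (is.null(v)) rep(default, n) else v
  }
  q <- grab("qvalue", NA_real_)
  tab <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = grab("name", "."),
    score = grab("score", 0),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    signalValue = grab("signalValue", 0),
    pValue = grab("pValue", -1),
    qValue = ifelse(is.na(q), -1, -log10(pmax(q, .Machine$double.xmin))),
    peak = grab("peak", -1L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write bedGraph signal tracks
#'
#' Piecewise-constant CPM signal. Segments must not overlap; uncovered bases
#' are implicitly 0 CPM (see [track_mean()]).
#'
#' @param path File path.
#' @param gn Optional `genome` for coordinate validation.
#' @return A sorted `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path, gn = NULL) {
  .scan_tsv(path, 4L, "bedGraph record")
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!GenomicRanges::isDisjoint(gr))
    stop("overlapping segments in bedGraph file: ", path)
  if (!is.null(gn)) gr <- bind_genome(gr, gn)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname read_bedgraph
#' @param track A signal-track `GRanges` with `score`.
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Read gene models from GTF/GFF3 (or stranded BED)
#'
#' Keeps `type == "gene"` records when a type column is present. Every gene
#' must be stranded; the TSS is the start of `+` genes and the end of `-`
#' genes. GTF/GFF 1-based inclusive coordinates are converted by the parser.
#'
#' @param path File path (`.gtf`, `.gff`, `.gff3` or `.bed`).
#' @param gn Optional `genome` for coordinate validation.
#' @return A `GRanges` with a `gene_id` column, sorted by position.
#' @export
read_gene_models <- function(path, gn = NULL) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- read_bed(path)
    if (is.null(gr$name)) stop("BED gene models need a name column: ", path)
    gr$gene_id <- gr$name
  } else {
    .scan_tsv(path, 8L, "GFF record")
    gr <- rtracklayer::import(path)
    if (!is.null(gr$type)) gr <- gr[gr$type == "gene"]
    id <- gr$gene_id
    if (is.null(id)) id <- gr$ID
    if (is.null(id)) id <- gr$Name
    if (is.null(id)) stop("no gene_id/ID/Name attribute in ", path)
    S4Vectors::mcols(gr) <- NULL
    gr$gene_id <- as.character(id)
  }
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("unstranded gene model in ", path,
         " (strand is required to anchor the TSS)")
  if (anyDuplicated(gr$gene_id))
    stop("duplicated gene_id in ", path)
  if (!is.null(gn)) gr <- bind_genome(gr, gn)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname read_gene_models
#' @param genes A gene-model `GRanges` with `gene_id`.
#' @export
write_gene_models <- function(genes, path) {
  out <- genes
  out$type <- "gene"
  out$ID <- out$gene_id
  rtracklayer::export(out, path, format = "GFF3")
  invisible(path)
}

#' Read / write a numeric sample matrix as TSV
#'
#' Rows are regions or genes (first column holds row names), columns samples.
#'
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = 1L, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_matrix_tsv
#' @param m A numeric matrix with row and column names.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' Flat YAML of paths, thresholds and the run seed (see the packaged example
#' written by [write_config_template()]).
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

#' @rdname read_config
#' @export
write_config_template <- function(path) {
  yaml::write_yaml(default_config(), path)
  invisible(path)
}
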