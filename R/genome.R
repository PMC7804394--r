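#' Construct a genome: named chromosome lengths
#'
#' A genome is represented as a named integer vector of chromosome lengths in
#' base pairs. It anchors coordinate validation for every region set in the
#' pipeline and supplies the sampling space for random-region placement.
#'
#' @param lengths Named numeric vector; names are chromosome names, values
#'   chromosome lengths in bp (each >= 1).
#' @return A named integer vector of class `genome`.
#' @examples
#' gn <- genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome <- function(lengths) {
  if (length(lengths) == 0L)
    stop("genome must contain at least one chromosome")
  nm <- names(lengths)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(nm))
    stop("duplicated chromosome name: ", nm[duplicated(nm)][1L])
  if (anyNA(lengths) || any(lengths < 1))
    stop("chromosome lengths must be >= 1")
  structure(as.integer(round(lengths)), names = nm, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "chromosome(s),",
      format(sum(as.numeric(x)), big.mark = ","), "bp total\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Convert a genome to a Seqinfo object
#' @param gn A `genome`.
#' @return A [GenomeInfoDb::Seqinfo] with the same chromosomes and lengths.
#' @export
genome_seqinfo <- function(gn) {
  GenomeInfoDb::Seqinfo(seqnames = names(gn), seqlengths = as.integer(gn))
}

#' Read / write a chromosome-sizes table
#'
#' Two-column tab-separated text: chromosome name, length in bp.
#'
#' @param path File path.
#' @return `read_genome` returns a `genome`; `write_genome` returns `path`
#'   invisibly.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) stop("empty genome file: ", path)
  genome(stats::setNames(tab$length, tab$chrom))
}

#' @rdname read_genome
#' @param gn A `genome`.
#' @export
write_genome <- function(gn, path) {
  utils::write.table(data.frame(names(gn), as.integer(gn)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
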