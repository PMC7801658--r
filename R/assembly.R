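#' Assembly objects
#'
#' An assembly is a named, ordered collection of contig sequences over
#' {A,C,G,T,N} with optional soft-mask intervals (recorded when lowercase
#' bases are read from FASTA, re-emitted as lowercase on write, and ignored
#' by every algorithm in the package).
#'
#' @param name assembly identifier.
#' @param seqs named character vector of uppercase contig sequences.
#' @param softmask named list of two-column matrices of 0-based half-open
#'   intervals (one matrix per contig), or NULL.
#' @return an object of class `assembly`.
#' @export
assembly <- function(name, seqs, softmask = NULL) {
  if (length(seqs) == 0) stop_ctx("assembly must contain at least one contig")
  cn <- names(seqs)
  if (is.null(cn) || any(cn == "") || anyDuplicated(cn))
    stop_ctx("contig names must be present and unique")
  if (any(nchar(seqs) == 0)) stop_ctx("contig lengths must be > 0")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_ctx("illegal character in contig(s): ", paste(cn[bad], collapse = ", "))
  if (is.null(softmask)) softmask <- setNames(vector("list", length(seqs)), cn)
  structure(list(name = name, seqs = seqs, softmask = softmask),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly '%s': %d contig(s), %s bp>\n", x$name,
              length(x$seqs), format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Contig lengths of an assembly
#' @param x an `assembly`.
#' @return named integer vector.
#' @export
contig_lengths <- function(x) {
  stopifnot(inherits(x, "assembly"))
  setNames(nchar(x$seqs), names(x$seqs))
}

#' Extract a subsequence (0-based half-open)
#' @param x an `assembly`.
#' @param contig contig name.
#' @param start,end 0-based half-open bounds.
#' @return character scalar.
#' @export
subseq0 <- function(x, contig, start, end) {
  s <- x$seqs[[contig]]
  if (is.null(s)) stop_ctx("unknown contig: ", contig)
  if (start < 0 || end > nchar(s) || end < start)
    stop_ctx("interval out of range for contig ", contig)
  substr(s, start + 1, end)
}
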