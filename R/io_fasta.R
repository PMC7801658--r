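# FASTA I/O. Reading goes through Biostrings; lowercase bases are uppercased
# and recorded as soft-mask intervals so that write_fasta() can re-emit them.

#' Read a FASTA file into an assembly
#'
#' Lowercase (soft-masked) bases are uppercased and their intervals recorded;
#' any character outside A/C/G/T/N (either case) is an error.
#'
#' @param path FASTA file.
#' @param name assembly name; defaults to the file stem.
#' @return an [assembly()].
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop_ctx("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop_ctx("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop_ctx("duplicate contig names in ", path)
  raw <- as.character(ss)
  if (any(grepl("[^ACGTNacgtn]", raw)))
    stop_ctx("illegal character in FASTA ", path)
  softmask <- lapply(raw, function(s) {
    r <- rle(grepl("[acgtn]", strsplit(s, "", fixed = TRUE)[[1]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    m <- cbind(start = starts[r$values], end = ends[r$values])
    if (nrow(m) == 0) NULL else m
  })
  names(softmask) <- nm
  assembly(name %||% sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path)),
           setNames(toupper(raw), nm), softmask)
}

#' Write an assembly to FASTA
#'
#' Soft-mask intervals are re-emitted as lowercase. `wrap = 0` writes each
#' sequence on a single line.
#'
#' @param x an [assembly()].
#' @param path output file.
#' @param wrap line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap = 60) {
  stopifnot(inherits(x, "assembly"))
  seqs <- x$seqs
  for (cn in names(seqs)) {
    m <- x$softmask[[cn]]
    if (!is.null(m) && nrow(m) > 0) {
      s <- seqs[[cn]]
      for (i in seq_len(nrow(m))) {
        lo <- m[i, 1] + 1; hi <- m[i, 2]
        substr(s, lo, hi) <- tolower(substr(s, lo, hi))
      }
      seqs[[cn]] <- s
    }
  }
  ss <- Biostrings::BStringSet(seqs)
  width <- if (wrap <= 0) max(nchar(seqs)) + 1L else as.integer(wrap)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
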