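# PAF import/export with cs-tag expansion (short ":12*at" and long "=ACGT*at"
# forms). Alignment ops are run-length data.frames with columns
#   kind  one of match / sub / ins / del
#   len   run length (bases)
#   alt   query bases for sub/ins, "" for match/del
# adjacent same-kind runs are always merged.

ops_df <- function(kind = character(), len = integer(), alt = character()) {
  new_df(kind = kind, len = as.integer(len), alt = alt)
}

merge_ops <- function(ops) {
  ops <- ops[ops$len > 0, , drop = FALSE]
  if (nrow(ops) < 2) return(ops)
  grp <- cumsum(c(TRUE, ops$kind[-1] != ops$kind[-nrow(ops)]))
  g <- factor(grp, levels = unique(grp))
  ops_df(ops$kind[!duplicated(grp)],
         as.integer(tapply(ops$len, g, sum)),
         as.character(tapply(ops$alt, g, paste, collapse = "")))
}

ops_spans <- function(ops) {
  tcons <- ops$kind %in% c("match", "sub", "del")
  qcons <- ops$kind %in% c("match", "sub", "ins")
  c(target = sum(ops$len[tcons]), query = sum(ops$len[qcons]))
}

#' Expand a cs tag into an alignment op list
#'
#' Both the short (`:12*at`) and long (`=ACGT*at`) forms are accepted.
#'
#' @param cs the cs tag payload (without the `cs:Z:` prefix).
#' @return op data.frame (kind/len/alt; alt holds uppercased query bases).
#' @export
parse_cs <- function(cs) {
  toks <- regmatches(cs, gregexpr("[:=*+-][A-Za-z0-9]*", cs))[[1]]
  if (sum(nchar(toks)) != nchar(cs)) stop_ctx("malformed cs tag: ", cs)
  kind <- character(0); len <- integer(0); alt <- character(0)
  for (tk in toks) {
    op <- substr(tk, 1, 1); body <- substring(tk, 2)
    if (op == ":") {
      kind <- c(kind, "match"); len <- c(len, as.integer(body)); alt <- c(alt, "")
    } else if (op == "=") {
      kind <- c(kind, "match"); len <- c(len, nchar(body)); alt <- c(alt, "")
    } else if (op == "*") {
      if (nchar(body) != 2) stop_ctx("malformed cs substitution: ", tk)
      kind <- c(kind, "sub"); len <- c(len, 1L)
      alt <- c(alt, toupper(substr(body, 2, 2)))
    } else if (op == "+") {
      kind <- c(kind, "ins"); len <- c(len, nchar(body)); alt <- c(alt, toupper(body))
    } else {
      kind <- c(kind, "del"); len <- c(len, nchar(body)); alt <- c(alt, "")
    }
  }
  merge_ops(ops_df(kind, len, alt))
}

# cs long form for an op list; needs the target slice covered by the ops
ops_to_cs <- function(ops, target_seq) {
  out <- character(nrow(ops)); tpos <- 0
  for (i in seq_len(nrow(ops))) {
    k <- ops$kind[i]; l <- ops$len[i]
    if (k == "match") {
      out[i] <- paste0("=", substr(target_seq, tpos + 1, tpos + l)); tpos <- tpos + l
    } else if (k == "sub") {
      refb <- strsplit(tolower(substr(target_seq, tpos + 1, tpos + l)), "")[[1]]
      altb <- strsplit(tolower(ops$alt[i]), "")[[1]]
      out[i] <- paste0("*", refb, altb, collapse = ""); tpos <- tpos + l
    } else if (k == "ins") {
      out[i] <- paste0("+", tolower(ops$alt[i]))
    } else {
      out[i] <- paste0("-", tolower(substr(target_seq, tpos + 1, tpos + l)))
      tpos <- tpos + l
    }
  }
  paste(out, collapse = "")
}

#' Read a PAF file
#'
#' @param path PAF file (>= 12 tab-separated columns; optional `cs:Z:` tag).
#' @return list of alignment records; each has query/target names, lengths,
#'   0-based half-open coordinates, strand, and `ops` when a cs tag is present.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stop_ctx(path, " line ", i, ": PAF needs >= 12 columns, found ", length(f))
    rec <- list(qname = f[1], qlen = as.integer(f[2]),
                qstart = as.integer(f[3]), qend = as.integer(f[4]),
                strand = f[5], tname = f[6], tlen = as.integer(f[7]),
                tstart = as.integer(f[8]), tend = as.integer(f[9]),
                nmatch = as.integer(f[10]), alen = as.integer(f[11]),
                mapq = as.integer(f[12]))
    cs <- grep("^cs:Z:", f[-(1:12)], value = TRUE)
    if (length(cs) == 1) {
      rec$ops <- parse_cs(substring(cs, 6))
      sp <- ops_spans(rec$ops)
      if (sp["target"] != rec$tend - rec$tstart ||
          sp["query"] != rec$qend - rec$qstart)
        stop_ctx(path, " line ", i, ": cs tag inconsistent with alignment span")
    }
    rec
  })
}

#' Write alignment blocks as PAF with long-form cs tags
#'
#' @param blocks list of alignment blocks (see [align_genomes()]).
#' @param target target [assembly()] (needed to spell out match/del bases).
#' @param query query [assembly()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, target, query, path) {
  qlen <- contig_lengths(query); tlen <- contig_lengths(target)
  lines <- vapply(blocks, function(b) {
    tseq <- subseq0(target, b$target$contig, b$target$start, b$target$end)
    sp <- ops_spans(b$ops)
    nmatch <- sum(b$ops$len[b$ops$kind == "match"])
    cs <- ops_to_cs(b$ops, tseq)
    paste(b$query$contig, qlen[[b$query$contig]], b$query$start, b$query$end,
          b$strand, b$target$contig, tlen[[b$target$contig]],
          b$target$start, b$target$end, nmatch,
          max(sp), 60, paste0("cs:Z:", cs), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
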