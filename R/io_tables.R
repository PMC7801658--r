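# extract `key=value` from ;-separated attribute/INFO strings
kv_field <- function(x, key) {
  pat <- paste0("(^|;)", key, "=[^;]*")
  m <- regexpr(pat, x)
  out <- rep(NA_character_, length(x))
  out[m > 0] <- sub(paste0("^;?", key, "="), "", regmatches(x, m))
  out
}

# Tabular format readers/writers: marker TSV, AF-panel TSV / minimal VCF,
# BED (0-based half-open), AGP 2.1, minimal 9-column GFF3, and the minimal
# VCF 4.2 dialect used for variant exchange (INFO keys SVTYPE, SVLEN, SUPP,
# TIE; no genotypes).

#' Read an STS marker table
#'
#' Tab-separated with header columns: marker_id, map_id, map_type (genetic or
#' RH), linkage_group, map_position, primer_fwd, primer_rev, expected_size
#' (optional; "lo-hi", a single integer, or empty).
#'
#' @param path marker TSV.
#' @return data.frame of marker records with size_min/size_max columns.
#' @export
read_marker_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("marker_id", "map_id", "map_type", "linkage_group",
            "map_position", "primer_fwd", "primer_rev")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_ctx(path, ": missing marker columns: ",
                             paste(miss, collapse = ", "))
  d$map_position <- as.numeric(d$map_position)
  bad <- which(!d$map_type %in% c("genetic", "RH"))
  if (length(bad)) stop_ctx(path, " row ", bad[1], ": map_type must be genetic or RH")
  bad <- which(nchar(d$primer_fwd) < 15 | nchar(d$primer_rev) < 15)
  if (length(bad)) stop_ctx(path, " row ", bad[1], ": primers must be >= 15 bp")
  bad <- which(d$map_position < 0)
  if (length(bad)) stop_ctx(path, " row ", bad[1], ": map_position must be >= 0")
  es <- if ("expected_size" %in% names(d)) d$expected_size else rep("", nrow(d))
  es[is.na(es)] <- ""
  lo <- hi <- rep(NA_integer_, nrow(d))
  rng <- grepl("^[0-9]+-[0-9]+$", es)
  lo[rng] <- as.integer(sub("-.*", "", es[rng]))
  hi[rng] <- as.integer(sub(".*-", "", es[rng]))
  one <- grepl("^[0-9]+$", es)
  lo[one] <- hi[one] <- as.integer(es[one])
  d$size_min <- lo; d$size_max <- hi
  d$expected_size <- NULL
  d
}

#' Write an STS marker table
#' @param markers marker data.frame (as from [read_marker_table()]).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  m <- markers
  m$expected_size <- ifelse(is.na(m$size_min), "",
                            ifelse(m$size_min == m$size_max, as.character(m$size_min),
                                   paste0(m$size_min, "-", m$size_max)))
  m$size_min <- NULL; m$size_max <- NULL
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency panel
#'
#' Accepts a TSV with header contig/pos/ref/alt/af (pos 1-based) or a minimal
#' VCF with an `AF` INFO key. One record per (contig, pos, ref, alt).
#'
#' @param path panel file.
#' @return data.frame with contig, pos, ref, alt, af, plus a `key` column.
#' @export
read_af_panel <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- read_vcf_min(path)
    af <- as.numeric(kv_field(v$info, "AF"))
    d <- new_df(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt, af = af)
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "pos", "ref", "alt", "af")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop_ctx(path, ": missing AF panel columns: ",
                               paste(miss, collapse = ", "))
  }
  if (any(d$ref == d$alt)) stop_ctx(path, ": AF panel has ref == alt")
  if (any(d$af < 0 | d$af > 1)) stop_ctx(path, ": af must be in [0,1]")
  d$key <- paste(d$contig, d$pos, d$ref, d$alt, sep = ":")
  if (anyDuplicated(d$key)) stop_ctx(path, ": duplicate AF panel site")
  d
}

#' Write an allele-frequency panel TSV
#' @param panel data.frame with contig/pos/ref/alt/af.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_af_panel <- function(panel, path) {
  write.table(panel[, c("contig", "pos", "ref", "alt", "af")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BED (0-based half-open)
#'
#' @param path BED file (3-6 columns, no header).
#' @return data.frame with contig, start, end and, when present, name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop_ctx(path, ": BED needs >= 3 columns")
  names(d)[1:3] <- c("contig", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  if (ncol(d) >= 5) names(d)[5] <- "score"
  if (ncol(d) >= 6) names(d)[6] <- "strand"
  if (any(d$end <= d$start)) stop_ctx(path, ": BED interval with end <= start")
  d
}

#' @rdname read_bed
#' @param bed data.frame with contig/start/end (+ optional name/score/strand).
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("contig", "start", "end", "name", "score", "strand"),
                    names(bed))
  write.table(bed[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an AGP 2.1 file for a pseudo-molecule build
#'
#' @param agp data.frame as produced by [build_pseudomolecules()] (columns
#'   object, object_beg, object_end, part_number, component_type, and the
#'   W/N-specific columns 6-9).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(agp, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an AGP 2.1 file
#' @param path AGP file.
#' @return data.frame with the nine AGP columns.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  d <- read.delim(text = paste(lines, collapse = "\n"), header = FALSE,
                  stringsAsFactors = FALSE,
                  colClasses = c("character", "integer", "integer", "integer",
                                 "character", "character", "character",
                                 "character", "character"))
  names(d) <- c("object", "object_beg", "object_end", "part_number",
                "component_type", "c6", "c7", "c8", "c9")
  d
}

# minimal 9-column GFF3 ------------------------------------------------------

#' Read / write minimal 9-column GFF3
#'
#' @param path GFF3 file.
#' @return data.frame with seqid, source, type, start, end (1-based closed),
#'   score, strand, phase, attributes, plus parsed ID and Parent columns.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(new_df(seqid = character(), source = character(), type = character(),
                  start = integer(), end = integer(), score = character(),
                  strand = character(), phase = character(),
                  attributes = character(), ID = character(),
                  Parent = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9)
  if (length(bad)) stop_ctx(path, " line ", bad[1], ": GFF3 needs 9 columns")
  m <- do.call(rbind, parts)
  d <- new_df(seqid = m[, 1], source = m[, 2], type = m[, 3],
              start = as.integer(m[, 4]), end = as.integer(m[, 5]),
              score = m[, 6], strand = m[, 7], phase = m[, 8],
              attributes = m[, 9])
  d$ID <- kv_field(d$attributes, "ID")
  d$Parent <- kv_field(d$attributes, "Parent")
  d
}

#' @rdname read_gff3
#' @param gff data.frame with the nine GFF3 columns.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  cols <- c("seqid", "source", "type", "start", "end", "score", "strand",
            "phase", "attributes")
  write.table(gff[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# minimal VCF 4.2 ------------------------------------------------------------

#' Read / write the minimal VCF 4.2 dialect
#'
#' Site-only records (no genotypes). INFO keys: SVTYPE, SVLEN, SUPP
#' (comma-separated supporting assembly ids) and TIE=1 for randomly resolved
#' sites. Positions are 1-based.
#'
#' @param path VCF file.
#' @return variant data.frame (contig, pos, ref, alt, vtype, sv, support,
#'   tie, info).
#' @export
read_vcf_min <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    out <- empty_variant_df(); out$info <- character(0); return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8)
  if (length(bad)) stop_ctx(path, ": VCF row ", bad[1], " has < 8 columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:8))
  info <- m[, 8]
  get1 <- function(key) kv_field(info, key)
  ref <- toupper(m[, 4]); alt <- toupper(m[, 5])
  vtype <- ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1, "SNV",
                  ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  sv <- abs(nchar(ref) - nchar(alt)) >= 51
  svl <- get1("SVLEN")
  new_df(contig = m[, 1], pos = as.integer(m[, 2]), ref = ref, alt = alt,
         vtype = vtype, sv = sv,
         support = ifelse(is.na(get1("SUPP")), "", get1("SUPP")),
         tie = !is.na(get1("TIE")) & get1("TIE") == "1",
         info = info)
}

#' @rdname read_vcf_min
#' @param variants variant data.frame (contig, pos, ref, alt, and optionally
#'   vtype, sv, support, tie).
#' @param contig_lengths named integer vector for `##contig` header lines
#'   (optional).
#' @export
write_vcf_min <- function(variants, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SUPP,Number=1,Type=String,Description=\"Supporting assembly ids\">",
    "##INFO=<ID=TIE,Number=1,Type=Integer,Description=\"1 if allele chosen by random tie-break\">"),
    con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       contig_lengths), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants) > 0) {
    v <- variants
    if (is.null(v$vtype))
      v$vtype <- ifelse(nchar(v$ref) == nchar(v$alt) & nchar(v$ref) == 1, "SNV",
                        ifelse(nchar(v$alt) > nchar(v$ref), "INS", "DEL"))
    svlen <- nchar(v$alt) - nchar(v$ref)
    info <- paste0("SVTYPE=", v$vtype,
                   ifelse(v$vtype == "SNV", "", paste0(";SVLEN=", svlen)))
    if (!is.null(v$support))
      info <- ifelse(nzchar(v$support), paste0(info, ";SUPP=", v$support), info)
    if (!is.null(v$tie)) info <- ifelse(v$tie, paste0(info, ";TIE=1"), info)
    writeLines(paste(v$contig, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                     sep = "\t"), con)
  }
  invisible(path)
}
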