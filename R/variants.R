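# Variant extraction from alignment blocks and representation normalization
# (left alignment + parsimony, multiallelic handling). Positions follow VCF
# convention: 1-based, indels left-anchored on a shared leading base.

#' Call variants from alignment blocks against a backbone
#'
#' Every sub/ins/del op becomes one record. Indels are anchored on the
#' backbone base preceding the event; events at the very start of a contig
#' (no anchor base) and records containing N are skipped (variants are never
#' called across N-gaps).
#'
#' @param blocks one-to-one blocks (after [select_primary()]) with the
#'   backbone as target.
#' @param backbone backbone [assembly()].
#' @param query_id assembly id recorded in the support set.
#' @param sv_min_len minimum |len(ref)-len(alt)| for the sv flag (default 51).
#' @return variant data.frame (contig, pos, ref, alt, vtype, sv, support, tie).
#' @export
call_variants <- function(blocks, backbone, query_id, sv_min_len = 51) {
  out <- list()
  for (b in blocks) {
    tc <- b$target$contig
    tseq <- backbone$seqs[[tc]]
    if (is.null(tseq)) stop_ctx("block target contig not in backbone: ", tc)
    tpos <- b$target$start  # 0-based cursor
    ops <- b$ops
    for (i in seq_len(nrow(ops))) {
      k <- ops$kind[i]; l <- ops$len[i]
      if (k == "match") {
        tpos <- tpos + l
      } else if (k == "sub") {
        refb <- substr(tseq, tpos + 1, tpos + l)
        altb <- ops$alt[i]
        if (nchar(altb) != l) stop_ctx("corrupt block: sub alt length mismatch")
        for (j in seq_len(l)) {
          r1 <- substr(refb, j, j); a1 <- substr(altb, j, j)
          if (r1 == a1) stop_ctx("corrupt block: substitution equals backbone")
          if (r1 != "N" && a1 != "N")
            out[[length(out) + 1]] <- list(contig = tc, pos = tpos + j,
                                           ref = r1, alt = a1)
        }
        tpos <- tpos + l
      } else if (k == "ins") {
        if (tpos > 0) {
          anchor <- substr(tseq, tpos, tpos)
          alt <- paste0(anchor, ops$alt[i])
          if (!grepl("N", alt, fixed = TRUE))
            out[[length(out) + 1]] <- list(contig = tc, pos = tpos,
                                           ref = anchor, alt = alt)
        }
      } else { # del
        if (tpos > 0) {
          anchor <- substr(tseq, tpos, tpos)
          ref <- paste0(anchor, substr(tseq, tpos + 1, tpos + l))
          if (!grepl("N", ref, fixed = TRUE))
            out[[length(out) + 1]] <- list(contig = tc, pos = tpos,
                                           ref = ref, alt = anchor)
        }
        tpos <- tpos + l
      }
    }
  }
  if (length(out) == 0) return(empty_variant_df())
  d <- new_df(contig = vapply(out, `[[`, character(1), "contig"),
              pos = vapply(out, `[[`, numeric(1), "pos"),
              ref = vapply(out, `[[`, character(1), "ref"),
              alt = vapply(out, `[[`, character(1), "alt"))
  # ref must match the backbone
  chk <- vapply(seq_len(nrow(d)), function(i) {
    substr(backbone$seqs[[d$contig[i]]], d$pos[i], d$pos[i] + nchar(d$ref[i]) - 1)
  }, character(1))
  if (any(chk != d$ref)) stop_ctx("corrupt block: ref does not match backbone")
  d$vtype <- ifelse(nchar(d$ref) == nchar(d$alt), "SNV",
                    ifelse(nchar(d$alt) > nchar(d$ref), "INS", "DEL"))
  d$sv <- abs(nchar(d$ref) - nchar(d$alt)) >= sv_min_len
  d$support <- query_id
  d$tie <- FALSE
  d[order(d$contig, d$pos), , drop = FALSE]
}

# left-align + parsimony for one indel record; returns c(pos, ref, alt)
normalize_one <- function(seq, pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1 || na > 1)) {
      ref <- substr(ref, 1, nr - 1); alt <- substr(alt, 1, na - 1)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (pos == 1) { # cannot extend further left; undo
          b <- substr(seq, pos, pos) # should not happen for anchored records
          ref <- paste0(ref, b); alt <- paste0(alt, b)
          break
        }
        pos <- pos - 1
        b <- substr(seq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substring(ref, 2); alt <- substring(alt, 2); pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant representation
#'
#' Indels are left-aligned to the smallest position yielding an identical
#' alternate haplotype and reduced to their parsimonious representation;
#' SNVs are unchanged. Idempotent.
#'
#' @param variants variant data.frame.
#' @param backbone backbone [assembly()].
#' @return normalized variant data.frame, sorted by contig and position.
#' @export
normalize_variants <- function(variants, backbone) {
  if (nrow(variants) == 0) return(variants)
  d <- variants
  for (i in seq_len(nrow(d))) {
    if (nchar(d$ref[i]) == nchar(d$alt[i]) && nchar(d$ref[i]) == 1) next
    nm <- normalize_one(backbone$seqs[[d$contig[i]]], d$pos[i], d$ref[i], d$alt[i])
    d$pos[i] <- nm$pos; d$ref[i] <- nm$ref; d$alt[i] <- nm$alt
  }
  d$vtype <- ifelse(nchar(d$ref) == nchar(d$alt) & nchar(d$ref) == 1, "SNV",
                    ifelse(nchar(d$alt) > nchar(d$ref), "INS", "DEL"))
  if (!is.null(d$sv)) d$sv <- abs(nchar(d$ref) - nchar(d$alt)) >= 51
  d[order(d$contig, d$pos, nchar(d$ref), d$alt), , drop = FALSE]
}

#' Group per-assembly variants into biallelic records and a multiallelic
#' registry
#'
#' Identical (contig, pos, ref, alt) records from different assemblies are
#' merged with a combined support set; distinct alternate alleles at one
#' normalized site stay separate records and the site is counted in the
#' multiallelic registry.
#'
#' @param variants combined normalized variant data.frame (one record per
#'   assembly occurrence, `support` holding the assembly id).
#' @return list with `variants` (merged, support comma-joined, support_n) and
#'   `multiallelic_sites` (contig, pos, n_alleles).
#' @export
split_multiallelic <- function(variants) {
  if (nrow(variants) == 0) {
    v <- empty_variant_df(); v$support_n <- integer(0)
    return(list(variants = v,
                multiallelic_sites = new_df(contig = character(),
                                            pos = integer(),
                                            n_alleles = integer())))
  }
  key <- paste(variants$contig, variants$pos, variants$ref, variants$alt,
               sep = "\r")
  first <- !duplicated(key)
  supp <- vapply(split(variants$support, key)[unique(key)],
                 function(s) paste(sort(unique(s)), collapse = ","),
                 character(1))
  d <- variants[first, , drop = FALSE]
  d$support <- unname(supp)
  d$support_n <- lengths(strsplit(d$support, ",", fixed = TRUE))
  skey <- paste(d$contig, d$pos, sep = "\r")
  na <- table(skey)
  multi <- names(na)[na >= 2]
  parts <- strsplit(multi, "\r", fixed = TRUE)
  reg <- new_df(contig = vapply(parts, `[`, character(1), 1),
                pos = as.integer(vapply(parts, `[`, character(1), 2)),
                n_alleles = as.integer(na[multi]))
  d <- d[order(d$contig, d$pos, nchar(d$ref), d$alt), , drop = FALSE]
  rownames(d) <- NULL
  list(variants = d, multiallelic_sites = reg[order(reg$contig, reg$pos), ,
                                              drop = FALSE])
}
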