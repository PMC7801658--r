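# Majority vote across N assemblies, seeded tie-breaking, consensus
# application with coordinate tracking.

#' Vote major alleles across assemblies
#'
#' An allele supported by at least `min_share` assemblies becomes a major
#' allele. A site where at least two distinct alternate alleles are observed
#' but none reaches `min_share` is a tie site; a site with a single alternate
#' allele below `min_share` keeps the backbone allele. Allele identity is
#' decided after normalization, so voting is representation-invariant.
#'
#' @param variants_per_assembly named list of normalized variant data.frames
#'   (one per assembly), all called against the same backbone.
#' @param n_assemblies N.
#' @param min_share majority threshold (default `floor(N/2) + 1`).
#' @param include_backbone include the backbone allele as a tie candidate
#'   (default TRUE).
#' @return list with `major` (variant data.frame with support/support_n),
#'   `ties` (candidate data.frame, one row per candidate allele, backbone
#'   candidates marked with `is_backbone`), and `multiallelic_sites`.
#' @export
vote_major_alleles <- function(variants_per_assembly, n_assemblies,
                               min_share = floor(n_assemblies / 2) + 1,
                               include_backbone = TRUE) {
  if (min_share > n_assemblies) stop_ctx("min_share exceeds the number of assemblies")
  ids <- names(variants_per_assembly)
  if (is.null(ids)) stop_ctx("variants_per_assembly must be a named list")
  all <- do.call(rbind, lapply(ids, function(id) {
    v <- variants_per_assembly[[id]]
    if (nrow(v) == 0) return(NULL)
    v$support <- id
    v[, c("contig", "pos", "ref", "alt", "vtype", "sv", "support", "tie")]
  }))
  if (is.null(all)) all <- empty_variant_df()
  sm <- split_multiallelic(all)
  d <- sm$variants
  skey <- paste(d$contig, d$pos, sep = "\r")
  major_keep <- logical(nrow(d))
  tie_rows <- list()
  for (grp in split(seq_len(nrow(d)), skey)) {
    sn <- d$support_n[grp]
    if (max(sn) >= min_share) {
      top <- grp[sn == max(sn)]
      if (length(top) == 1) {
        major_keep[top] <- TRUE
      } else {
        tie_rows[[length(tie_rows) + 1]] <- top  # co-equal majors: tie site
      }
    } else if (length(grp) >= 2) {
      tie_rows[[length(tie_rows) + 1]] <- grp
    } # single sub-threshold allele: backbone retained
  }
  ties <- if (length(tie_rows)) {
    td <- d[unlist(tie_rows), , drop = FALSE]
    td$is_backbone <- FALSE
    if (include_backbone) {
      sites <- unique(td[, c("contig", "pos")])
      bb <- td[!duplicated(paste(td$contig, td$pos, sep = "\r")), , drop = FALSE]
      bb$alt <- bb$ref <- substr(bb$ref, 1, 1)
      bb$vtype <- "BACKBONE"; bb$sv <- FALSE; bb$support <- ""
      bb$support_n <- 0L; bb$is_backbone <- TRUE
      td <- rbind(td, bb)
    }
    td[order(td$contig, td$pos, td$is_backbone, nchar(td$ref), td$alt), ,
       drop = FALSE]
  } else {
    v <- empty_variant_df(); v$support_n <- integer(0); v$is_backbone <- logical(0)
    v
  }
  major <- d[major_keep, , drop = FALSE]
  rownames(major) <- rownames(ties) <- NULL
  list(major = major, ties = ties, multiallelic_sites = sm$multiallelic_sites)
}

#' Break tie sites by seeded uniform random choice
#'
#' Candidates at each tie site (including the backbone allele when present)
#' are drawn uniformly. Identical (sites, seed) inputs give identical
#' choices. Chosen non-backbone alleles carry `tie = TRUE`.
#'
#' @param ties candidate data.frame from [vote_major_alleles()].
#' @param seed integer seed (required).
#' @return list with `chosen` (variant records to apply) and `log` (one row
#'   per site: candidates, chosen allele, whether backbone was chosen).
#' @export
break_ties <- function(ties, seed) {
  if (missing(seed) || is.null(seed)) stop_ctx("break_ties requires a seed")
  if (nrow(ties) == 0) {
    ch <- empty_variant_df(); ch$support_n <- integer(0)
    return(list(chosen = ch,
                log = new_df(contig = character(), pos = integer(),
                             n_candidates = integer(), candidates = character(),
                             chosen = character(), backbone_chosen = logical())))
  }
  skey <- paste(ties$contig, ties$pos, sep = "\r")
  sites <- unique(skey)
  chosen_idx <- integer(0)
  log <- vector("list", length(sites))
  with_seed(seed, {
    for (si in seq_along(sites)) {
      grp <- which(skey == sites[si])
      if (length(grp) == 0) stop_ctx("empty candidate set")
      pick <- grp[sample.int(length(grp), 1)]
      log[[si]] <- new_df(
        contig = ties$contig[grp[1]], pos = ties$pos[grp[1]],
        n_candidates = length(grp),
        candidates = paste(ifelse(ties$is_backbone[grp], "<backbone>",
                                  paste0(ties$ref[grp], ">", ties$alt[grp])),
                           collapse = ","),
        chosen = if (ties$is_backbone[pick]) "<backbone>"
                 else paste0(ties$ref[pick], ">", ties$alt[pick]),
        backbone_chosen = ties$is_backbone[pick])
      if (!ties$is_backbone[pick]) chosen_idx <- c(chosen_idx, pick)
    }
  })
  chosen <- ties[chosen_idx, , drop = FALSE]
  chosen$is_backbone <- NULL
  if (nrow(chosen)) chosen$tie <- TRUE
  rownames(chosen) <- NULL
  list(chosen = chosen, log = do.call(rbind, log))
}

#' Apply major variants to the backbone
#'
#' Variants must be normalized and sorted; overlapping records are resolved
#' coordinate-sorted first-wins (the dropped records are returned and a
#' warning is raised). Returns the consensus assembly and a coordinate map
#' that exactly reflects the length changes.
#'
#' @param backbone backbone [assembly()].
#' @param variants variant data.frame to substitute.
#' @param name name for the consensus assembly.
#' @return list with `consensus` ([assembly()]), `coordmap` (see
#'   [map_point()]), `dropped` (overlap-dropped records).
#' @export
apply_variants <- function(backbone, variants, name = "consensus") {
  v <- variants[order(variants$contig, variants$pos, -nchar(variants$ref),
                      variants$alt), , drop = FALSE]
  dropped <- list()
  segs <- list()
  out_seqs <- character(0)
  for (cn in names(backbone$seqs)) {
    seq <- backbone$seqs[[cn]]
    vc <- v[v$contig == cn, , drop = FALSE]
    parts <- character(0)
    b <- 0; cpos <- 0  # 0-based cursors on backbone / consensus
    for (i in seq_len(nrow(vc))) {
      p0 <- vc$pos[i] - 1                     # 0-based start of ref span
      span <- nchar(vc$ref[i])
      if (p0 < b) {                           # overlap: first-wins
        dropped[[length(dropped) + 1]] <- vc[i, , drop = FALSE]
        next
      }
      if (substr(seq, p0 + 1, p0 + span) != vc$ref[i])
        stop_ctx("variant ref does not match backbone at ", cn, ":", vc$pos[i])
      pre <- p0 - b
      # aligned run: untouched prefix plus the anchor/substituted base(s)
      ref <- vc$ref[i]; alt <- vc$alt[i]
      if (nchar(ref) == nchar(alt)) {         # SNV / MNV: coordinate-preserving
        parts <- c(parts, substr(seq, b + 1, p0), alt)
        segs[[length(segs) + 1]] <- new_df(contig = cn, b_start = b,
                                           c_start = cpos, len = pre + span)
        b <- p0 + span; cpos <- cpos + pre + span
      } else {
        anchor_len <- 1
        parts <- c(parts, substr(seq, b + 1, p0), alt)
        segs[[length(segs) + 1]] <- new_df(contig = cn, b_start = b,
                                           c_start = cpos, len = pre + anchor_len)
        b <- p0 + span
        cpos <- cpos + pre + nchar(alt)
      }
    }
    tail_len <- nchar(seq) - b
    parts <- c(parts, substr(seq, b + 1, nchar(seq)))
    if (tail_len > 0)
      segs[[length(segs) + 1]] <- new_df(contig = cn, b_start = b,
                                         c_start = cpos, len = tail_len)
    out_seqs[[cn]] <- paste(parts, collapse = "")
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    v[0, , drop = FALSE]
  if (nrow(dropped))
    warning(nrow(dropped), " overlapping variant(s) dropped (first-wins)")
  consensus <- assembly(name, out_seqs)
  coordmap <- structure(list(segments = do.call(rbind, segs),
                             backbone_len = contig_lengths(backbone),
                             consensus_len = contig_lengths(consensus)),
                        class = "coordmap")
  list(consensus = consensus, coordmap = coordmap, dropped = dropped)
}

#' Map backbone points through a coordinate map
#'
#' @param coordmap from [apply_variants()].
#' @param contig contig name (scalar).
#' @param pos 0-based positions.
#' @param reverse map consensus -> backbone instead.
#' @return integer positions (NA where the point falls in an unaligned
#'   segment, e.g. inside a deleted span).
#' @export
map_point <- function(coordmap, contig, pos, reverse = FALSE) {
  s <- coordmap$segments[coordmap$segments$contig == contig, , drop = FALSE]
  from <- if (reverse) s$c_start else s$b_start
  to <- if (reverse) s$b_start else s$c_start
  idx <- findInterval(pos, from)
  out <- rep(NA_integer_, length(pos))
  ok <- idx >= 1
  okk <- ok & pos < from[pmax(idx, 1)] + s$len[pmax(idx, 1)]
  out[okk] <- to[idx[okk]] + (pos[okk] - from[idx[okk]])
  out
}

#' Summarize major variants by support level
#'
#' @param major variant data.frame with `support_n` (or comma-joined
#'   `support`).
#' @param n_assemblies N.
#' @param digits decimals for the percentage (default 0, matching how such
#'   shares are conventionally reported).
#' @return data.frame with support_level, count, pct.
#' @export
support_summary <- function(major, n_assemblies, digits = 0) {
  if (nrow(major) == 0) stop_ctx("no variants to summarize")
  sn <- major$support_n %||% lengths(strsplit(major$support, ",", fixed = TRUE))
  total <- length(sn)
  lev <- seq_len(n_assemblies)
  cnt <- vapply(lev, function(l) sum(sn == l), integer(1))
  new_df(support_level = lev, count = cnt,
         pct = round(100 * cnt / total, digits))
}

#' Expected number of erroneous random tie choices
#'
#' For a tie site with m candidates, the error probability of a uniform
#' choice is 1 - (1/m) if the panel-major allele is among the candidates and
#' 1 otherwise. Sites absent from the panel are counted separately and
#' excluded from the sum.
#'
#' @param ties candidate data.frame from [vote_major_alleles()].
#' @param panel AF panel from [read_af_panel()].
#' @return list with `expected_errors`, `per_site` table, `n_missing`.
#' @export
expected_tie_errors <- function(ties, panel) {
  if (nrow(ties) == 0)
    return(list(expected_errors = 0,
                per_site = new_df(contig = character(), pos = integer(),
                                  m = integer(), panel_major = character(),
                                  in_candidates = logical(), p_err = numeric()),
                n_missing = 0L))
  skey <- paste(ties$contig, ties$pos, sep = "\r")
  pkey <- paste(panel$contig, panel$pos, sep = "\r")
  rows <- list(); n_missing <- 0L
  for (sk in unique(skey)) {
    grp <- which(skey == sk)
    prow <- which(pkey == sk)
    contig <- ties$contig[grp[1]]; pos <- ties$pos[grp[1]]
    if (length(prow) == 0) { n_missing <- n_missing + 1L; next }
    ref <- panel$ref[prow[1]]
    freqs <- c(setNames(1 - sum(panel$af[prow]), ref),
               setNames(panel$af[prow], panel$alt[prow]))
    panel_major <- names(freqs)[which.max(freqs)]
    cand <- ifelse(ties$is_backbone[grp], ties$ref[grp], ties$alt[grp])
    m <- length(grp)
    inc <- panel_major %in% cand
    rows[[length(rows) + 1]] <- new_df(contig = contig, pos = pos, m = m,
                                       panel_major = panel_major,
                                       in_candidates = inc,
                                       p_err = 1 - (1 / m) * inc)
  }
  per_site <- if (length(rows)) do.call(rbind, rows) else
    new_df(contig = character(), pos = integer(), m = integer(),
           panel_major = character(), in_candidates = logical(),
           p_err = numeric())
  list(expected_errors = sum(per_site$p_err), per_site = per_site,
       n_missing = n_missing)
}
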