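# In-silico STS PCR: a marker amplifies where its forward primer and the
# reverse complement of its reverse primer occur on opposite strands,
# correctly oriented toward each other, each within the mismatch budget and
# with an exact 3'-terminal block, and with an amplicon size inside the
# marker's expected window.

#' Scan an assembly for in-silico STS marker amplification
#'
#' @param markers marker data.frame (see [read_marker_table()]); scanned per
#'   distinct (marker_id, primer pair).
#' @param assembly [assembly()] to scan.
#' @param max_mismatch per-primer mismatch budget (default 1).
#' @param three_prime_exact exact 3'-terminal bases required (default 3).
#' @param size_tolerance relative half-width of the amplicon size window
#'   around the expected size (default 0.5).
#' @param max_amplicon size cap when no expected size is given (default 5 kb).
#' @return data.frame of hits: marker_id, scaffold, start, end (0-based
#'   half-open amplicon incl. both primers), strand, mismatches_fwd,
#'   mismatches_rev.
#' @export
epcr_scan <- function(markers, assembly, max_mismatch = 1,
                      three_prime_exact = 3, size_tolerance = 0.5,
                      max_amplicon = 5000) {
  stopifnot(inherits(assembly, "assembly"))
  mk <- markers[!duplicated(markers$marker_id), , drop = FALSE]
  if (any(nchar(mk$primer_fwd) < 15 | nchar(mk$primer_rev) < 15))
    stop_ctx("primers must be >= 15 bp")
  hits <- list()
  for (i in seq_len(nrow(mk))) {
    pf <- mk$primer_fwd[i]; pr <- mk$primer_rev[i]
    mf <- nchar(pf); mr <- nchar(pr)
    lo <- if (!is.na(mk$size_min[i])) floor((1 - size_tolerance) * mk$size_min[i])
          else mf + mr
    hi <- if (!is.na(mk$size_max[i])) ceiling((1 + size_tolerance) * mk$size_max[i])
          else max_amplicon
    for (cn in names(assembly$seqs)) {
      s <- assembly$seqs[[cn]]
      pair_up <- function(left, right, rlen, llen) {
        # left starts a, right starts b; amplicon [a, b + rlen)
        out <- list()
        for (ai in seq_len(nrow(left))) {
          a <- left$start[ai]
          b <- right[right$start >= a + llen, , drop = FALSE]
          size <- b$start + rlen - a
          keep <- size >= lo & size <= hi
          if (any(keep))
            out[[length(out) + 1]] <- new_df(start = a, end = b$start[keep] + rlen,
                                             mm_left = left$mm[ai],
                                             mm_right = b$mm[keep])
        }
        if (length(out)) do.call(rbind, out) else NULL
      }
      # '+' orientation: fwd primer then rc(rev)
      fw <- cpp_primer_matches(s, pf, max_mismatch, three_prime_exact, FALSE)
      if (nrow(fw)) {
        rcrev <- cpp_primer_matches(s, revcomp(pr), max_mismatch,
                                    three_prime_exact, TRUE)
        p <- pair_up(fw, rcrev, mr, mf)
        if (!is.null(p))
          hits[[length(hits) + 1]] <- new_df(marker_id = mk$marker_id[i],
                                             scaffold = cn, start = p$start,
                                             end = p$end, strand = "+",
                                             mismatches_fwd = p$mm_left,
                                             mismatches_rev = p$mm_right)
      }
      # '-' orientation: rev primer then rc(fwd)
      rv <- cpp_primer_matches(s, pr, max_mismatch, three_prime_exact, FALSE)
      if (nrow(rv)) {
        rcfwd <- cpp_primer_matches(s, revcomp(pf), max_mismatch,
                                    three_prime_exact, TRUE)
        p <- pair_up(rv, rcfwd, mf, mr)
        if (!is.null(p))
          hits[[length(hits) + 1]] <- new_df(marker_id = mk$marker_id[i],
                                             scaffold = cn, start = p$start,
                                             end = p$end, strand = "-",
                                             mismatches_fwd = p$mm_right,
                                             mismatches_rev = p$mm_left)
      }
    }
  }
  if (length(hits) == 0)
    return(new_df(marker_id = character(), scaffold = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches_fwd = integer(), mismatches_rev = integer()))
  d <- do.call(rbind, hits)
  d[order(d$marker_id, d$scaffold, d$start), , drop = FALSE]
}

# markers amplifying on more than one scaffold are ambiguous for anchoring
drop_ambiguous_hits <- function(hits) {
  nsc <- tapply(hits$scaffold, hits$marker_id, function(s) length(unique(s)))
  ambiguous <- names(nsc)[nsc > 1]
  list(hits = hits[!hits$marker_id %in% ambiguous, , drop = FALSE],
       ambiguous = ambiguous)
}

#' Flag chimeric scaffolds from marker hits
#'
#' A scaffold is flagged when at least `min_markers` distinct markers from
#' each of two or more linkage groups amplify on it.
#'
#' @param hits from [epcr_scan()].
#' @param markers marker table.
#' @param min_markers markers per linkage group required (default 2).
#' @return data.frame: scaffold, flagged, breakdown ("lg:count" pairs).
#' @export
flag_chimeric_scaffolds <- function(hits, markers, min_markers = 2) {
  j <- merge(hits, markers[, c("marker_id", "linkage_group")], by = "marker_id")
  j <- j[!duplicated(paste(j$scaffold, j$marker_id, j$linkage_group)), ]
  out <- lapply(split(j, j$scaffold), function(d) {
    cnt <- table(tapply(d$linkage_group, d$marker_id, `[`, 1))
    new_df(scaffold = d$scaffold[1],
           flagged = sum(cnt >= min_markers) >= 2,
           breakdown = paste(paste0(names(cnt), ":", as.integer(cnt)),
                             collapse = ","))
  })
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Assign scaffolds to chromosomes by weighted marker vote
#'
#' Each hit contributes the weight of its map's type (default genetic 5,
#' RH 1), once per (marker, map). The chromosome is the weighted argmax;
#' exact ties leave the scaffold unplaced (with a warning).
#'
#' @param hits from [epcr_scan()] (ambiguous markers removed internally).
#' @param markers marker table.
#' @param weights named vector, weight per map_type.
#' @return data.frame: scaffold, chromosome (NA if unplaced), score.
#' @export
assign_chromosome <- function(hits, markers, weights = c(genetic = 5, RH = 1)) {
  if (nrow(hits) == 0)
    return(new_df(scaffold = character(), chromosome = character(),
                  score = numeric()))
  da <- drop_ambiguous_hits(hits)
  j <- merge(da$hits, markers, by = "marker_id")
  j$w <- unname(weights[j$map_type])
  out <- lapply(split(j, j$scaffold), function(d) {
    sc <- tapply(d$w, d$linkage_group, sum)
    best <- max(sc)
    top <- names(sc)[sc == best]
    if (length(top) > 1) {
      warning("scaffold ", d$scaffold[1], ": weighted tie between ",
              paste(top, collapse = ","), "; left unplaced")
      top <- NA_character_
    }
    new_df(scaffold = d$scaffold[1], chromosome = top, score = best)
  })
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my))
  cx <- sum(w * (x - mx)^2); cy <- sum(w * (y - my)^2)
  if (cx == 0 || cy == 0) return(NA_real_)
  cxy / sqrt(cx * cy)
}

#' Order and orient assigned scaffolds into an anchor plan
#'
#' Scaffolds are ordered within each chromosome by the weighted mean of
#' their hit markers' map positions; orientation is the sign of the
#' weight-combined per-map Pearson correlation between the within-scaffold
#' amplicon coordinate and the map position (fewer than 2 usable markers:
#' '+').
#'
#' @param assigned from [assign_chromosome()].
#' @param hits from [epcr_scan()].
#' @param markers marker table.
#' @param weights named vector, weight per map_type.
#' @param gap_size gap inserted between scaffolds (default 10000).
#' @return `anchor_plan`: list with `plan` (chromosome, scaffold, orientation,
#'   position_score, in order), `gap_size`, `unplaced`, `ambiguous_markers`.
#' @export
order_orient <- function(assigned, hits, markers,
                         weights = c(genetic = 5, RH = 1), gap_size = 10000) {
  da <- drop_ambiguous_hits(hits)
  j <- merge(da$hits, markers, by = "marker_id")
  j$w <- unname(weights[j$map_type])
  j <- merge(j, assigned, by = "scaffold")
  j <- j[!is.na(j$chromosome) & j$linkage_group == j$chromosome, , drop = FALSE]
  # maps use different units (cM vs cR); rescale each (map, chromosome) to
  # [0, 1] over the full marker table before mixing them in a weighted mean
  mkey <- paste(markers$map_id, markers$linkage_group, sep = "\r")
  lo <- tapply(markers$map_position, mkey, min)
  hi <- tapply(markers$map_position, mkey, max)
  jkey <- paste(j$map_id, j$linkage_group, sep = "\r")
  span <- pmax(hi[jkey] - lo[jkey], 1e-12)
  j$map_norm <- unname((j$map_position - lo[jkey]) / span)
  rows <- lapply(split(j, j$scaffold), function(d) {
    score <- sum(d$w * d$map_norm) / sum(d$w)
    rs <- vapply(split(d, d$map_id), function(m) {
      if (nrow(m) < 2) return(NA_real_)
      weighted_pearson((m$start + m$end) / 2, m$map_position, m$w)
    }, numeric(1))
    wmap <- vapply(split(d, d$map_id), function(m) m$w[1], numeric(1))
    use <- !is.na(rs)
    ori <- if (!any(use)) "+" else if (sum(wmap[use] * rs[use]) >= 0) "+" else "-"
    new_df(chromosome = d$chromosome[1], scaffold = d$scaffold[1],
           orientation = ori, position_score = score)
  })
  plan <- do.call(rbind, rows)
  plan <- plan[order(plan$chromosome, plan$position_score, plan$scaffold), ,
               drop = FALSE]
  rownames(plan) <- NULL
  unplaced <- assigned$scaffold[is.na(assigned$chromosome)]
  structure(list(plan = plan, gap_size = gap_size, unplaced = unplaced,
                 ambiguous_markers = da$ambiguous), class = "anchor_plan")
}

#' Co-linearity between anchored scaffolds and marker maps
#'
#' Pearson correlation, per (map, chromosome), between the pseudo-molecule
#' coordinate of each hit and its map position; |r| is reported (orientation
#' applied by the plan). Pairs with fewer than 2 markers are excluded.
#'
#' @param anchor_plan from [order_orient()].
#' @param hits from [epcr_scan()].
#' @param markers marker table.
#' @param scaffold_lengths named lengths of the scaffolds in the plan.
#' @return list with `per_map` (map_id, map_type, chromosome, r, n) and
#'   `summary` (map_type, mean_r, sd_r).
#' @export
colinearity <- function(anchor_plan, hits, markers, scaffold_lengths) {
  plan <- anchor_plan$plan
  gap <- anchor_plan$gap_size
  offs <- list()
  for (chrom in unique(plan$chromosome)) {
    p <- plan[plan$chromosome == chrom, , drop = FALSE]
    off <- 0
    for (i in seq_len(nrow(p))) {
      offs[[p$scaffold[i]]] <- list(chromosome = chrom, offset = off,
                                    orientation = p$orientation[i],
                                    len = scaffold_lengths[[p$scaffold[i]]])
      off <- off + scaffold_lengths[[p$scaffold[i]]] + gap
    }
  }
  da <- drop_ambiguous_hits(hits)
  j <- merge(da$hits, markers, by = "marker_id")
  j <- j[j$scaffold %in% names(offs), , drop = FALSE]
  pm <- vapply(seq_len(nrow(j)), function(i) {
    o <- offs[[j$scaffold[i]]]
    mid <- (j$start[i] + j$end[i]) / 2
    if (o$orientation == "+") o$offset + mid else o$offset + o$len - mid
  }, numeric(1))
  j$pseudo_coord <- pm
  j$chromosome <- vapply(j$scaffold, function(s) offs[[s]]$chromosome,
                         character(1))
  j <- j[j$linkage_group == j$chromosome, , drop = FALSE]
  per <- lapply(split(j, paste(j$map_id, j$chromosome, sep = "\r")),
                function(d) {
    if (nrow(d) < 2) return(NULL)
    new_df(map_id = d$map_id[1], map_type = d$map_type[1],
           chromosome = d$chromosome[1],
           r = abs(cor(d$pseudo_coord, d$map_position)), n = nrow(d))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$map_type), function(d)
    new_df(map_type = d$map_type[1], mean_r = mean(d$r), sd_r = sd(d$r))))
  rownames(summ) <- NULL
  list(per_map = per, summary = summ)
}

#' Build pseudo-molecules from an anchor plan
#'
#' Scaffolds are concatenated in plan order and orientation with
#' `gap_size` Ns between consecutive scaffolds; AGP 2.1 rows alternate W/N.
#' Unplaced scaffolds are carried over unchanged.
#'
#' @param anchor_plan from [order_orient()].
#' @param assembly scaffold [assembly()].
#' @param gap_size override the plan's gap size.
#' @param name output assembly name.
#' @return list with `assembly` (chromosomes + unplaced) and `agp`.
#' @export
build_pseudomolecules <- function(anchor_plan, assembly, gap_size = NULL,
                                  name = "anchored") {
  plan <- anchor_plan$plan
  gap <- gap_size %||% anchor_plan$gap_size
  miss <- setdiff(plan$scaffold, names(assembly$seqs))
  if (length(miss)) stop_ctx("scaffold missing from assembly: ",
                             paste(miss, collapse = ","))
  seqs <- character(0)
  agp <- list()
  for (chrom in unique(plan$chromosome)) {
    p <- plan[plan$chromosome == chrom, , drop = FALSE]
    parts <- character(0); pos <- 0; part <- 0
    for (i in seq_len(nrow(p))) {
      if (i > 1) {
        part <- part + 1
        agp[[length(agp) + 1]] <- new_df(object = chrom, object_beg = pos + 1,
                                         object_end = pos + gap,
                                         part_number = part,
                                         component_type = "N",
                                         c6 = as.character(gap),
                                         c7 = "scaffold", c8 = "yes",
                                         c9 = "map")
        parts <- c(parts, strrep("N", gap)); pos <- pos + gap
      }
      s <- assembly$seqs[[p$scaffold[i]]]
      if (p$orientation[i] == "-") s <- revcomp(s)
      part <- part + 1
      agp[[length(agp) + 1]] <- new_df(object = chrom, object_beg = pos + 1,
                                       object_end = pos + nchar(s),
                                       part_number = part,
                                       component_type = "W",
                                       c6 = p$scaffold[i], c7 = "1",
                                       c8 = as.character(nchar(s)),
                                       c9 = p$orientation[i])
      parts <- c(parts, s); pos <- pos + nchar(s)
    }
    seqs[[chrom]] <- paste(parts, collapse = "")
  }
  placed <- plan$scaffold
  for (cn in setdiff(names(assembly$seqs), placed))
    seqs[[cn]] <- assembly$seqs[[cn]]
  list(assembly = assembly(name, seqs), agp = do.call(rbind, agp))
}

#' Mask intervals with N
#'
#' @param x [assembly()].
#' @param intervals data.frame with contig, start, end (0-based half-open).
#' @return masked assembly (length unchanged).
#' @export
mask_intervals <- function(x, intervals) {
  stopifnot(inherits(x, "assembly"))
  seqs <- x$seqs
  for (i in seq_len(nrow(intervals))) {
    cn <- intervals$contig[i]
    s <- seqs[[cn]]
    if (is.null(s)) stop_ctx("unknown contig: ", cn)
    st <- intervals$start[i]; en <- intervals$end[i]
    if (st < 0 || en > nchar(s) || en <= st)
      stop_ctx("mask interval out of range on ", cn)
    substr(s, st + 1, en) <- strrep("N", en - st)
    seqs[[cn]] <- s
  }
  assembly(x$name, seqs, x$softmask)
}

#' Rotate a circular sequence to start at an anchor subsequence
#'
#' @param seq sequence string.
#' @param anchor_subseq subsequence that must occur exactly once (searching
#'   the doubled sequence, i.e. across the origin).
#' @return rotated sequence (same length and base multiset).
#' @export
rotate_circular <- function(seq, anchor_subseq) {
  n <- nchar(seq)
  if (nchar(anchor_subseq) > n) stop_ctx("anchor longer than sequence")
  doubled <- paste0(seq, substr(seq, 1, nchar(anchor_subseq) - 1))
  m <- gregexpr(anchor_subseq, doubled, fixed = TRUE)[[1]]
  if (m[1] == -1) stop_ctx("anchor not found")
  if (length(m) > 1) stop_ctx("anchor occurs more than once")
  p <- m[1]
  if (p == 1) return(seq)
  paste0(substr(seq, p, n), substr(seq, 1, p - 1))
}

#' Resize named N-gap runs
#'
#' @param x [assembly()].
#' @param gap_spec data.frame with contig, gap_index (1-based index of the
#'   N-run within the contig), new_len.
#' @return list with `assembly` and `report` (inserted N totals per edit).
#' @export
resize_gaps <- function(x, gap_spec) {
  stopifnot(inherits(x, "assembly"))
  if (is.null(gap_spec) || nrow(gap_spec) == 0)
    return(list(assembly = x, report = new_df(contig = character(),
                                              gap_index = integer(),
                                              old_len = integer(),
                                              new_len = integer())))
  seqs <- x$seqs
  report <- list()
  for (cn in unique(gap_spec$contig)) {
    s <- seqs[[cn]]
    if (is.null(s)) stop_ctx("unknown contig: ", cn)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "N")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    gs <- starts[r$values]; ge <- ends[r$values]
    spec <- gap_spec[gap_spec$contig == cn, , drop = FALSE]
    if (any(spec$gap_index < 1 | spec$gap_index > length(gs)))
      stop_ctx("gap_index out of range on ", cn, " (", length(gs), " N-runs)")
    # apply right-to-left so earlier coordinates stay valid
    for (i in order(spec$gap_index, decreasing = TRUE)) {
      gi <- spec$gap_index[i]
      old_len <- ge[gi] - gs[gi]
      s <- paste0(substr(s, 1, gs[gi]), strrep("N", spec$new_len[i]),
                  substr(s, ge[gi] + 1, nchar(s)))
      report[[length(report) + 1]] <- new_df(contig = cn, gap_index = gi,
                                             old_len = old_len,
                                             new_len = spec$new_len[i])
    }
    seqs[[cn]] <- s
  }
  list(assembly = assembly(x$name, seqs),
       report = do.call(rbind, report))
}
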