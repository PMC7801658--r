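# Lightweight whole-assembly pairwise alignment: unique k-mer anchors are
# merged into maximal exact matches, chained by weighted LIS, and inter-anchor
# gaps are closed with banded affine-gap global alignment. Produces the same
# role of alignment blocks as an asm5-style aligner at desk scale; external
# PAF (+cs) is accepted as a bypass via read_paf()/paf_to_blocks().

#' Alignment parameters
#'
#' Scoring mimics asm5-like behaviour on >= 95%-identity pairs: match 0,
#' mismatch 4, gap open 4, gap extend 2 (cost minimisation).
#'
#' @param k anchor k-mer size (>= 11).
#' @param mismatch,gap_open,gap_ext affine alignment costs.
#' @param band initial alignment band half-width; doubled until the optimal
#'   path stays inside the band.
#' @param max_band_cells cell budget per gap alignment; beyond it the gap pair
#'   is emitted as paired ins+del.
#' @param max_gap maximum inter-anchor gap closed by alignment (bp).
#' @param min_match minimum matched bases for a block to be reported.
#' @return parameter list.
#' @export
align_params <- function(k = 19, mismatch = 4, gap_open = 4, gap_ext = 2,
                         band = 32, max_band_cells = 6.4e7, max_gap = 50000,
                         min_match = 100) {
  list(k = k, mismatch = mismatch, gap_open = gap_open, gap_ext = gap_ext,
       band = band, max_band_cells = max_band_cells, max_gap = max_gap,
       min_match = min_match)
}

#' Find exact k-mer anchors between two sequences
#'
#' Only k-mers unique in the target are used; k-mers containing N are skipped.
#' Reverse-strand anchors are reported with `qpos` on the original query
#' coordinates (position of the k-mer's first base on the forward strand).
#'
#' @param query_seq,target_seq uppercase sequences.
#' @param k k-mer size (>= 11).
#' @return data.frame with qpos, tpos (0-based), strand.
#' @export
find_anchors <- function(query_seq, target_seq, k = 19) {
  if (k < 11) stop_ctx("k must be >= 11")
  if (k > min(nchar(query_seq), nchar(target_seq)))
    stop_ctx("k exceeds sequence length")
  expand <- function(seg, strand, qlen) {
    if (nrow(seg) == 0)
      return(new_df(qpos = integer(), tpos = integer(), strand = character()))
    qp <- integer(0); tp <- integer(0)
    for (i in seq_len(nrow(seg))) {
      n <- seg$len[i] - k + 1
      qp <- c(qp, seg$qstart[i] + 0:(n - 1))
      tp <- c(tp, seg$tstart[i] + 0:(n - 1))
    }
    if (strand == "-") qp <- qlen - (qp + k)
    new_df(qpos = qp, tpos = tp, strand = strand)
  }
  qlen <- nchar(query_seq)
  both <- cpp_mem_anchors_multi(c(query_seq, revcomp(query_seq)), "t",
                                target_seq, as.integer(k))
  rbind(expand(both[[1]], "+", qlen), expand(both[[2]], "-", qlen))
}

#' Chain anchors into the best co-linear subset
#'
#' Weighted LIS maximising anchor count; strictly increasing in both
#' coordinates. Ties are resolved toward smaller target coordinates.
#'
#' @param anchors data.frame with qpos, tpos (one query/target/strand group).
#' @return the retained subset of `anchors`, in chain order.
#' @export
chain_anchors <- function(anchors) {
  if (nrow(anchors) == 0) return(anchors)
  idx <- cpp_chain_segments(as.integer(anchors$qpos), as.integer(anchors$tpos),
                            rep(1L, nrow(anchors)), Inf)
  anchors[idx, , drop = FALSE]
}

#' Globally align two gap sequences with affine gap costs
#'
#' The band is widened (doubled) while the optimal path touches the band
#' boundary; when the cell budget is exhausted the pair is emitted as paired
#' ins+del. Traceback prefers the leftmost placement of indels.
#'
#' @param query_gap,target_gap sequences (either may be "").
#' @param params [align_params()].
#' @return op data.frame (kind/len/alt).
#' @export
extend_align <- function(query_gap, target_gap, params = align_params()) {
  res <- cpp_affine_align(target_gap, query_gap, params$mismatch,
                          params$gap_open, params$gap_ext,
                          as.integer(params$band), params$max_band_cells)
  if (is.null(res)) {
    ops <- ops_df(c("del", "ins"), c(nchar(target_gap), nchar(query_gap)),
                  c("", query_gap))
    return(ops[ops$len > 0, , drop = FALSE])
  }
  kinds <- c("match", "sub", "ins", "del")[res$kind + 1]
  alt <- character(length(kinds))
  qpos <- 0
  for (i in seq_along(kinds)) {
    if (kinds[i] %in% c("match", "sub", "ins")) {
      if (kinds[i] != "match")
        alt[i] <- substr(query_gap, qpos + 1, qpos + res$len[i])
      qpos <- qpos + res$len[i]
    }
  }
  ops_df(kinds, res$len, alt)  # traceback already merges same-kind runs
}

block_identity <- function(ops) {
  cols <- sum(ops$len)
  if (cols == 0) return(0)
  sum(ops$len[ops$kind == "match"]) / cols
}

make_block <- function(qcontig, tcontig, strand, qstart, qend, tstart, tend,
                       ops, qlen) {
  ops <- merge_ops(ops)
  sp <- ops_spans(ops)
  stopifnot(sp[["target"]] == tend - tstart, sp[["query"]] == qend - qstart)
  qs <- if (strand == "+") qstart else qlen - qend
  qe <- if (strand == "+") qend else qlen - qstart
  list(query = list(contig = qcontig, start = qs, end = qe),
       target = list(contig = tcontig, start = tstart, end = tend),
       strand = strand, ops = ops,
       score = sum(ops$len[ops$kind == "match"]),
       identity = block_identity(ops))
}

# chain MEM segments for one oriented query against one target contig and
# close the gaps; returns a block or NULL
chain_to_block <- function(seg, qseq_oriented, tseq, qcontig, tcontig, strand,
                           params) {
  idx <- cpp_chain_segments(seg$qstart, seg$tstart, seg$len, params$max_gap)
  seg <- seg[idx, , drop = FALSE]
  if (nrow(seg) == 0) return(NULL)
  kk <- vector("list", 2 * nrow(seg))
  ll <- vector("list", 2 * nrow(seg))
  aa <- vector("list", 2 * nrow(seg))
  for (i in seq_len(nrow(seg))) {
    if (i > 1) {
      q0 <- seg$qstart[i - 1] + seg$len[i - 1]; q1 <- seg$qstart[i]
      t0 <- seg$tstart[i - 1] + seg$len[i - 1]; t1 <- seg$tstart[i]
      g <- extend_align(substr(qseq_oriented, q0 + 1, q1),
                        substr(tseq, t0 + 1, t1), params)
      kk[[2 * i - 1]] <- g$kind; ll[[2 * i - 1]] <- g$len; aa[[2 * i - 1]] <- g$alt
    }
    kk[[2 * i]] <- "match"; ll[[2 * i]] <- seg$len[i]; aa[[2 * i]] <- ""
  }
  ops <- ops_df(unlist(kk), unlist(ll), unlist(aa))
  qstart <- seg$qstart[1]; qend <- seg$qstart[nrow(seg)] + seg$len[nrow(seg)]
  tstart <- seg$tstart[1]; tend <- seg$tstart[nrow(seg)] + seg$len[nrow(seg)]
  # terminal extension: close short unaligned flanks when both sides present
  ext_left <- function() {
    fq <- qstart; ft <- tstart
    if (fq == 0 || fq > params$max_gap) return(NULL)
    tt <- min(ft, fq + 50)
    if (tt == 0) return(NULL)
    go <- extend_align(substr(qseq_oriented, 1, fq),
                       substr(tseq, ft - tt + 1, ft), params)
    if (block_identity(go) < 0.8) return(NULL)
    list(ops = go, dq = fq, dt = tt)
  }
  ext_right <- function() {
    fq <- nchar(qseq_oriented) - qend; ft <- nchar(tseq) - tend
    if (fq == 0 || fq > params$max_gap) return(NULL)
    tt <- min(ft, fq + 50)
    if (tt == 0) return(NULL)
    go <- extend_align(substr(qseq_oriented, qend + 1, qend + fq),
                       substr(tseq, tend + 1, tend + tt), params)
    if (block_identity(go) < 0.8) return(NULL)
    list(ops = go, dq = fq, dt = tt)
  }
  el <- ext_left()
  if (!is.null(el)) { ops <- rbind(el$ops, ops); qstart <- qstart - el$dq; tstart <- tstart - el$dt }
  er <- ext_right()
  if (!is.null(er)) { ops <- rbind(ops, er$ops); qend <- qend + er$dq; tend <- tend + er$dt }
  make_block(qcontig, tcontig, strand, qstart, qend, tstart, tend, ops,
             nchar(qseq_oriented))
}

#' Align two assemblies
#'
#' Anchors each query contig on both strands against all target contigs,
#' chains, closes gaps, and reports one block per (query contig, target
#' contig) pair on the better strand. Blocks are sorted by target coordinate.
#'
#' @param query,target [assembly()] objects.
#' @param params [align_params()].
#' @return list of alignment blocks.
#' @export
align_genomes <- function(query, target, params = align_params()) {
  stopifnot(inherits(query, "assembly"), inherits(target, "assembly"))
  tnames <- names(target$seqs)
  qnames <- names(query$seqs)
  oriented <- c(unname(query$seqs), revcomp(unname(query$seqs)))
  strands <- rep(c("+", "-"), each = length(qnames))
  qcontigs <- rep(qnames, 2)
  seg_list <- cpp_mem_anchors_multi(oriented, tnames, unname(target$seqs),
                                    as.integer(params$k))
  blocks <- list()
  for (z in seq_along(oriented)) {
    segs <- seg_list[[z]]
    if (nrow(segs) == 0) next
    for (tc in unique(segs$target)) {
      s <- segs[segs$target == tc, , drop = FALSE]
      b <- chain_to_block(s, oriented[[z]], target$seqs[[tc]], qcontigs[z],
                          tc, strands[z], params)
      if (!is.null(b) && b$score >= params$min_match)
        blocks[[length(blocks) + 1]] <- b
    }
  }
  # keep the better strand per contig pair
  if (length(blocks) > 1) {
    key <- vapply(blocks, function(b) paste(b$query$contig, b$target$contig),
                  character(1))
    keep <- unlist(lapply(split(seq_along(blocks), key), function(ii) {
      if (length(ii) == 1) return(ii)
      ii[which.max(vapply(blocks[ii], `[[`, numeric(1), "score"))]
    }), use.names = FALSE)
    blocks <- blocks[sort(keep)]
  }
  ord <- order(vapply(blocks, function(b) b$target$contig, character(1)),
               vapply(blocks, function(b) b$target$start, numeric(1)))
  blocks[ord]
}

#' Resolve block overlaps to a one-to-one cover
#'
#' Greedy by descending score (ties toward smaller target coordinate); a
#' block is retained only if it overlaps no retained block on either the
#' query or the target.
#'
#' @param blocks list of alignment blocks.
#' @return non-redundant subset, sorted by target coordinate.
#' @export
select_primary <- function(blocks) {
  if (length(blocks) <= 1) return(blocks)
  sc <- vapply(blocks, `[[`, numeric(1), "score")
  ts <- vapply(blocks, function(b) b$target$start, numeric(1))
  ord <- order(-sc, ts)
  kept <- list()
  overlaps <- function(a, b) {
    (a$query$contig == b$query$contig &&
       a$query$start < b$query$end && b$query$start < a$query$end) ||
    (a$target$contig == b$target$contig &&
       a$target$start < b$target$end && b$target$start < a$target$end)
  }
  for (i in ord) {
    ok <- TRUE
    for (kb in kept) if (overlaps(blocks[[i]], kb)) { ok <- FALSE; break }
    if (ok) kept[[length(kept) + 1]] <- blocks[[i]]
  }
  ord2 <- order(vapply(kept, function(b) b$target$contig, character(1)),
                vapply(kept, function(b) b$target$start, numeric(1)))
  kept[ord2]
}

#' Convert PAF records (with cs tags) to alignment blocks
#'
#' @param paf list as returned by [read_paf()].
#' @return list of alignment blocks.
#' @export
paf_to_blocks <- function(paf) {
  lapply(paf, function(r) {
    if (is.null(r$ops))
      stop_ctx("PAF record lacks a cs tag; cannot reconstruct ops")
    list(query = list(contig = r$qname, start = r$qstart, end = r$qend),
         target = list(contig = r$tname, start = r$tstart, end = r$tend),
         strand = r$strand, ops = r$ops,
         score = sum(r$ops$len[r$ops$kind == "match"]),
         identity = block_identity(r$ops))
  })
}
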