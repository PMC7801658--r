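# UCSC chain construction from alignment blocks or coordinate maps, and
# interval/annotation lifting between genomes. Chain convention: the target
# (reference) genome is the lift source, the query is the destination;
# '-' strand query coordinates are expressed in the reversed frame.

chain_from_runs <- function(t_name, t_size, t_start, t_end, q_name, q_size,
                            q_strand, q_start, q_end, blocks, chain_id) {
  stopifnot(sum(blocks$size) + sum(blocks$dt, na.rm = TRUE) == t_end - t_start,
            sum(blocks$size) + sum(blocks$dq, na.rm = TRUE) == q_end - q_start)
  structure(list(score = sum(blocks$size), t_name = t_name, t_size = t_size,
                 t_strand = "+", t_start = t_start, t_end = t_end,
                 q_name = q_name, q_size = q_size, q_strand = q_strand,
                 q_start = q_start, q_end = q_end, chain_id = chain_id,
                 blocks = blocks), class = "chain")
}

# ops -> (size, dt, dq) runs; consecutive del/ins collapse into one gap
ops_to_chain_blocks <- function(ops) {
  size <- integer(0); dt <- integer(0); dq <- integer(0)
  cur <- 0L; gt <- 0L; gq <- 0L; open_gap <- FALSE
  flush_gap <- function() {
    size <<- c(size, cur); dt <<- c(dt, gt); dq <<- c(dq, gq)
    cur <<- 0L; gt <<- 0L; gq <<- 0L; open_gap <<- FALSE
  }
  for (i in seq_len(nrow(ops))) {
    k <- ops$kind[i]; l <- ops$len[i]
    if (k %in% c("match", "sub")) {
      if (open_gap) flush_gap()
      cur <- cur + l
    } else if (k == "del") { gt <- gt + l; open_gap <- TRUE }
    else { gq <- gq + l; open_gap <- TRUE }
  }
  if (open_gap) flush_gap()  # trailing gap folds into a zero-size block
  new_df(size = c(size, cur), dt = c(dt, NA), dq = c(dq, NA))
}

#' Build chain records from alignment blocks or a coordinate map
#'
#' @param x list of alignment blocks (target = lift source), or a `coordmap`
#'   from [apply_variants()] (backbone = target, consensus = query).
#' @param target_lengths,query_lengths named contig lengths (required for
#'   blocks; implied for a coordmap).
#' @return list of chain records.
#' @export
blocks_to_chain <- function(x, target_lengths = NULL, query_lengths = NULL) {
  if (inherits(x, "coordmap")) {
    segs <- x$segments
    out <- list()
    for (cn in unique(segs$contig)) {
      s <- segs[segs$contig == cn, , drop = FALSE]
      n <- nrow(s)
      dt <- c(s$b_start[-1] - (s$b_start[-n] + s$len[-n]), NA)
      dq <- c(s$c_start[-1] - (s$c_start[-n] + s$len[-n]), NA)
      blocks <- new_df(size = s$len, dt = dt, dq = dq)
      out[[length(out) + 1]] <- chain_from_runs(
        cn, x$backbone_len[[cn]], s$b_start[1], s$b_start[n] + s$len[n],
        cn, x$consensus_len[[cn]], "+", s$c_start[1], s$c_start[n] + s$len[n],
        blocks, length(out) + 1)
    }
    return(out)
  }
  # alignment blocks: verify non-overlap on target per contig
  key <- vapply(x, function(b) b$target$contig, character(1))
  for (tc in unique(key)) {
    bs <- x[key == tc]
    iv <- do.call(rbind, lapply(bs, function(b) c(b$target$start, b$target$end)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop_ctx("overlapping blocks on target ", tc, "; run select_primary first")
  }
  lapply(seq_along(x), function(i) {
    b <- x[[i]]
    qsize <- query_lengths[[b$query$contig]]
    tsize <- target_lengths[[b$target$contig]]
    if (is.null(qsize) || is.null(tsize))
      stop_ctx("missing contig length for chain construction")
    qs <- if (b$strand == "+") b$query$start else qsize - b$query$end
    qe <- if (b$strand == "+") b$query$end else qsize - b$query$start
    chain_from_runs(b$target$contig, tsize, b$target$start, b$target$end,
                    b$query$contig, qsize, b$strand, qs, qe,
                    ops_to_chain_blocks(b$ops), i)
  })
}

#' Write / read UCSC chain files
#'
#' @param chains list of chain records.
#' @param path file path.
#' @return `path` (write) or list of chain records (read).
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    stopifnot(sum(ch$blocks$size) + sum(ch$blocks$dt, na.rm = TRUE) ==
                ch$t_end - ch$t_start,
              sum(ch$blocks$size) + sum(ch$blocks$dq, na.rm = TRUE) ==
                ch$q_end - ch$q_start)
    writeLines(paste("chain", ch$score, ch$t_name, ch$t_size, ch$t_strand,
                     ch$t_start, ch$t_end, ch$q_name, ch$q_size, ch$q_strand,
                     ch$q_start, ch$q_end, ch$chain_id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1)
      writeLines(paste(b$size[-n], b$dt[-n], b$dq[-n]), con)
    writeLines(as.character(b$size[n]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1; next }
    f <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (f[1] != "chain") stop_ctx(path, " line ", i, ": expected chain header")
    j <- i + 1
    size <- integer(0); dt <- integer(0); dq <- integer(0)
    repeat {
      g <- strsplit(lines[j], "[ \t]+")[[1]]
      size <- c(size, as.integer(g[1]))
      if (length(g) >= 3) { dt <- c(dt, as.integer(g[2])); dq <- c(dq, as.integer(g[3])); j <- j + 1 }
      else { dt <- c(dt, NA); dq <- c(dq, NA); j <- j + 1; break }
    }
    out[[length(out) + 1]] <- chain_from_runs(
      f[3], as.integer(f[4]), as.integer(f[6]), as.integer(f[7]),
      f[8], as.integer(f[9]), f[10], as.integer(f[11]), as.integer(f[12]),
      new_df(size = size, dt = dt, dq = dq), as.integer(f[13]))
    i <- j
  }
  out
}

# aligned runs of a chain: t_run, q_run (oriented frame), size
chain_runs <- function(ch) {
  b <- ch$blocks
  tr <- ch$t_start + c(0, cumsum(b$size[-nrow(b)] +
                                   ifelse(is.na(b$dt[-nrow(b)]), 0, b$dt[-nrow(b)])))
  qr <- ch$q_start + c(0, cumsum(b$size[-nrow(b)] +
                                   ifelse(is.na(b$dq[-nrow(b)]), 0, b$dq[-nrow(b)])))
  new_df(t = tr, q = qr, size = b$size)
}

#' Lift an interval through chains
#'
#' @param chains list of chain records (target = source genome).
#' @param contig,start,end 0-based half-open interval on the source genome.
#' @param min_overlap minimum fraction of the interval covered by aligned
#'   bases for a lift to be reported (default 1.0; use 0.95 for features).
#' @return list with status ("lifted", "partial" or "unmapped") and, when
#'   mapped, contig, start, end, strand on the destination genome.
#' @export
lift_interval <- function(chains, contig, start, end, min_overlap = 1.0) {
  if (end <= start) stop_ctx("malformed interval")
  cand <- Filter(function(ch) ch$t_name == contig &&
                   start < ch$t_end && end > ch$t_start, chains)
  if (length(cand) == 0) return(list(status = "unmapped"))
  best <- NULL; best_ov <- -1
  for (ch in cand) {
    runs <- chain_runs(ch)
    ov <- sum(pmax(0, pmin(end, runs$t + runs$size) - pmax(start, runs$t)))
    if (ov > best_ov) { best <- ch; best_ov <- ov; best_runs <- runs }
  }
  frac <- best_ov / (end - start)
  if (best_ov == 0 || frac < min_overlap) return(list(status = "unmapped"))
  runs <- best_runs
  lift_pt <- function(t, snap) {
    # snap = "fwd": first aligned base at or after t; "rev": last at or before
    idx <- findInterval(t, runs$t)
    if (idx >= 1 && t < runs$t[idx] + runs$size[idx])
      return(list(q = runs$q[idx] + (t - runs$t[idx]), exact = TRUE))
    if (snap == "fwd") {
      if (idx < nrow(runs)) return(list(q = runs$q[idx + 1], exact = FALSE))
      return(NULL)
    } else {
      if (idx >= 1) return(list(q = runs$q[idx] + runs$size[idx] - 1,
                                exact = FALSE))
      return(NULL)
    }
  }
  p1 <- lift_pt(start, "fwd")
  p2 <- lift_pt(end - 1, "rev")
  if (is.null(p1) || is.null(p2) || p2$q < p1$q)
    return(list(status = "unmapped"))
  status <- if (p1$exact && p2$exact && best_ov == end - start) "lifted"
            else "partial"
  qs <- p1$q; qe <- p2$q + 1
  if (best$q_strand == "-") {
    tmp <- best$q_size - qe
    qe <- best$q_size - qs
    qs <- tmp
  }
  list(status = status, contig = best$q_name, start = qs, end = qe,
       strand = best$q_strand)
}

#' Lift BED or GFF3 annotations through chains
#'
#' Under the strict policy a multi-part feature group (rows sharing an ID /
#' Parent root) is rejected whole if any member fails; the per-feature policy
#' keeps the parts that lift. Strand is flipped through '-' chains.
#'
#' @param annot data.frame from [read_bed()] or [read_gff3()].
#' @param chains list of chain records.
#' @param policy "strict" or "per-feature".
#' @param min_overlap passed to [lift_interval()] (default 0.95).
#' @return list with `lifted` (same shape as input) and `rejects`
#'   (row index + reason).
#' @export
lift_annotation <- function(annot, chains, policy = c("strict", "per-feature"),
                            min_overlap = 0.95) {
  policy <- match.arg(policy)
  is_gff <- "attributes" %in% names(annot)
  n <- nrow(annot)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_gff) {
      s0 <- annot$start[i] - 1; e0 <- annot$end[i]; cn <- annot$seqid[i]
    } else {
      s0 <- annot$start[i]; e0 <- annot$end[i]; cn <- annot$contig[i]
    }
    res[[i]] <- lift_interval(chains, cn, s0, e0, min_overlap)
  }
  ok <- vapply(res, function(r) r$status != "unmapped", logical(1))
  reason <- ifelse(ok, "", "unmapped")
  if (is_gff && policy == "strict") {
    root <- ifelse(is.na(annot$Parent), annot$ID, annot$Parent)
    root <- ifelse(is.na(root), paste0("row", seq_len(n)), root)
    for (g in unique(root)) {
      grp <- which(root == g)
      if (any(!ok[grp])) {
        reason[grp][ok[grp]] <- "group-member-failed"
        ok[grp] <- FALSE
      }
    }
  }
  lifted <- annot[ok, , drop = FALSE]
  if (nrow(lifted)) {
    for (k in seq_along(which(ok))) {
      i <- which(ok)[k]
      r <- res[[i]]
      if (is_gff) {
        lifted$seqid[k] <- r$contig
        lifted$start[k] <- r$start + 1
        lifted$end[k] <- r$end
        if (r$strand == "-" && lifted$strand[k] %in% c("+", "-"))
          lifted$strand[k] <- if (lifted$strand[k] == "+") "-" else "+"
      } else {
        lifted$contig[k] <- r$contig
        lifted$start[k] <- r$start
        lifted$end[k] <- r$end
        if (r$strand == "-" && "strand" %in% names(lifted) &&
            lifted$strand[k] %in% c("+", "-"))
          lifted$strand[k] <- if (lifted$strand[k] == "+") "-" else "+"
      }
    }
  }
  rejects <- new_df(row = which(!ok), reason = reason[!ok])
  list(lifted = lifted, rejects = rejects)
}
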