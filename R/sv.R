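# SV extraction and merging, depth-based representativeness statistics and
# concordance metrics. SV records live on the reference frame, 0-based
# half-open; insertions use a 1-bp anchor interval and carry their length on
# the inserted-sequence side.

#' Filter variants to structural variants
#'
#' @param variants variant data.frame (VCF-style records).
#' @param sv_min_len minimum |len(ref) - len(alt)| (default 51).
#' @param source identifier recorded on each record.
#' @return SV data.frame: contig, start, end (0-based half-open), svtype,
#'   length, source. For insertions end == start + 1.
#' @export
filter_svs <- function(variants, sv_min_len = 51, source = "caller") {
  len <- abs(nchar(variants$alt) - nchar(variants$ref))
  ins <- nchar(variants$alt) > nchar(variants$ref)
  keep <- len >= sv_min_len & variants$vtype != "SNV"
  v <- variants[keep, , drop = FALSE]
  len <- len[keep]; ins <- ins[keep]
  # anchored records: event begins after the shared anchor base
  start <- v$pos  # 0-based position just after the 1-based anchor
  new_df(contig = v$contig, start = start,
         end = ifelse(ins, start + 1, start + len),
         svtype = ifelse(ins, "INS", "DEL"), length = len, source = source)
}

# breakpoint-end used for merging: DEL uses the reference end, INS uses
# start + length on the inserted-sequence frame
merge_end <- function(svs) {
  ifelse(svs$svtype == "INS", svs$start + svs$length, svs$end)
}

#' Merge SV call sets by breakpoint proximity
#'
#' Single-linkage clustering: two records link iff they have the same svtype
#' (when `type_aware`), lie on the same contig, and both breakpoints are
#' within `max_dist` (inclusive). The merged representative is the record
#' from the first-listed set in the cluster; support lists the sets present.
#'
#' @param call_sets named list of SV data.frames (see [filter_svs()]).
#' @param max_dist breakpoint distance (default 1000, inclusive).
#' @param type_aware require equal svtype to link (default TRUE).
#' @return merged SV data.frame with `support` (comma-joined set names) and
#'   `n_support`.
#' @export
merge_svs <- function(call_sets, max_dist = 1000, type_aware = TRUE) {
  if (length(call_sets) == 0) stop_ctx("need at least one call set")
  ids <- names(call_sets) %||% as.character(seq_along(call_sets))
  all <- do.call(rbind, lapply(seq_along(call_sets), function(i) {
    d <- call_sets[[i]]
    if (nrow(d) == 0) return(NULL)
    d$set <- ids[i]; d$set_rank <- i
    d
  }))
  if (is.null(all)) return(new_df(contig = character(), start = integer(),
                                  end = integer(), svtype = character(),
                                  length = integer(), source = character(),
                                  support = character(), n_support = integer()))
  all$bend <- merge_end(all)
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { parent[find(i)] <<- find(j) }
  grp_key <- if (type_aware) paste(all$contig, all$svtype) else all$contig
  for (g in split(seq_len(n), grp_key)) {
    if (length(g) < 2) next
    o <- g[order(all$start[g])]
    for (a in seq_along(o)) {
      for (b in seq_len(length(o) - a)) {
        i <- o[a]; j <- o[a + b]
        if (all$start[j] - all$start[i] > max_dist) break
        if (abs(all$bend[j] - all$bend[i]) <= max_dist) union_(i, j)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), root), function(ii) {
    rep_i <- ii[order(all$set_rank[ii], all$start[ii])][1]
    r <- all[rep_i, c("contig", "start", "end", "svtype", "length", "source"),
             drop = FALSE]
    r$support <- paste(sort(unique(all$set[ii])), collapse = ",")
    r$n_support <- length(unique(all$set[ii]))
    r
  })
  d <- do.call(rbind, out)
  d <- d[order(d$contig, d$start, d$svtype), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Fraction of primary SVs supported by a validation set
#'
#' @param primary_set,validation_set SV data.frames.
#' @param max_dist breakpoint distance for a match (default 1000).
#' @return fraction in [0, 1].
#' @export
support_rate <- function(primary_set, validation_set, max_dist = 1000) {
  if (nrow(primary_set) == 0) stop_ctx("empty primary set")
  if (nrow(validation_set) == 0) return(0)
  # same linkage criterion as merge_svs, applied record-by-record
  pb <- merge_end(primary_set); vb <- merge_end(validation_set)
  hit <- vapply(seq_len(nrow(primary_set)), function(i) {
    cand <- validation_set$contig == primary_set$contig[i] &
      validation_set$svtype == primary_set$svtype[i] &
      abs(validation_set$start - primary_set$start[i]) <= max_dist &
      abs(vb - pb[i]) <= max_dist
    any(cand)
  }, logical(1))
  mean(hit)
}

#' Accessible regions of a depth track
#'
#' Maximal runs where the cross-sample mean depth lies in
#' [`min_depth`, mean + `sd_mult` * SD]; mean and SD are computed per contig.
#'
#' @param depth_track named list of per-position mean-depth vectors.
#' @param min_depth lower bound (default 5).
#' @param sd_mult upper bound in SDs above the contig mean (default 2).
#' @return data.frame with contig, start, end (0-based half-open).
#' @export
accessible_regions <- function(depth_track, min_depth = 5, sd_mult = 2) {
  out <- list()
  for (cn in names(depth_track)) {
    d <- depth_track[[cn]]
    hi <- mean(d) + sd_mult * sd(d)
    okk <- d >= min_depth & d <= hi
    r <- rle(okk)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    if (any(r$values))
      out[[length(out) + 1]] <- new_df(contig = cn,
                                       start = starts[r$values],
                                       end = ends[r$values])
  }
  if (length(out) == 0)
    return(new_df(contig = character(), start = integer(), end = integer()))
  do.call(rbind, out)
}

#' Delta average depth of an SV region
#'
#' The reference value is the mean depth of the adjacent upstream window of
#' the same length as the SV region; delta is the signed difference between
#' the most deviant position inside the SV region and that reference value.
#'
#' @param depth_track named list of per-position depth vectors.
#' @param contig,start,end SV region (0-based half-open) on the track's
#'   frame.
#' @return list with `delta` (float, reads) and `ref_value`; or
#'   `list(skipped = reason)` when the upstream window leaves the contig.
#' @export
delta_avg_depth <- function(depth_track, contig, start, end) {
  d <- depth_track[[contig]]
  if (is.null(d)) stop_ctx("unknown contig: ", contig)
  len <- end - start
  if (len <= 0) stop_ctx("malformed SV region")
  if (start - len < 0 || end > length(d))
    return(list(skipped = "upstream window out of bounds"))
  ref <- mean(d[(start - len + 1):start])       # upstream [start-len, start)
  win <- d[(start + 1):end]
  i <- which.max(abs(win - ref))
  list(delta = win[i] - ref, ref_value = ref)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon convention); the exact
#' distribution is used for n <= 25 pairs without ties, a normal
#' approximation with continuity correction otherwise.
#'
#' @param deltas_a,deltas_b equal-length paired vectors (n >= 5).
#' @return two-sided p-value.
#' @export
paired_wilcoxon <- function(deltas_a, deltas_b) {
  if (length(deltas_a) != length(deltas_b)) stop_ctx("vectors must be paired")
  if (length(deltas_a) < 5) stop_ctx("need n >= 5 pairs")
  d <- deltas_a - deltas_b
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  n <- length(d)
  exact <- n <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    wilcox.test(d, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Read / write bedGraph-like depth tracks
#'
#' Four columns (contig, start, end, depth; 0-based half-open), run-length
#' encoded. Tracks must tile each contig from 0 without holes.
#'
#' @param path depth file.
#' @return named list of per-position mean-depth vectors.
#' @export
read_depth_track <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("contig", "start", "end", "depth"))
  out <- lapply(split(d, d$contig), function(x) {
    x <- x[order(x$start), , drop = FALSE]
    if (x$start[1] != 0 || any(x$start[-1] != x$end[-nrow(x)]))
      stop_ctx(path, ": depth runs must tile the contig")
    rep(x$depth, x$end - x$start)
  })
  out[unique(d$contig)]
}

#' @rdname read_depth_track
#' @param track named list of per-position depth vectors.
#' @export
write_depth_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(track)) {
    r <- rle(track[[cn]])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    writeLines(paste(cn, starts, ends, r$values, sep = "\t"), con)
  }
  invisible(path)
}

#' Positive predictive value and sensitivity from validation counts
#'
#' @param n_called calls made; `n_called_confirmed` of them confirmed.
#' @param n_called_confirmed confirmed calls.
#' @param n_true true events; `n_true_detected` of them detected.
#' @param n_true_detected detected true events.
#' @return list with ppv and sensitivity (percent, one decimal; NA when the
#'   corresponding counts are missing).
#' @export
concordance_metrics <- function(n_called = NA, n_called_confirmed = NA,
                                n_true = NA, n_true_detected = NA) {
  ppv <- if (!is.na(n_called)) {
    if (n_called == 0) stop_ctx("zero denominator for PPV")
    round(100 * n_called_confirmed / n_called, 1)
  } else NA_real_
  sens <- if (!is.na(n_true)) {
    if (n_true == 0) stop_ctx("zero denominator for sensitivity")
    round(100 * n_true_detected / n_true, 1)
  } else NA_real_
  list(ppv = ppv, sensitivity = sens)
}
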