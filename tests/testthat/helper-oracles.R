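# Independent oracles used across the suite. These deliberately avoid the
# package's own implementation paths: brute-force enumeration, full
# unbanded dynamic programming, and direct arithmetic.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# --- brute-force leftmost parsimonious representation of an indel ----------
# Enumerates every (pos, ref, alt) in the contig equivalent to the given
# edit (identical alternate haplotype), keeps the parsimonious ones
# (anchored, not trimmable at either end), and returns the leftmost.
oracle_normalize <- function(seq, pos, ref, alt) {
  H <- paste0(substr(seq, 1, pos - 1), alt,
              substr(seq, pos + nchar(ref), nchar(seq)))
  dlen <- nchar(alt) - nchar(ref)
  best <- NULL
  for (p in seq_len(nchar(seq))) {
    for (r in 1:(min(nchar(seq) - p + 1, nchar(ref) + 10))) {
      a_len <- r + dlen
      if (a_len < 1) next
      cand_ref <- substr(seq, p, p + r - 1)
      cand_alt <- substr(H, p, p + a_len - 1)
      # equivalence: applying (p, cand_ref, cand_alt) must reproduce H
      H2 <- paste0(substr(seq, 1, p - 1), cand_alt,
                   substr(seq, p + r, nchar(seq)))
      if (H2 != H) next
      if (cand_ref == cand_alt) next
      # parsimony: not trimmable at the right (keeping both non-empty at
      # this position), nor at the left while both > 1
      nr <- nchar(cand_ref); na <- nchar(cand_alt)
      if ((nr > 1 || na > 1) && nr > 1 && na > 1 &&
          substr(cand_ref, nr, nr) == substr(cand_alt, na, na)) next
      if (nr > 1 && na > 1 &&
          substr(cand_ref, 1, 1) == substr(cand_alt, 1, 1)) next
      # VCF anchoring for indels: shared first base
      if (nr != na && substr(cand_ref, 1, 1) != substr(cand_alt, 1, 1)) next
      if (is.null(best) || p < best$pos ||
          (p == best$pos && nr < nchar(best$ref)))
        best <- list(pos = p, ref = cand_ref, alt = cand_alt)
    }
  }
  best
}

# --- full affine DP (no band), cost minimisation ---------------------------
# Returns only the optimal cost; used to check extend_align's optimality.
oracle_affine_cost <- function(a, b, mis = 4, open = 4, ext = 2) {
  la <- nchar(a); lb <- nchar(b)
  INF <- 1e9
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  M <- matrix(INF, la + 1, lb + 1)
  E <- matrix(INF, la + 1, lb + 1)  # gap consuming b
  F <- matrix(INF, la + 1, lb + 1)  # gap consuming a
  M[1, 1] <- 0
  for (i in 0:la) for (j in 0:lb) {
    if (i == 0 && j == 0) next
    ii <- i + 1; jj <- j + 1
    if (j > 0) E[ii, jj] <- min(M[ii, jj - 1] + open + ext, E[ii, jj - 1] + ext)
    if (i > 0) F[ii, jj] <- min(M[ii - 1, jj] + open + ext, F[ii - 1, jj] + ext)
    d <- INF
    if (i > 0 && j > 0) {
      sub <- if (A[i] == B[j] && A[i] != "N") 0 else mis
      d <- min(M[ii - 1, jj - 1], E[ii - 1, jj - 1], F[ii - 1, jj - 1]) + sub
    }
    M[ii, jj] <- min(d, E[ii, jj], F[ii, jj])
  }
  M[la + 1, lb + 1]
}

ops_cost <- function(ops, mis = 4, open = 4, ext = 2) {
  cost <- 0
  for (i in seq_len(nrow(ops))) {
    k <- ops$kind[i]; l <- ops$len[i]
    if (k == "sub") cost <- cost + mis * l
    else if (k %in% c("ins", "del")) cost <- cost + open + ext * l
  }
  cost
}

# --- brute-force primer scan ----------------------------------------------
# All-positions scan with <= max_mm mismatches and exact 3'-terminal block.
oracle_primer_matches <- function(seq, primer, max_mm = 1, exact_len = 3,
                                  exact_left = FALSE) {
  sc <- strsplit(seq, "")[[1]]; pc <- strsplit(primer, "")[[1]]
  m <- length(pc); n <- length(sc)
  if (n < m) return(integer(0))
  starts <- integer(0)
  for (s in 0:(n - m)) {
    w <- sc[(s + 1):(s + m)]
    mm <- sum(w != pc | pc == "N")
    exact_block <- if (exact_left) 1:exact_len else (m - exact_len + 1):m
    if (mm <= max_mm && all(w[exact_block] == pc[exact_block] &
                              pc[exact_block] != "N"))
      starts <- c(starts, s)
  }
  starts
}

oracle_epcr <- function(markers, assembly, max_mm = 1, exact_len = 3,
                        size_tolerance = 0.5, max_amplicon = 5000) {
  out <- list()
  markers <- markers[!duplicated(markers$marker_id), , drop = FALSE]
  for (i in seq_len(nrow(markers))) {
    pf <- markers$primer_fwd[i]; pr <- markers$primer_rev[i]
    mf <- nchar(pf); mr <- nchar(pr)
    lo <- if (!is.na(markers$size_min[i]))
      floor((1 - size_tolerance) * markers$size_min[i]) else mf + mr
    hi <- if (!is.na(markers$size_max[i]))
      ceiling((1 + size_tolerance) * markers$size_max[i]) else max_amplicon
    for (cn in names(assembly$seqs)) {
      s <- assembly$seqs[[cn]]
      combos <- list(list(l = pf, r = revcomp(pr), rl = mr, ll = mf, st = "+"),
                     list(l = pr, r = revcomp(pf), rl = mf, ll = mr, st = "-"))
      for (cb in combos) {
        ls <- oracle_primer_matches(s, cb$l, max_mm, exact_len, FALSE)
        rs <- oracle_primer_matches(s, cb$r, max_mm, exact_len, TRUE)
        for (a in ls) for (b in rs) {
          if (b < a + cb$ll) next
          size <- b + cb$rl - a
          if (size >= lo && size <= hi)
            out[[length(out) + 1]] <- data.frame(
              marker_id = markers$marker_id[i], scaffold = cn, start = a,
              end = b + cb$rl, strand = cb$st, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(NULL)
  d <- do.call(rbind, out)
  d[order(d$marker_id, d$scaffold, d$start), , drop = FALSE]
}

# --- exact signed-rank enumeration ----------------------------------------
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- grid %*% r
  mean(abs(Ws - sum(r) / 2) >= abs(W - sum(r) / 2))
}

# shared small fixtures -----------------------------------------------------
tiny_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_population(n_chrom = 1, chrom_len = 1e5, seed = 7)
    cache
  }
})
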