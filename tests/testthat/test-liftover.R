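# Chain construction, chain arithmetic invariants, interval lifting and
# annotation transfer.

test_that("identity and insertion blocks become correct chains", {
  b <- list(list(query = list(contig = "q", start = 0, end = 1000),
                 target = list(contig = "t", start = 0, end = 1000),
                 strand = "+",
                 ops = data.frame(kind = "match", len = 1000L, alt = "",
                                  stringsAsFactors = FALSE),
                 score = 1000, identity = 1))
  ch <- blocks_to_chain(b, c(t = 1000L), c(q = 1000L))
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$blocks), 1)
  expect_equal(ch[[1]]$blocks$size, 1000L)
  expect_equal(ch[[1]]$score, 1000)

  b[[1]]$ops <- data.frame(kind = c("match", "ins", "match"),
                           len = c(500L, 10L, 500L), alt = c("", strrep("A", 10), ""),
                           stringsAsFactors = FALSE)
  b[[1]]$query$end <- 1010
  ch <- blocks_to_chain(b, c(t = 1000L), c(q = 1010L))
  expect_equal(ch[[1]]$blocks$size, c(500L, 500L))
  expect_equal(ch[[1]]$blocks$dq[1], 10L)
  expect_equal(ch[[1]]$blocks$dt[1], 0L)

  # overlapping blocks rejected
  b2 <- c(b, b)
  expect_error(blocks_to_chain(b2, c(t = 1000L), c(q = 1010L)), "overlap")
})

test_that("chain arithmetic invariants are enforced on write", {
  ch <- list(structure(list(score = 10, t_name = "t", t_size = 100L,
                            t_strand = "+", t_start = 0L, t_end = 50L,
                            q_name = "q", q_size = 100L, q_strand = "+",
                            q_start = 0L, q_end = 49L, chain_id = 1,
                            blocks = data.frame(size = 50L, dt = NA, dq = NA)),
                       class = "chain"))
  f <- tempfile()
  expect_error(write_chain(ch, f))
  ch[[1]]$q_end <- 50L
  write_chain(ch, f)
  expect_equal(read_chain(f)[[1]]$blocks$size, 50L)
})

test_that("minus-strand chains lift points into the reversed frame", {
  set.seed(22)
  s <- rand_seq(4000)
  tgt <- assembly("t", c(c1 = s))
  qry <- assembly("q", c(c1 = revcomp(s)))
  blocks <- select_primary(align_genomes(qry, tgt))
  ch <- blocks_to_chain(blocks, contig_lengths(tgt), contig_lengths(qry))
  expect_equal(ch[[1]]$q_strand, "-")
  for (t in c(0L, 17L, 2000L, 3999L)) {
    r <- lift_interval(ch, "c1", t, t + 1)
    expect_equal(r$status, "lifted")
    # base at t on target equals revcomp of query base at lifted position
    expect_equal(substr(s, t + 1, t + 1),
                 substr(revcomp(substr(qry$seqs[["c1"]], r$start + 1, r$end)),
                        1, 1))
    expect_equal(r$start, 4000 - 1 - t)
  }
})

test_that("lift_interval agrees with the coordinate map from apply_variants", {
  truth <- tiny_truth()
  smp <- sample_haploid_assembly(truth, 23, name = "lift")
  ap <- apply_variants(truth$ancestral,
                       truth$catalogue[smp$carried$carried, , drop = FALSE])
  ch <- blocks_to_chain(ap$coordmap)
  set.seed(23)
  pts <- sample(0:(nchar(truth$ancestral$seqs[[1]]) - 1), 1000)
  viamap <- map_point(ap$coordmap, "chr1", pts)
  viachain <- vapply(pts, function(p) {
    r <- lift_interval(ch, "chr1", p, p + 1)
    if (r$status == "lifted") r$start else NA_integer_
  }, numeric(1))
  expect_equal(is.na(viamap), is.na(viachain))
  expect_equal(viamap[!is.na(viamap)], viachain[!is.na(viachain)])

  # insertion shifts downstream coordinates (worked example)
  bb <- assembly("bb", c(c1 = strrep("ACGT", 100)))
  ins <- data.frame(contig = "c1", pos = 100L, ref = substr(bb$seqs[[1]], 100, 100),
                    alt = paste0(substr(bb$seqs[[1]], 100, 100), rand_seq(10)),
                    vtype = "INS", sv = FALSE, support = "a", tie = FALSE,
                    stringsAsFactors = FALSE)
  ap2 <- apply_variants(bb, ins)
  ch2 <- blocks_to_chain(ap2$coordmap)
  r <- lift_interval(ch2, "c1", 200, 210)
  expect_equal(r$status, "lifted")
  expect_equal(c(r$start, r$end), c(210, 220))

  # interval entirely inside a deleted segment is unmapped
  del <- data.frame(contig = "c1", pos = 50L,
                    ref = substr(bb$seqs[[1]], 50, 60),
                    alt = substr(bb$seqs[[1]], 50, 50),
                    vtype = "DEL", sv = FALSE, support = "a", tie = FALSE,
                    stringsAsFactors = FALSE)
  ap3 <- apply_variants(bb, del)
  ch3 <- blocks_to_chain(ap3$coordmap)
  expect_equal(lift_interval(ch3, "c1", 52, 55)$status, "unmapped")
  expect_error(lift_interval(ch3, "c1", 55, 52), "malformed")
})

test_that("round trip backbone -> consensus -> backbone is the identity", {
  truth <- tiny_truth()
  smp <- sample_haploid_assembly(truth, 24, name = "rt2")
  ap <- apply_variants(truth$ancestral,
                       truth$catalogue[smp$carried$carried, , drop = FALSE])
  set.seed(24)
  pts <- sample(0:(nchar(truth$ancestral$seqs[[1]]) - 1), 500)
  fwd <- map_point(ap$coordmap, "chr1", pts)
  back <- map_point(ap$coordmap, "chr1", fwd[!is.na(fwd)], reverse = TRUE)
  expect_equal(back, pts[!is.na(fwd)])
})

test_that("annotation lifting flips strand and applies the strict policy", {
  # identity chain: 3-exon toy gene unchanged
  cm <- structure(list(segments = data.frame(contig = "c1", b_start = 0,
                                             c_start = 0, len = 1000,
                                             stringsAsFactors = FALSE),
                       backbone_len = c(c1 = 1000L),
                       consensus_len = c(c1 = 1000L)), class = "coordmap")
  ch <- blocks_to_chain(cm)
  g <- data.frame(seqid = "c1", source = ".", type = c("gene", "exon", "exon"),
                  start = c(101, 101, 301), end = c(400, 200, 400),
                  score = ".", strand = "+", phase = ".",
                  attributes = c("ID=g1", "ID=e1;Parent=g1", "ID=e2;Parent=g1"),
                  ID = c("g1", "e1", "e2"), Parent = c(NA, "g1", "g1"),
                  stringsAsFactors = FALSE)
  r <- lift_annotation(g, ch)
  expect_equal(r$lifted$start, g$start)
  expect_equal(nrow(r$rejects), 0)

  # gene on a '-' chain: coordinates reversed, strand flipped, and lifting
  # back restores the original
  set.seed(25)
  s <- rand_seq(1000)
  tgt <- assembly("t", c(c1 = s)); qry <- assembly("q", c(c1 = revcomp(s)))
  chm <- blocks_to_chain(select_primary(align_genomes(qry, tgt)),
                         contig_lengths(tgt), contig_lengths(qry))
  r2 <- lift_annotation(g, chm)
  expect_true(all(r2$lifted$strand == "-"))
  expect_equal(r2$lifted$start[1], 1000 - 400 + 1)
  chb <- blocks_to_chain(select_primary(align_genomes(tgt, qry)),
                         contig_lengths(qry), contig_lengths(tgt))
  r3 <- lift_annotation(r2$lifted, chb)
  expect_equal(r3$lifted$start, g$start)
  expect_equal(r3$lifted$end, g$end)
  expect_true(all(r3$lifted$strand == "+"))

  # exon overlapping a deleted segment: whole gene rejected under strict
  cm2 <- structure(list(segments = data.frame(contig = "c1",
                                              b_start = c(0, 350),
                                              c_start = c(0, 250),
                                              len = c(250, 650),
                                              stringsAsFactors = FALSE),
                        backbone_len = c(c1 = 1000L),
                        consensus_len = c(c1 = 900L)), class = "coordmap")
  ch2 <- blocks_to_chain(cm2)
  r4 <- lift_annotation(g, ch2, policy = "strict")
  expect_equal(nrow(r4$lifted), 0)
  expect_setequal(r4$rejects$reason, c("unmapped", "group-member-failed"))
  r5 <- lift_annotation(g, ch2, policy = "per-feature")
  expect_equal(r5$lifted$ID, c("e1"))
})
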