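# In-silico PCR and marker-map anchoring: scan semantics (with brute-force
# oracle), chimera flagging, weighted assignment, ordering/orientation,
# co-linearity and pseudo-molecule construction.

mk_marker <- function(id, fwd, rev, lg = "chr1", map_id = "g1",
                      map_type = "genetic", pos = 1, size = NA_integer_) {
  data.frame(marker_id = id, map_id = map_id, map_type = map_type,
             linkage_group = lg, map_position = pos, primer_fwd = fwd,
             primer_rev = rev, size_min = size, size_max = size,
             stringsAsFactors = FALSE)
}

test_that("epcr_scan requires orientation, 3' exactness and size window", {
  set.seed(14)
  pf <- rand_seq(20); pr <- rand_seq(20); insert <- rand_seq(460)
  scaf <- paste0(rand_seq(80), pf, insert, revcomp(pr), rand_seq(80))
  asm <- assembly("t", c(s1 = scaf))
  mk <- mk_marker("m1", pf, pr)

  h <- epcr_scan(mk, asm)
  expect_equal(nrow(h), 1)
  expect_equal(h$end - h$start, 460 + 40)
  expect_equal(h$strand, "+")

  h2 <- epcr_scan(mk, assembly("t2", c(s1 = revcomp(scaf))))
  expect_equal(h2$strand, "-")
  expect_equal(h2$end - h2$start, 500)

  # one mismatch in the 3'-terminal trinucleotide: no hit
  bad <- pf
  substr(bad, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(pf, 20, 20))[1]
  expect_equal(nrow(epcr_scan(mk_marker("m1", bad, pr), asm)), 0)
  # one mismatch away from the 3' end: still amplifies
  bad2 <- pf
  substr(bad2, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(pf, 5, 5))[1]
  h3 <- epcr_scan(mk_marker("m1", bad2, pr), asm)
  expect_equal(nrow(h3), 1)
  expect_equal(h3$mismatches_fwd, 1)
  # two mismatches: rejected
  bad3 <- bad2
  substr(bad3, 8, 8) <- setdiff(c("A", "C", "G", "T"), substr(pf, 8, 8))[1]
  expect_equal(nrow(epcr_scan(mk_marker("m1", bad3, pr), asm)), 0)
  # expected size window: 500 observed vs expected 200 +/- 50% -> no hit
  expect_equal(nrow(epcr_scan(mk_marker("m1", pf, pr, size = 200), asm)), 0)
  expect_equal(nrow(epcr_scan(mk_marker("m1", pf, pr, size = 450), asm)), 1)
})

test_that("epcr_scan equals the brute-force all-positions oracle", {
  set.seed(15)
  truth <- simulate_population(n_chrom = 1, chrom_len = 5e4, seed = 15)
  mm <- simulate_marker_maps(truth, markers_per_chrom = 8,
                             map_specs = default_map_specs(1, 1, 0, 0),
                             seed = 15)
  # scan a mutated sample, not the genome the primers were cut from
  smp <- sample_haploid_assembly(truth, 16, name = "oracle")
  got <- epcr_scan(mm$markers, smp$assembly)
  exp <- oracle_epcr(mm$markers, smp$assembly)
  expect_equal(got[, c("marker_id", "scaffold", "start", "end", "strand")],
               exp, ignore_attr = TRUE)
  expect_gt(nrow(got), 0)
})

test_that("chimera flagging needs two linkage groups with enough markers", {
  hits <- data.frame(marker_id = paste0("m", 1:6), scaffold = "s1",
                     start = 1:6 * 100, end = 1:6 * 100 + 50, strand = "+",
                     mismatches_fwd = 0, mismatches_rev = 0,
                     stringsAsFactors = FALSE)
  mks <- do.call(rbind, lapply(1:6, function(i)
    mk_marker(paste0("m", i), strrep("ACGTG", 4), strrep("TGCAT", 4),
              lg = if (i <= 3) "chr1" else "chr5")))
  f <- flag_chimeric_scaffolds(hits, mks)          # 3 chr1 + 3 chr5
  expect_true(f$flagged)

  mks$linkage_group <- c(rep("chr1", 5), "chr5")   # singleton tolerated
  f <- flag_chimeric_scaffolds(hits, mks)
  expect_false(f$flagged)
})

test_that("chromosome assignment uses genetic 5 / RH 1 weights", {
  hits <- data.frame(marker_id = paste0("m", 1:5), scaffold = "s1",
                     start = 1:5 * 100, end = 1:5 * 100 + 50, strand = "+",
                     mismatches_fwd = 0, mismatches_rev = 0,
                     stringsAsFactors = FALSE)
  mks <- rbind(
    do.call(rbind, lapply(1:2, function(i)
      mk_marker(paste0("m", i), strrep("ACGTG", 4), strrep("TGCAT", 4),
                lg = "chr1", map_id = "g1", map_type = "genetic"))),
    do.call(rbind, lapply(3:5, function(i)
      mk_marker(paste0("m", i), strrep("ACGTG", 4), strrep("TGCAT", 4),
                lg = "chr2", map_id = "r1", map_type = "RH"))))
  a <- assign_chromosome(hits, mks)
  expect_equal(a$chromosome, "chr1")  # 2x5 = 10 beats 3x1 = 3
  expect_equal(a$score, 10)

  # exact weighted tie (5 vs 5x1) -> unplaced
  mks2 <- rbind(
    mk_marker("m1", strrep("ACGTG", 4), strrep("TGCAT", 4), lg = "chr1",
              map_type = "genetic"),
    do.call(rbind, lapply(2:6, function(i)
      mk_marker(paste0("m", i), strrep("ACGTG", 4), strrep("TGCAT", 4),
                lg = "chr2", map_id = "r1", map_type = "RH"))))
  hits2 <- rbind(hits, hits[5, ])
  hits2$marker_id <- paste0("m", 1:6)
  expect_warning(a2 <- assign_chromosome(hits2, mks2), "tie")
  expect_true(is.na(a2$chromosome))

  expect_equal(nrow(assign_chromosome(hits[0, ], mks)), 0)
})

test_that("noiseless maps recover order and orientation exactly", {
  truth <- simulate_population(n_chrom = 2, chrom_len = 8e4, seed = 17)
  specs <- default_map_specs(genetic_noise = 0, rh_noise = 0)
  mm <- simulate_marker_maps(truth, markers_per_chrom = 30,
                             map_specs = specs, seed = 17)
  fr <- fragment_into_scaffolds(truth$ancestral, target_n50 = 1.6e4,
                                gap_len_range = c(200, 200), seed = 17)
  hits <- epcr_scan(mm$markers, fr$assembly)
  asg <- assign_chromosome(hits, mm$markers)
  plan <- order_orient(asg, hits, mm$markers)
  pl <- fr$placement
  m <- merge(plan$plan, pl, by = "scaffold")
  expect_true(all(m$chromosome == m$contig))
  for (chrom in unique(plan$plan$chromosome)) {
    d <- plan$plan[plan$plan$chromosome == chrom, ]
    tru <- pl[match(d$scaffold, pl$scaffold), ]
    expect_equal(cor(seq_len(nrow(d)), rank(tru$start), method = "kendall"), 1)
  }
  nhits <- table(hits$scaffold)
  ori_ok <- m$orientation == m$strand
  expect_true(all(ori_ok[nhits[m$scaffold] >= 2]))

  # descending map positions within a scaffold -> '-'
  expect_true(any(plan$plan$orientation == "-"))
})

test_that("heuristic order equals the exhaustive-permutation optimum", {
  # objective: sum over maps of weight x Pearson r between plan position
  # and map position
  truth <- simulate_population(n_chrom = 1, chrom_len = 6e4, seed = 18)
  specs <- default_map_specs(1, 1, genetic_noise = 0, rh_noise = 0.04)
  mm <- simulate_marker_maps(truth, markers_per_chrom = 15,
                             map_specs = specs, seed = 18)
  fr <- fragment_into_scaffolds(truth$ancestral, target_n50 = 1.2e4,
                                gap_len_range = c(200, 200), seed = 18)
  hits <- epcr_scan(mm$markers, fr$assembly)
  asg <- assign_chromosome(hits, mm$markers)
  plan <- order_orient(asg, hits, mm$markers)
  scaffolds <- plan$plan$scaffold
  expect_lte(length(scaffolds), 7)
  j <- merge(hits, mm$markers, by = "marker_id")
  j$w <- ifelse(j$map_type == "genetic", 5, 1)
  objective <- function(ord) {
    offs <- setNames(match(j$scaffold, ord), NULL)
    sum(vapply(split(j, j$map_id), function(d) {
      po <- match(d$scaffold, ord) * 1e6 + (d$start + d$end) / 2
      if (nrow(d) < 2) return(0)
      d$w[1] * cor(po, d$map_position)
    }, numeric(1)))
  }
  perms <- combinat_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- max(vapply(perms(scaffolds), objective, numeric(1)))
  expect_equal(objective(scaffolds), best)
})

test_that("co-linearity summary arithmetic is plain mean +/- SD", {
  # perfect ordering: r = 1; reversed scaffold still 1 after orientation
  truth <- simulate_population(n_chrom = 1, chrom_len = 5e4, seed = 19)
  specs <- default_map_specs(1, 0, genetic_noise = 0)
  mm <- simulate_marker_maps(truth, markers_per_chrom = 12,
                             map_specs = specs, seed = 19)
  fr <- fragment_into_scaffolds(truth$ancestral, target_n50 = 1e4,
                                gap_len_range = c(500, 500), seed = 19)
  hits <- epcr_scan(mm$markers, fr$assembly)
  asg <- assign_chromosome(hits, mm$markers)
  plan <- order_orient(asg, hits, mm$markers, gap_size = 500)
  col <- colinearity(plan, hits, mm$markers, contig_lengths(fr$assembly))
  expect_true(all(col$per_map$r > 0.99))

  # summary over {1.0, 0.98, 0.96} -> 0.98 +/- 0.02
  fake <- data.frame(map_id = c("a", "b", "c"), map_type = "genetic",
                     chromosome = "chr1", r = c(1.0, 0.98, 0.96), n = 5,
                     stringsAsFactors = FALSE)
  s <- do.call(rbind, lapply(split(fake, fake$map_type), function(d)
    data.frame(map_type = d$map_type[1], mean_r = mean(d$r), sd_r = sd(d$r))))
  expect_equal(s$mean_r, 0.98)
  expect_equal(s$sd_r, 0.02)
})

test_that("pseudo-molecules concatenate with fixed gaps and AGP agrees", {
  set.seed(20)
  scf <- assembly("s", c(scf_1 = rand_seq(1000), scf_2 = rand_seq(2000)))
  plan <- structure(list(
    plan = data.frame(chromosome = "chr1", scaffold = c("scf_1", "scf_2"),
                      orientation = c("+", "-"), position_score = c(1, 2),
                      stringsAsFactors = FALSE),
    gap_size = 10000, unplaced = character(0),
    ambiguous_markers = character(0)), class = "anchor_plan")
  built <- build_pseudomolecules(plan, scf)
  expect_equal(nchar(built$assembly$seqs[["chr1"]]), 13000)
  expect_equal(built$agp$component_type, c("W", "N", "W"))
  # '-' scaffold emitted reverse-complemented; AGP rebuild is byte-identical
  rebuilt <- paste0(scf$seqs[["scf_1"]], strrep("N", 10000),
                    revcomp(scf$seqs[["scf_2"]]))
  expect_equal(built$assembly$seqs[["chr1"]], rebuilt)

  plan$plan <- plan$plan[1, ]
  expect_equal(nchar(build_pseudomolecules(plan, scf)$assembly$seqs[["chr1"]]),
               1000)
  plan$plan$scaffold <- "nope"
  expect_error(build_pseudomolecules(plan, scf), "missing")
})

test_that("masking, circular rotation and gap resizing are exact edits", {
  a <- assembly("a", c(c1 = strrep("ACGT", 5)))
  m <- mask_intervals(a, data.frame(contig = "c1", start = 0, end = 10))
  expect_equal(m$seqs[["c1"]], paste0(strrep("N", 10), "GTACGTACGT"))
  expect_equal(mask_intervals(a, data.frame(contig = character(0),
                                            start = integer(0),
                                            end = integer(0)))$seqs, a$seqs)
  expect_error(mask_intervals(a, data.frame(contig = "c1", start = 10,
                                            end = 30)), "range")

  expect_equal(rotate_circular("CGTA", "AC"), "ACGT")
  expect_equal(rotate_circular("ACGT", "AC"), "ACGT")
  expect_error(rotate_circular("ACGT", "TT"), "not found")
  expect_error(rotate_circular("ACAC", "AC"), "more than once")

  g <- assembly("g", c(c1 = paste0(strrep("A", 50), strrep("N", 100),
                                   strrep("C", 50))))
  r <- resize_gaps(g, data.frame(contig = "c1", gap_index = 1L,
                                 new_len = 500L))
  expect_equal(nchar(r$assembly$seqs[["c1"]]), 600)
  expect_equal(r$report$old_len, 100L)
  expect_error(resize_gaps(g, data.frame(contig = "c1", gap_index = 2L,
                                         new_len = 10L)), "out of range")
  expect_equal(resize_gaps(g, NULL)$assembly$seqs, g$seqs)
})
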