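# Majority voting, seeded tie-breaking, consensus application, support
# summary and expected tie errors.

vdf <- function(pos, ref, alt, contig = "c1") {
  if (length(pos) == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), sv = logical(0),
                      support = character(0), tie = logical(0),
                      stringsAsFactors = FALSE))
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             vtype = ifelse(nchar(ref) == nchar(alt), "SNV",
                            ifelse(nchar(alt) > nchar(ref), "INS", "DEL")),
             sv = FALSE, support = "", tie = FALSE, stringsAsFactors = FALSE)
}

test_that("vote applies the shared-by-majority rule", {
  # N=3: {G, G, backbone} -> G is major
  v <- vote_major_alleles(list(a = vdf(5, "A", "G"), b = vdf(5, "A", "G"),
                               c = vdf(integer(0), character(0), character(0))),
                          n_assemblies = 3)
  expect_equal(nrow(v$major), 1)
  expect_equal(v$major$alt, "G")
  expect_equal(v$major$support_n, 2L)
  expect_equal(nrow(v$ties), 0)

  # {G, T, backbone} -> tie site with candidates G, T and backbone
  v <- vote_major_alleles(list(a = vdf(5, "A", "G"), b = vdf(5, "A", "T"),
                               c = vdf(integer(0), character(0), character(0))),
                          n_assemblies = 3)
  expect_equal(nrow(v$major), 0)
  expect_equal(nrow(v$ties), 3)
  expect_equal(sum(v$ties$is_backbone), 1)

  # {G, T, C} -> tie site with 3 observed + backbone candidate
  v <- vote_major_alleles(list(a = vdf(5, "A", "G"), b = vdf(5, "A", "T"),
                               c = vdf(5, "A", "C")), n_assemblies = 3)
  expect_equal(nrow(v$ties), 4)
  v2 <- vote_major_alleles(list(a = vdf(5, "A", "G"), b = vdf(5, "A", "T"),
                                c = vdf(5, "A", "C")), n_assemblies = 3,
                           include_backbone = FALSE)
  expect_equal(nrow(v2$ties), 3)

  # single sub-threshold allele: backbone retained, no tie
  v <- vote_major_alleles(list(a = vdf(5, "A", "G"),
                               b = vdf(integer(0), character(0), character(0)),
                               c = vdf(integer(0), character(0), character(0))),
                          n_assemblies = 3)
  expect_equal(nrow(v$major), 0)
  expect_equal(nrow(v$ties), 0)

  expect_error(vote_major_alleles(list(a = vdf(5, "A", "G")), 1,
                                  min_share = 2), "exceeds")
})

test_that("vote is invariant to assembly input order", {
  sets <- list(a = vdf(c(5, 9), c("A", "C"), c("G", "T")),
               b = vdf(5, "A", "G"), c = vdf(9, "C", "A"))
  v1 <- vote_major_alleles(sets, 3)
  v2 <- vote_major_alleles(rev(sets), 3)
  expect_equal(v1$major[, c("contig", "pos", "ref", "alt", "support")],
               v2$major[, c("contig", "pos", "ref", "alt", "support")])
  expect_equal(v1$ties[, c("pos", "ref", "alt")],
               v2$ties[, c("pos", "ref", "alt")])
})

test_that("break_ties is seeded, uniform and logged", {
  v <- vote_major_alleles(list(a = vdf(5, "A", "G"), b = vdf(5, "A", "T"),
                               c = vdf(5, "A", "C")), n_assemblies = 3,
                          include_backbone = FALSE)
  r1 <- break_ties(v$ties, seed = 42)
  r2 <- break_ties(v$ties, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$chosen$tie))
  expect_error(break_ties(v$ties), "seed")

  # uniformity: 3 candidates drawn many times, chi-square at alpha = 0.01
  counts <- table(vapply(1:3000, function(s)
    break_ties(v$ties, seed = s)$log$chosen, character(1)))
  expect_equal(length(counts), 3)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # single-candidate "tie" still flagged
  single <- v$ties[1, , drop = FALSE]
  r <- break_ties(single, seed = 1)
  expect_equal(nrow(r$chosen), 1)
  expect_true(r$chosen$tie)
})

test_that("apply_variants substitutes, tracks coordinates, drops overlaps", {
  bb <- assembly("bb", c(c1 = "AAAA"))
  r <- apply_variants(bb, vdf(2, "A", "G"))
  expect_equal(r$consensus$seqs[["c1"]], "AGAA")

  set.seed(10)
  s <- rand_seq(40)
  bb <- assembly("bb", c(c1 = s))
  ins <- vdf(10, substr(s, 10, 10), paste0(substr(s, 10, 10), "GG"))
  r <- apply_variants(bb, ins)
  expect_equal(nchar(r$consensus$seqs[["c1"]]), 42)
  # positions >= 11 (1-based) shift +2
  expect_equal(map_point(r$coordmap, "c1", 15), 17)
  expect_equal(map_point(r$coordmap, "c1", 5), 5)
  # verify by re-alignment round trip
  blocks <- select_primary(align_genomes(r$consensus, bb,
                                         align_params(k = 11, min_match = 10)))
  rec <- normalize_variants(call_variants(blocks, bb, "x"), bb)
  expect_equal(rec[, c("pos", "ref", "alt")],
               normalize_variants(ins, bb)[, c("pos", "ref", "alt")])

  # overlapping DEL + SNV at same pos: DEL (larger span sorts first) wins
  del <- vdf(10, substr(s, 10, 12), substr(s, 10, 10))
  snv <- vdf(11, substr(s, 11, 11),
             setdiff(c("A", "C", "G", "T"), substr(s, 11, 11))[1])
  expect_warning(r <- apply_variants(bb, rbind(snv, del)), "dropped")
  expect_equal(nrow(r$dropped), 1)
  expect_equal(r$dropped$vtype, "SNV")
  expect_equal(nchar(r$consensus$seqs[["c1"]]), 38)
})

test_that("consensus length change equals the sum of allele length changes", {
  truth <- tiny_truth()
  smp <- sample_haploid_assembly(truth, 31, name = "len")
  applied <- truth$catalogue[smp$carried$carried, , drop = FALSE]
  expect_equal(sum(nchar(smp$assembly$seqs)) - sum(nchar(truth$ancestral$seqs)),
               sum(nchar(applied$alt) - nchar(applied$ref)))
})

test_that("majority-recovery law holds across allele-frequency bins", {
  set.seed(12)
  ps <- c(0.55, 0.7, 0.85, 0.95)
  n_sites <- 800
  for (p in ps) {
    carried <- matrix(rbinom(3 * n_sites, 1, p) == 1, ncol = 3)
    sets <- lapply(1:3, function(j) {
      idx <- which(carried[, j])
      vdf(10 * idx, "A", "G")
    })
    names(sets) <- c("a", "b", "c")
    v <- vote_major_alleles(sets, 3)
    obs <- nrow(v$major) / n_sites   # population-major allele is the alt
    expe <- p^3 + 3 * p^2 * (1 - p)
    se <- sqrt(expe * (1 - expe) / n_sites)
    expect_lt(abs(obs - expe), 3 * se + 1e-9)
  }
})

test_that("support_summary reproduces reported share arithmetic", {
  sn <- rep(c(3L, 2L, 1L), times = c(1176922L, 1204762L, 119891L))
  s <- support_summary(data.frame(support_n = sn), 3)
  expect_equal(s$pct[s$support_level == 3], 47)
  expect_equal(s$pct[s$support_level == 2], 48)

  s2 <- support_summary(data.frame(support_n = rep(3L, 10)), 3)
  expect_equal(s2$pct[s2$support_level == 3], 100)
  expect_error(support_summary(data.frame(support_n = integer(0)), 3))
})

test_that("expected tie errors follow the stated per-site definition", {
  v <- vote_major_alleles(list(a = vdf(101, "A", "G"), b = vdf(101, "A", "T"),
                               c = vdf(101, "A", "C")), n_assemblies = 3,
                          include_backbone = FALSE)
  panel <- data.frame(contig = "c1", pos = 101L, ref = "A", alt = "G",
                      af = 0.8, stringsAsFactors = FALSE)
  panel$key <- paste(panel$contig, panel$pos, panel$ref, panel$alt, sep = ":")
  r <- expected_tie_errors(v$ties, panel)
  expect_equal(r$expected_errors, 2 / 3)   # panel-major G among 3 candidates

  panel$alt <- "G"; panel$af <- 0.2        # panel-major becomes backbone A
  v2 <- vote_major_alleles(list(a = vdf(101, "A", "G"), b = vdf(101, "A", "T"),
                                c = vdf(101, "A", "C")), n_assemblies = 3,
                           include_backbone = FALSE)
  r2 <- expected_tie_errors(v2$ties, panel)
  expect_equal(r2$expected_errors, 1)      # major allele not a candidate

  # missing site counted separately
  panel$pos <- 999L
  panel$key <- paste(panel$contig, panel$pos, panel$ref, panel$alt, sep = ":")
  r3 <- expected_tie_errors(v$ties, panel)
  expect_equal(r3$n_missing, 1L)
  expect_equal(r3$expected_errors, 0)

  # Monte-Carlo replay of break_ties matches the expectation within 3 SE
  v4 <- vote_major_alleles(list(a = vdf(101, "A", "G"), b = vdf(101, "A", "T"),
                                c = vdf(101, "A", "C")), n_assemblies = 3,
                           include_backbone = FALSE)
  panel4 <- data.frame(contig = "c1", pos = 101L, ref = "A", alt = "G",
                       af = 0.8, stringsAsFactors = FALSE)
  panel4$key <- paste(panel4$contig, panel4$pos, panel4$ref, panel4$alt,
                      sep = ":")
  n_mc <- 4000
  err <- vapply(seq_len(n_mc), function(s)
    break_ties(v4$ties, seed = s)$log$chosen != "A>G", logical(1))
  p_hat <- mean(err)
  se <- sqrt(p_hat * (1 - p_hat) / n_mc)
  expect_lt(abs(p_hat - 2 / 3), 3 * se)
})
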