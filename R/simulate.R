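# Seeded synthetic-data generator: population variant catalogue with stated
# allele frequencies, haploid assemblies sampled from it, fragmented
# scaffolds, noisy genetic/RH marker maps with primer pairs, and per-sample
# depth tracks. All randomness flows from one master seed via named
# substreams, so any stage can be re-run in isolation.

#' Default map specifications: three genetic maps, six RH maps
#'
#' `scale` converts bp to map units (about 1 cM/Mb for genetic maps, about
#' 300 cR/Mb for RH maps); `noise_frac` is the positional noise SD as a
#' fraction of the chromosome's map length.
#'
#' @param n_genetic,n_rh number of maps per type.
#' @param genetic_noise,rh_noise noise fractions.
#' @return data.frame with map_id, map_type, scale, noise_frac.
#' @export
default_map_specs <- function(n_genetic = 3, n_rh = 6, genetic_noise = 0.002,
                              rh_noise = 0.03) {
  rbind(
    new_df(map_id = paste0("gen_", seq_len(n_genetic)), map_type = "genetic",
           scale = 1e-6, noise_frac = genetic_noise),
    new_df(map_id = paste0("rh_", seq_len(n_rh)), map_type = "RH",
           scale = 3e-4, noise_frac = rh_noise))
}

#' Simulate a population variant catalogue over an ancestral genome
#'
#' Variant allele frequencies are drawn from Beta(`af_shape1`, `af_shape2`)
#' (both-allele-segregating); SV insertion/deletion lengths come from a
#' two-mode log-normal mixture centred near 300 bp and 6 kb. Variant spans
#' are kept non-overlapping with a safety margin so that every haploid
#' sample is a valid sequence edit script.
#'
#' @param n_chrom,chrom_len genome shape.
#' @param snv_rate,indel_rate,sv_rate per-bp event rates.
#' @param af_shape1,af_shape2 Beta parameters for allele frequencies.
#' @param sv_modes,sv_mode_probs,sv_mode_sdlog insertion-length mixture.
#' @param margin minimum distance between variant spans (bp).
#' @param seed master seed.
#' @return `population_truth`: list with `ancestral` ([assembly()]),
#'   `catalogue` (contig, pos, ref, alt, vtype, sv, af), `params`.
#' @export
simulate_population <- function(n_chrom = 3, chrom_len = 1e5,
                                snv_rate = 1.2e-3, indel_rate = 2e-4,
                                sv_rate = 1e-5, af_shape1 = 0.8,
                                af_shape2 = 0.8,
                                sv_modes = c(300, 6000),
                                sv_mode_probs = c(0.7, 0.3),
                                sv_mode_sdlog = c(0.25, 0.15),
                                margin = 20, seed = 1) {
  anc <- with_seed(derive_seed(seed, "ancestral"), {
    seqs <- vapply(seq_len(n_chrom), function(i)
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    seqs
  })
  catalogue <- with_seed(derive_seed(seed, "catalogue"), {
    rows <- list()
    for (cn in names(anc)) {
      s <- anc[[cn]]; L <- nchar(s)
      n_snv <- rpois(1, snv_rate * L)
      n_ind <- rpois(1, indel_rate * L)
      n_sv <- rpois(1, sv_rate * L)
      n_tot <- n_snv + n_ind + n_sv
      if (n_tot == 0) next
      vtype <- sample(c(rep("SNV", n_snv), rep("indel", n_ind),
                        rep("SV", n_sv)))
      pos <- sort(sample.int(L - 2, n_tot) + 1)  # keep off the first base
      prev_end <- -margin
      for (i in seq_len(n_tot)) {
        p <- pos[i]
        if (p < prev_end + margin) next
        kind <- vtype[i]
        if (kind == "SNV") {
          ref <- substr(s, p, p)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
          span <- 1
        } else {
          if (kind == "indel") len <- sample.int(10, 1)
          else {
            m <- sample.int(length(sv_modes), 1, prob = sv_mode_probs)
            len <- max(51, round(rlnorm(1, log(sv_modes[m]), sv_mode_sdlog[m])))
          }
          anchor <- substr(s, p, p)
          if (runif(1) < 0.5) {        # insertion
            ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = "")
            ref <- anchor; alt <- paste0(anchor, ins); span <- 1
          } else {                     # deletion
            if (p + len > nchar(s) - margin) next
            ref <- substr(s, p, p + len); alt <- anchor; span <- len + 1
          }
        }
        rows[[length(rows) + 1]] <- new_df(contig = cn, pos = p, ref = ref,
                                           alt = alt,
                                           vtype = if (kind == "SNV") "SNV"
                                                   else if (nchar(alt) > nchar(ref)) "INS"
                                                   else "DEL")
        prev_end <- p + span
      }
    }
    d <- if (length(rows)) do.call(rbind, rows) else
      new_df(contig = character(), pos = integer(), ref = character(),
             alt = character(), vtype = character())
    d$sv <- abs(nchar(d$ref) - nchar(d$alt)) >= 51
    d$af <- if (nrow(d)) rbeta(nrow(d), af_shape1, af_shape2) else numeric(0)
    d
  })
  structure(list(ancestral = assembly("ancestral", anc),
                 catalogue = catalogue,
                 params = list(n_chrom = n_chrom, chrom_len = chrom_len,
                               snv_rate = snv_rate, indel_rate = indel_rate,
                               sv_rate = sv_rate, seed = seed)),
            class = "population_truth")
}

#' Export the population catalogue as an AF panel (ancestral frame)
#' @param truth from [simulate_population()].
#' @return AF-panel data.frame (matches the catalogue exactly).
#' @export
truth_af_panel <- function(truth) {
  d <- truth$catalogue[, c("contig", "pos", "ref", "alt", "af")]
  d$key <- paste(d$contig, d$pos, d$ref, d$alt, sep = ":")
  d
}

#' Sample one haploid assembly from the population truth
#'
#' Each catalogued site's alternate allele is carried independently with
#' probability equal to its population frequency.
#'
#' @param truth from [simulate_population()].
#' @param seed substream seed.
#' @param name assembly name.
#' @return list with `assembly` and `carried` (catalogue + carried flag).
#' @export
sample_haploid_assembly <- function(truth, seed, name = "sample") {
  cat <- truth$catalogue
  carried <- with_seed(derive_seed(seed, paste0("haploid-", name)),
                       rbinom(nrow(cat), 1, cat$af) == 1)
  ap <- apply_variants(truth$ancestral, cat[carried, , drop = FALSE],
                       name = name)
  out_cat <- cat
  out_cat$carried <- carried
  list(assembly = ap$consensus, carried = out_cat, coordmap = ap$coordmap)
}

#' Fragment an assembly into scaffolds with a ground-truth placement table
#'
#' Chromosomes are cut into scaffold/gap alternations; gap segments are
#' dropped sequence (unsequenced), so scaffold lengths plus gap lengths sum
#' to the chromosome length. Scaffolds are randomly reverse-complemented.
#'
#' @param x [assembly()].
#' @param target_n50 target scaffold N50 (bp).
#' @param gap_len_range sampled gap lengths (bp).
#' @param len_sd_frac scaffold length SD as a fraction of `target_n50`.
#' @param seed substream seed.
#' @param prefix scaffold name prefix.
#' @return list with `assembly` (scaffolds) and `placement` (scaffold,
#'   contig, start, end, strand).
#' @export
fragment_into_scaffolds <- function(x, target_n50, gap_len_range = c(100, 1000),
                                    len_sd_frac = 0.25, seed = 1,
                                    prefix = "scf") {
  with_seed(derive_seed(seed, "fragment"), {
    seqs <- character(0)
    placement <- list()
    k <- 0
    for (cn in names(x$seqs)) {
      s <- x$seqs[[cn]]; L <- nchar(s)
      pos <- 0
      while (pos < L) {
        flen <- max(1000, round(rnorm(1, target_n50,
                                      len_sd_frac * target_n50)))
        flen <- min(flen, L - pos)
        k <- k + 1
        nm <- sprintf("%s_%04d", prefix, k)
        strand <- sample(c("+", "-"), 1)
        frag <- substr(s, pos + 1, pos + flen)
        seqs[[nm]] <- if (strand == "+") frag else revcomp(frag)
        placement[[k]] <- new_df(scaffold = nm, contig = cn, start = pos,
                                 end = pos + flen, strand = strand)
        pos <- pos + flen
        if (pos < L) {
          gaps <- gap_len_range[1]:gap_len_range[2]
          gap <- gaps[sample.int(length(gaps), 1)]
          pos <- min(L, pos + gap)
        }
      }
    }
    list(assembly = assembly(paste0(x$name, "-scaffolds"), seqs),
         placement = do.call(rbind, placement))
  })
}

#' Simulate genetic and RH marker maps with primer pairs
#'
#' Markers are placed in variant-free, unique windows of the ancestral
#' genome; primers are exact substrings flanking the amplicon. Genetic maps
#' get low positional noise, RH maps higher, per `map_specs`.
#'
#' @param truth from [simulate_population()].
#' @param markers_per_chrom markers per chromosome.
#' @param primer_len primer length (>= 15).
#' @param amplicon_len sampled amplicon length range (bp).
#' @param map_specs from [default_map_specs()].
#' @param seed substream seed.
#' @return list with `markers` (marker table rows: marker x map) and
#'   `marker_truth` (marker_id, contig, pos).
#' @export
simulate_marker_maps <- function(truth, markers_per_chrom = 24,
                                 primer_len = 20,
                                 amplicon_len = c(150, 400),
                                 map_specs = default_map_specs(),
                                 seed = 1) {
  anc <- truth$ancestral
  cat <- truth$catalogue
  with_seed(derive_seed(seed, "markers"), {
    marker_truth <- list()
    for (cn in names(anc$seqs)) {
      s <- anc$seqs[[cn]]; L <- nchar(s)
      vc <- cat[cat$contig == cn, , drop = FALSE]
      vstart <- vc$pos - 1; vend <- vc$pos - 1 + nchar(vc$ref)
      step <- floor(L / (markers_per_chrom + 1))
      for (i in seq_len(markers_per_chrom)) {
        base <- i * step
        amps <- amplicon_len[1]:amplicon_len[2]
        amp <- amps[sample.int(length(amps), 1)]
        placed <- FALSE
        for (off in seq(0, step - amp, by = 25)) {
          p <- base + off
          if (p + amp > L) break
          # window must be variant-free
          if (any(vstart < p + amp + 2 & vend > p - 2)) next
          fwd <- substr(s, p + 1, p + primer_len)
          rev <- revcomp(substr(s, p + amp - primer_len + 1, p + amp))
          if (grepl("N", fwd) || grepl("N", rev)) next
          # primers must be unique genome-wide (either strand)
          occ <- function(pat) {
            sum(vapply(anc$seqs, function(ss) {
              length(gregexpr(pat, ss, fixed = TRUE)[[1]][
                gregexpr(pat, ss, fixed = TRUE)[[1]] > 0]) +
                length(gregexpr(revcomp(pat), ss, fixed = TRUE)[[1]][
                  gregexpr(revcomp(pat), ss, fixed = TRUE)[[1]] > 0])
            }, numeric(1)))
          }
          if (occ(fwd) != 1 || occ(rev) != 1) next
          marker_truth[[length(marker_truth) + 1]] <-
            new_df(marker_id = sprintf("sts_%s_%03d", cn, i), contig = cn,
                   pos = p, amplicon = amp, primer_fwd = fwd, primer_rev = rev)
          placed <- TRUE
          break
        }
        if (!placed) next
      }
    }
    mt <- do.call(rbind, marker_truth)
    rows <- list()
    for (mi in seq_len(nrow(map_specs))) {
      sc <- map_specs$scale[mi]
      for (cn in unique(mt$contig)) {
        m <- mt[mt$contig == cn, , drop = FALSE]
        map_len <- nchar(anc$seqs[[cn]]) * sc
        noise_sd <- map_specs$noise_frac[mi] * map_len
        # a marker's map position refers to its amplicon midpoint
        mpos <- pmax(0, (m$pos + m$amplicon / 2) * sc +
                       rnorm(nrow(m), 0, noise_sd))
        rows[[length(rows) + 1]] <-
          new_df(marker_id = m$marker_id, map_id = map_specs$map_id[mi],
                 map_type = map_specs$map_type[mi], linkage_group = cn,
                 map_position = mpos, primer_fwd = m$primer_fwd,
                 primer_rev = m$primer_rev, size_min = m$amplicon,
                 size_max = m$amplicon)
      }
    }
    list(markers = do.call(rbind, rows), marker_truth = mt)
  })
}

#' Simulate cross-sample mean depth tracks around shared SVs
#'
#' Per sample, per position, read depth is Poisson(`mean_depth`); the
#' returned track is the mean across `n_samples`. Samples carrying a
#' deletion absent from the track's frame contribute zero depth inside it;
#' samples carrying an insertion absent from the frame pile up at the
#' anchor; when the frame itself carries an insertion, non-carrier samples
#' contribute zero depth across the inserted span.
#'
#' @param lengths named contig lengths of the frame genome.
#' @param svs data.frame: contig, start, end (frame coordinates; for an
#'   absent insertion end = start + 1 anchor), svtype, length, n_carriers,
#'   frame_has_alt.
#' @param n_samples,mean_depth cohort shape.
#' @param seed substream seed.
#' @param pileup_window width of the insertion pile-up spike (bp).
#' @return named list of per-position mean-depth vectors.
#' @export
simulate_depth_tracks <- function(lengths, svs = NULL, n_samples = 200,
                                  mean_depth = 30, seed = 1,
                                  pileup_window = 100) {
  with_seed(derive_seed(seed, "depth"), {
    tracks <- lapply(lengths, function(L)
      rpois(L, mean_depth * n_samples) / n_samples)
    names(tracks) <- names(lengths)
    if (!is.null(svs) && nrow(svs) > 0) {
      for (i in seq_len(nrow(svs))) {
        cn <- svs$contig[i]
        d <- tracks[[cn]]
        k <- svs$n_carriers[i]
        s0 <- svs$start[i]; e0 <- svs$end[i]
        if (svs$svtype[i] == "DEL") {
          if (!svs$frame_has_alt[i]) {
            # frame retains the sequence; carriers contribute nothing inside
            idx <- (s0 + 1):e0
            d[idx] <- rpois(length(idx), mean_depth * (n_samples - k)) / n_samples
          } else if (k < n_samples) {
            # frame lacks the sequence; non-carriers pile up at the junction
            w <- min(pileup_window, length(d) - s0)
            idx <- (s0 + 1):(s0 + w)
            d[idx] <- d[idx] +
              rpois(length(idx), mean_depth * (n_samples - k) * 0.5) / n_samples
          }
        } else { # INS
          if (!svs$frame_has_alt[i]) {
            # carriers' inserted-sequence reads pile at the anchor
            w <- min(pileup_window, svs$length[i])
            lo <- max(1, s0 - floor(w / 2) + 1)
            idx <- lo:min(length(d), lo + w - 1)
            d[idx] <- d[idx] + rpois(length(idx), mean_depth * k) / n_samples
          } else {
            # frame carries the insertion; only carriers map inside it
            idx <- (s0 + 1):e0
            d[idx] <- rpois(length(idx), mean_depth * k) / n_samples
          }
        }
        tracks[[cn]] <- d
      }
    }
    tracks
  })
}

#' Generate a complete, ground-truthed fixture directory
#'
#' Profiles: "tiny" (3 x 100 kb) and "desk" (3 x 1 Mb), both with three
#' haploid samples. The first sample doubles as the backbone (any backbone
#' is accepted downstream).
#'
#' @param profile "tiny" or "desk".
#' @param seed master seed.
#' @param dir output directory (created).
#' @return invisible list of generated objects (truth, samples, markers...).
#' @export
make_fixture <- function(profile = c("tiny", "desk"), seed = 1,
                         dir = tempfile("fixture")) {
  profile <- match.arg(profile)
  chrom_len <- if (profile == "tiny") 1e5 else 1e6
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_population(n_chrom = 3, chrom_len = chrom_len, seed = seed)
  write_fasta(truth$ancestral, file.path(dir, "ancestral.fa"))
  write.table(truth$catalogue, file.path(dir, "truth_catalogue.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_af_panel(truth_af_panel(truth), file.path(dir, "af_panel.tsv"))
  ids <- c("smp_a", "smp_b", "smp_c")
  samples <- lapply(ids, function(id)
    sample_haploid_assembly(truth, seed, name = id))
  names(samples) <- ids
  for (id in ids) {
    write_fasta(samples[[id]]$assembly, file.path(dir, paste0(id, ".fa")))
    write.table(samples[[id]]$carried,
                file.path(dir, paste0(id, "_carried.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  mm <- simulate_marker_maps(truth, seed = seed)
  write_marker_table(mm$markers, file.path(dir, "markers.tsv"))
  write.table(mm$marker_truth, file.path(dir, "marker_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fr <- fragment_into_scaffolds(samples[[1]]$assembly,
                                target_n50 = chrom_len / 5, seed = seed)
  write_fasta(fr$assembly, file.path(dir, "scaffolds.fa"))
  write.table(fr$placement, file.path(dir, "scaffold_placement.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(dir = dir, truth = truth, samples = samples, markers = mm,
                 scaffolds = fr))
}
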