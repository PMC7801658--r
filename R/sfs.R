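# Site-frequency spectrum of the alleles employed in a consensus, measured
# against a population allele-frequency panel.

#' Look up the panel frequency of each employed (non-reference-type) allele
#'
#' For each SNV called consensus-vs-external-reference, the consensus allele
#' is looked up in the panel at the same (contig, pos, ref).
#'
#' @param variants SNV data.frame (contig, pos, ref, alt) on the external
#'   reference frame; `alt` is the allele employed in the consensus.
#' @param panel AF panel from [read_af_panel()].
#' @return input with `af` and `status` (found / missing / allele_mismatch)
#'   columns.
#' @export
employed_allele_freq <- function(variants, panel) {
  keep <- if (!is.null(variants$vtype)) variants$vtype == "SNV"
          else nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  v <- variants[keep, , drop = FALSE]
  key_full <- paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
  key_site <- paste(v$contig, v$pos, sep = ":")
  panel_site <- paste(panel$contig, panel$pos, sep = ":")
  i_full <- match(key_full, panel$key)
  v$af <- panel$af[i_full]
  v$status <- ifelse(!is.na(i_full), "found",
                     ifelse(key_site %in% panel_site, "allele_mismatch",
                            "missing"))
  v$af[v$status != "found"] <- NA_real_
  v
}

#' Build an unfolded site frequency spectrum
#'
#' Bins of width 0.01 over [0, 1); sites with AF exactly 1.0 form their own
#' closed bin. Sites with AF exactly 0 are kept (flagged via the first bin),
#' not dropped.
#'
#' @param per_site from [employed_allele_freq()] (uses `af` and `status`).
#' @return list of class `sfs`: bin_lo, bin_hi, counts, n_missing,
#'   n_allele_mismatch, n_input_sites.
#' @export
build_sfs <- function(per_site) {
  af <- per_site$af[per_site$status == "found"]
  lo <- seq(0, 1, by = 0.01)          # 101 bins; last is the closed [1,1] bin
  hi <- c(seq(0.01, 1, by = 0.01), 1)
  counts <- integer(length(lo))
  if (length(af)) {
    idx <- pmin(findInterval(af, lo), length(lo))
    counts <- tabulate(idx, nbins = length(lo))
  }
  out <- list(bin_lo = lo, bin_hi = hi, counts = counts,
              n_missing = sum(per_site$status == "missing"),
              n_allele_mismatch = sum(per_site$status == "allele_mismatch"),
              n_input_sites = nrow(per_site))
  stopifnot(sum(out$counts) + out$n_missing + out$n_allele_mismatch ==
              out$n_input_sites)
  class(out) <- "sfs"
  out
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("<sfs: %d sites binned, %d missing, %d allele mismatches>\n",
              sum(x$counts), x$n_missing, x$n_allele_mismatch))
  invisible(x)
}

#' Write an SFS as TSV
#' @param sfs from [build_sfs()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path) {
  write.table(new_df(bin_lo = sfs$bin_lo, bin_hi = sfs$bin_hi,
                     count = sfs$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Representativeness of the consensus at high panel frequencies
#'
#' For each AF threshold, counts the consensus sites whose employed allele
#' meets it and reports the percentage of the panel's own site count at
#' that threshold.
#'
#' @param per_site from [employed_allele_freq()], or a numeric vector of AFs.
#' @param panel_totals named numeric vector: panel site counts at each
#'   threshold (denominators; supplied explicitly since they depend on the
#'   panel's scope).
#' @param thresholds named list of predicates; defaults to AF = 1.0,
#'   >= 0.99, >= 0.90.
#' @return data.frame with threshold, count, panel_total, pct (two decimals).
#' @export
representativeness_summary <- function(per_site, panel_totals,
                                       thresholds = NULL) {
  af <- if (is.numeric(per_site)) per_site
        else per_site$af[per_site$status == "found"]
  if (is.null(thresholds))
    thresholds <- list("af=1.0" = function(x) x == 1.0,
                       "af>=0.99" = function(x) x >= 0.99,
                       "af>=0.90" = function(x) x >= 0.90)
  if (any(panel_totals[names(thresholds)] == 0))
    stop_ctx("zero panel total")
  rows <- lapply(names(thresholds), function(nm) {
    cnt <- sum(thresholds[[nm]](af), na.rm = TRUE)
    tot <- panel_totals[[nm]]
    new_df(threshold = nm, count = cnt, panel_total = tot,
           pct = round(100 * cnt / tot, 2))
  })
  do.call(rbind, rows)
}
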