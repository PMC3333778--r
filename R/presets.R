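# Built-in simulation presets.
#
# Miniature genomes (three chromosomes, 1 marker/kb) emulating the study
# designs the package is validated on: a near-triploid tumor with 35
# aberrations (14 with LOH) for the dilution-series benchmark, a balanced
# diploid genome with aberrations, a subclonal-deletion scenario, and a
# double-minute-like run of short amplicons.

# Build a region table from per-chromosome (n_markers, c, m[, clone])
# rows; marker spacing 1 kb, regions contiguous from bp 1.
regions_from_counts <- function(spec_list, spacing = 1000) {
  out <- NULL
  for (chr in names(spec_list)) {
    m <- spec_list[[chr]]
    n <- m[, 1L]
    end <- cumsum(n) * spacing
    start <- c(1, utils::head(end, -1L) + 1)
    out <- rbind(out, data.frame(
      chrom = chr, start = start, end = end, c = m[, 2L], m = m[, 3L],
      clone_fraction = if (ncol(m) >= 4L) m[, 4L] else 1,
      stringsAsFactors = FALSE))
  }
  out
}

#' Simulation presets
#'
#' Ready-made [truth_profile()]s:
#' * `"triploid"` (alias `"dilution"`): near-triploid genome (average
#'   tumor ploidy ~3.35), 60,000 markers on three chromosomes, 35
#'   aberrant regions of which 14 have minor copy number 0 (LOH), copy
#'   numbers up to 8; the base karyotype of the dilution-series
#'   benchmark.
#' * `"diploid"`: average tumor ploidy exactly 2.0 with balanced gains
#'   and losses, including a homozygous deletion (cn0).
#' * `"subclone"`: one chromosome carrying a clonal hemizygous deletion
#'   and an 800-marker deletion present in only 50% of tumor cells,
#'   flanked by unaltered segments.
#' * `"dm"`: a chromosome with three 250-marker amplicons (cn 4, 6, 8,
#'   minor copy 1) on an LOH background, the double-minute-like scenario
#'   for short-segment analysis.
#'
#' @param name preset name.
#' @param tumor_fraction tumor cell fraction f.
#' @param ... passed to [truth_profile()] (e.g. `noise`, `het_rate`).
#' @return a `truth_profile`.
#' @export
preset_profile <- function(name = c("triploid", "dilution", "diploid",
                                    "subclone", "dm"),
                           tumor_fraction = 1.0, ...) {
  name <- match.arg(name)
  if (name == "dilution") name <- "triploid"
  k <- switch(name,
    triploid = list(
      chr1 = rbind(
        c(2500, 2, 1), c(2000, 3, 1), c(1200, 2, 0), c(1800, 4, 2),
        c(1000, 1, 0), c(2000, 4, 0), c(2200, 3, 0), c(700, 2, 1),
        c(2000, 4, 1), c(1300, 3, 1), c(1500, 5, 2), c(1000, 2, 0),
        c(800, 4, 1), c(1000, 3, 1), c(1000, 7, 2)),
      chr2 = rbind(
        c(2800, 2, 1), c(2000, 3, 0), c(1500, 4, 1), c(1200, 1, 0),
        c(1700, 3, 1), c(800, 8, 2), c(1000, 2, 0), c(1200, 2, 1),
        c(800, 5, 1), c(1800, 4, 2), c(1200, 5, 1), c(1500, 3, 0),
        c(1500, 6, 2), c(1000, 4, 0)),
      chr3 = rbind(
        c(2200, 2, 1), c(1500, 3, 1), c(1800, 4, 0), c(1000, 2, 0),
        c(2000, 4, 1), c(1500, 1, 0), c(2000, 3, 1), c(1500, 5, 2),
        c(1300, 3, 0), c(1200, 6, 3), c(1200, 2, 1), c(800, 6, 1))),
    diploid = list(
      chr1 = rbind(
        c(3000, 2, 1), c(1500, 1, 0), c(2000, 2, 0), c(1500, 3, 1),
        c(4000, 2, 1)),
      chr2 = rbind(
        c(2500, 2, 1), c(2000, 3, 1), c(2500, 2, 1), c(2000, 1, 0),
        c(1500, 2, 0), c(1500, 2, 1)),
      chr3 = rbind(
        c(3000, 2, 1), c(1600, 4, 2), c(3000, 2, 1), c(800, 0, 0),
        c(1600, 1, 0), c(2000, 2, 1))),
    subclone = list(
      chr1 = rbind(
        c(2500, 2, 1, 1), c(1500, 1, 0, 1), c(2000, 2, 1, 1),
        c(800, 1, 0, 0.5), c(2200, 2, 1, 1))),
    dm = list(
      chr1 = rbind(
        c(2500, 2, 1), c(2000, 3, 1), c(1500, 2, 0), c(250, 4, 1),
        c(400, 2, 0), c(250, 6, 1), c(400, 2, 0), c(250, 8, 1),
        c(1450, 2, 0), c(1000, 2, 1))))
  truth_profile(regions_from_counts(k), tumor_fraction = tumor_fraction,
                ...)
}
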