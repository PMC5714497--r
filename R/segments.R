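#' Segment qualification criteria
#'
#' A shared haplotype segment qualifies if it contains at least
#' `min_markers` consecutive identical markers and spans at least
#' `min_length_mb` megabases (first to last marker of the run). A marker of
#' a focal haplotype is classified native when the frequency of haplotypes
#' carrying a qualifying shared segment covering that marker is strictly
#' below `max_ref_freq` in every reference breed.
#'
#' @param min_markers minimum number of consecutive identical markers
#'   (default 20).
#' @param min_length_mb minimum physical span in Mb (default 2.5).
#' @param max_ref_freq native-classification frequency threshold
#'   (default 0.01, strict `<`).
#' @return An object of class `segment_criteria`.
#' @export
segment_criteria <- function(min_markers = 20, min_length_mb = 2.5,
                             max_ref_freq = 0.01) {
  if (min_markers < 2) stop("min_markers must be >= 2")
  if (min_length_mb <= 0) stop("min_length_mb must be positive")
  if (max_ref_freq <= 0 || max_ref_freq >= 1)
    stop("max_ref_freq must be in (0, 1)")
  structure(list(min_markers = as.integer(min_markers),
                 min_length_mb = min_length_mb,
                 max_ref_freq = max_ref_freq),
            class = "segment_criteria")
}

#' Qualifying shared segments between two haplotypes
#'
#' Finds the maximal runs of marker-wise allele identity between two
#' haplotypes, per chromosome, that meet both qualification thresholds.
#'
#' @param h1,h2 integer 0/1 vectors of equal length, one allele per marker
#'   of `map`.
#' @param map a `marker_map`.
#' @param criteria a [segment_criteria()].
#' @return data.frame with one row per qualifying segment: `chromosome`,
#'   `start_marker`, `end_marker` (1-based indices into the map),
#'   `start_bp`, `end_bp`, `n_markers`, `length_mb`.
#' @export
shared_segments <- function(h1, h2, map, criteria = segment_criteria()) {
  if (length(h1) != nrow(map) || length(h2) != nrow(map))
    stop("haplotype length must equal the number of markers in the map")
  blocks <- chrom_blocks(map)
  runs <- cpp_pair_runs(as.integer(h1), as.integer(h2), blocks$start,
                        blocks$end, map$position_bp, criteria$min_markers,
                        criteria$min_length_mb * 1e6)
  s <- runs[, 1]
  e <- runs[, 2]
  data.frame(chromosome = map$chromosome[s],
             start_marker = s, end_marker = e,
             start_bp = map$position_bp[s], end_bp = map$position_bp[e],
             n_markers = e - s + 1L,
             length_mb = (map$position_bp[e] - map$position_bp[s]) / 1e6,
             stringsAsFactors = FALSE)
}

#' Native/migrant classification of focal haplotypes
#'
#' For each haplotype of the focal panel and each marker, computes in every
#' reference breed the frequency of haplotypes that share a qualifying
#' segment covering the marker with the focal haplotype. The marker is
#' native iff this frequency is strictly below `criteria$max_ref_freq` in
#' all reference breeds.
#'
#' @param focal `haplotype_panel` of the focal breed.
#' @param refs `haplotype_panel` containing the reference breeds (its
#'   `breed` labels define the breed grouping).
#' @param criteria a [segment_criteria()].
#' @return logical matrix (markers x focal haplotypes), `TRUE` = native,
#'   with the focal haplotype names as column names.
#' @export
native_mask <- function(focal, refs, criteria = segment_criteria()) {
  if (!identical(focal$map$marker_id, refs$map$marker_id))
    stop("focal and reference panels must share the marker map")
  breeds <- unique(refs$breed)
  if (length(breeds) == 0 || n_individuals(refs) == 0)
    stop("at least one non-empty reference breed is required")
  blocks <- chrom_blocks(focal$map)
  native <- matrix(TRUE, nrow(focal$map), ncol(focal$alleles))
  for (b in breeds) {
    idx <- which(refs$breed == b)
    Hr <- refs$alleles[, hap_cols(idx), drop = FALSE]
    counts <- cpp_share_counts(focal$alleles, Hr, blocks$start, blocks$end,
                               focal$map$position_bp, criteria$min_markers,
                               criteria$min_length_mb * 1e6)
    native <- native & (counts / ncol(Hr) < criteria$max_ref_freq)
  }
  colnames(native) <- colnames(focal$alleles)
  native
}

#' Migrant contribution per individual
#'
#' The proportion of an individual's genome not classified native,
#' averaged over its two haplotypes and weighted by [marker_weights()].
#'
#' @param mask logical native mask from [native_mask()] covering both
#'   haplotypes of each individual.
#' @param map the `marker_map` the mask was computed on.
#' @param weighting `"length"` (default) or `"count"`, see
#'   [marker_weights()].
#' @return numeric vector of MC values in \[0, 1\], one per individual.
#' @export
migrant_contribution <- function(mask, map, weighting = "length") {
  if (ncol(mask) %% 2 != 0)
    stop("mask must cover both haplotypes of each individual")
  w <- marker_weights(map, weighting)
  nat_hap <- colSums(mask * w)
  n <- ncol(mask) / 2
  mc <- unname(1 - (nat_hap[seq(1, 2 * n, by = 2)] +
                      nat_hap[seq(2, 2 * n, by = 2)]) / 2)
  if (!is.null(colnames(mask)))
    names(mc) <- sub("\\.1$", "", colnames(mask)[seq(1, 2 * n, by = 2)])
  mc
}

#' True migrant fraction of simulated focal haplotypes
#'
#' Reads the ground-truth origin labels retained by
#' [simulate_breed_panels()] and returns the per-individual migrant genome
#' fraction under the same genome weighting as [migrant_contribution()].
#'
#' @param panel a panel carrying a `true_origin` attribute (markers x
#'   focal haplotypes, `TRUE` = migrant).
#' @param weighting `"length"` or `"count"`.
#' @return numeric vector, one value per focal individual.
#' @export
true_migrant_fraction <- function(panel, weighting = "length") {
  origin <- attr(panel, "true_origin")
  if (is.null(origin)) stop("panel carries no true_origin ground truth")
  migrant_contribution(!origin, panel$map, weighting)
}
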