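#' Segment-based kinship matrix
#'
#' The kinship `fSEG` between individuals i and j is the probability that
#' two alleles taken from a random genome position on randomly chosen
#' haplotypes of the two individuals lie on a qualifying shared segment:
#' the average over the four haplotype pairings of the genome fraction
#' covered by qualifying shared segments of that pairing. For i = j the two
#' same-haplotype pairings each contribute 1, so diagonal entries are at
#' least 0.5.
#'
#' @param panel a phased `haplotype_panel`.
#' @param criteria a [segment_criteria()].
#' @param weighting `"length"` (default) or `"count"` genome weighting.
#' @return symmetric matrix with individual ids as dimnames.
#' @export
fseg_matrix <- function(panel, criteria = segment_criteria(),
                        weighting = "length") {
  blocks <- chrom_blocks(panel$map)
  w <- marker_weights(panel$map, weighting)
  cov <- cpp_coverage_matrix(panel$alleles, blocks$start, blocks$end,
                             panel$map$position_bp, w,
                             criteria$min_markers,
                             criteria$min_length_mb * 1e6)
  pairings_to_individuals(cov, panel$individual_id)
}

# Average a haplotype-by-haplotype matrix over the 2x2 pairings of each
# individual pair.
pairings_to_individuals <- function(M, ids) {
  n <- length(ids)
  o <- seq(1, 2 * n, by = 2)
  e <- o + 1
  F <- (M[o, o, drop = FALSE] + M[o, e, drop = FALSE] +
          M[e, o, drop = FALSE] + M[e, e, drop = FALSE]) / 4
  F <- (F + t(F)) / 2
  dimnames(F) <- list(ids, ids)
  F
}

#' Numerator and denominator matrices for kinship at native alleles
#'
#' The kinship at native alleles `fSEG|N` is the conditional probability
#' that two randomly sampled alleles lie on a qualifying shared segment
#' given that both are native. Its population value under contributions c
#' is `(c' Snat c) / (c' Dnat c)` where, per individual pair, `Snat`
#' integrates positions that are covered by a qualifying shared segment and
#' native on both sampled haplotypes, and `Dnat` integrates positions
#' native on both (each averaged over the four haplotype pairings).
#'
#' @param panel a phased `haplotype_panel`.
#' @param mask logical native mask from [native_mask()] for this panel.
#' @param criteria a [segment_criteria()].
#' @param weighting genome weighting, as in [fseg_matrix()].
#' @return list with symmetric matrices `Snat` and `Dnat`.
#' @export
fseg_native_matrices <- function(panel, mask,
                                 criteria = segment_criteria(),
                                 weighting = "length") {
  if (!identical(dim(mask), dim(panel$alleles)))
    stop("mask must match the panel's marker x haplotype layout")
  blocks <- chrom_blocks(panel$map)
  w <- marker_weights(panel$map, weighting)
  snum <- cpp_native_shared(panel$alleles, mask, blocks$start, blocks$end,
                            panel$map$position_bp, w,
                            criteria$min_markers,
                            criteria$min_length_mb * 1e6)
  dnum <- crossprod(mask * sqrt(w))
  list(Snat = pairings_to_individuals(snum, panel$individual_id),
       Dnat = pairings_to_individuals(dnum, panel$individual_id))
}

#' Bundle kinship components
#'
#' @param F segment-based kinship matrix ([fseg_matrix()]).
#' @param Snat,Dnat native-kinship numerator/denominator matrices
#'   ([fseg_native_matrices()]).
#' @param mc migrant-contribution vector ([migrant_contribution()]).
#' @return An object of class `kinship_set`.
#' @export
kinship_set <- function(F, Snat, Dnat, mc) {
  n <- nrow(F)
  stopifnot(nrow(Snat) == n, nrow(Dnat) == n, length(mc) == n)
  structure(list(F = F, Snat = Snat, Dnat = Dnat, mc = as.numeric(mc),
                 ids = rownames(F)),
            class = "kinship_set")
}

#' Compute the full kinship set of a focal panel
#'
#' Convenience wrapper running [native_mask()], [fseg_matrix()],
#' [fseg_native_matrices()] and [migrant_contribution()] in one call.
#'
#' @param focal focal `haplotype_panel`.
#' @param refs reference-breed `haplotype_panel`.
#' @param criteria a [segment_criteria()].
#' @param weighting genome weighting.
#' @param mask optional precomputed native mask (e.g. propagated from the
#'   parental generation by [advance_generation()]); computed with
#'   [native_mask()] when `NULL`.
#' @return A `kinship_set`.
#' @export
compute_kinship_set <- function(focal, refs,
                                criteria = segment_criteria(),
                                weighting = "length", mask = NULL) {
  if (is.null(mask)) mask <- native_mask(focal, refs, criteria)
  F <- fseg_matrix(focal, criteria, weighting)
  nat <- fseg_native_matrices(focal, mask, criteria, weighting)
  kinship_set(F, nat$Snat, nat$Dnat,
              migrant_contribution(mask, focal$map, weighting))
}

#' Population summaries under a contribution vector
#'
#' Mean kinship `c'Fc`, mean kinship at native alleles
#' `(c'Snat c)/(c'Dnat c)` and mean migrant contribution `c'm` for a
#' contribution vector c (uniform by default).
#'
#' @param kin a `kinship_set`.
#' @param c contribution vector (non-negative, summing to 1); `NULL` means
#'   uniform `1/n`.
#' @return list with `fseg`, `fseg_native`, `mc`.
#' @export
population_summaries <- function(kin, c = NULL) {
  n <- nrow(kin$F)
  if (is.null(c)) c <- rep(1 / n, n)
  if (length(c) != n || any(c < -1e-12) || abs(sum(c) - 1) > 1e-8)
    stop("c must be a non-negative vector summing to 1")
  d <- drop(c %*% kin$Dnat %*% c)
  if (d <= 0)
    stop("no native genome under these contributions; fSEG|N undefined")
  list(fseg = drop(c %*% kin$F %*% c),
       fseg_native = drop(c %*% kin$Snat %*% c) / d,
       mc = sum(c * kin$mc))
}

#' Breed-average segment-based kinship table
#'
#' Computes `fSEG` on a combined multi-breed panel and averages within and
#' between breeds. Between-breed entries are the mean over all cross-breed
#' pairs; within-breed entries average all pairs of the breed including
#' each individual's self-kinship by default (`within_diagonal = TRUE`,
#' giving the population mean kinship), or off-diagonal pairs only.
#'
#' @param panel combined multi-breed `haplotype_panel`.
#' @param criteria a [segment_criteria()].
#' @param within_diagonal include self-kinship in within-breed averages.
#' @param weighting genome weighting.
#' @return symmetric breed x breed matrix of average kinships.
#' @export
breed_average_kinship <- function(panel, criteria = segment_criteria(),
                                  within_diagonal = TRUE,
                                  weighting = "length") {
  F <- fseg_matrix(panel, criteria, weighting)
  breeds <- unique(panel$breed)
  out <- matrix(NA_real_, length(breeds), length(breeds),
                dimnames = list(breeds, breeds))
  for (a in seq_along(breeds)) {
    for (b in seq_len(a)) {
      ia <- which(panel$breed == breeds[a])
      ib <- which(panel$breed == breeds[b])
      block <- F[ia, ib, drop = FALSE]
      if (a == b && !within_diagonal && length(ia) > 1)
        out[a, b] <- mean(block[row(block) != col(block)])
      else out[a, b] <- mean(block)
      out[b, a] <- out[a, b]
    }
  }
  out
}

#' Project a symmetric matrix to the nearest positive semidefinite one
#'
#' Floors negative eigenvalues at zero. Estimated kinship matrices need not
#' be PSD, but the quadratic constraints of the contribution optimizer
#' require it; flooring is the minimal perturbation preserving the
#' constraint's meaning.
#'
#' @param m symmetric matrix.
#' @param tol eigenvalues below `-tol` trigger the projection.
#' @return PSD matrix with the same dimnames.
#' @export
nearest_psd <- function(m, tol = 1e-10) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  if (all(ev$values >= -tol)) return(m)
  v <- pmax(ev$values, 0)
  out <- ev$vectors %*% (v * t(ev$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  out
}
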