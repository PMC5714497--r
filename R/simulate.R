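#' Sample crossover positions on a chromosome
#'
#' Crossover counts are Poisson with mean equal to the genetic length in
#' Morgans (no interference), and breakpoint positions are uniform on the
#' genetic map between the terminal markers.
#'
#' @param cm_start,cm_end genetic positions (cM) of the chromosome's first
#'   and last marker.
#' @return numeric vector of breakpoint positions in cM (possibly empty).
#' @export
sample_breakpoints <- function(cm_start, cm_end) {
  len_morgan <- (cm_end - cm_start) / 100
  if (len_morgan <= 0) return(numeric(0))
  k <- rpois(1, len_morgan)
  if (k == 0) return(numeric(0))
  sort(runif(k, cm_start, cm_end))
}

#' Meiosis: sample one gamete from a parent
#'
#' Per chromosome, the starting parental haplotype is chosen with
#' probability 0.5 and the gamete switches source haplotype at each
#' crossover breakpoint.
#'
#' @param h1,h2 the parent's two haplotypes (integer vectors over the map).
#' @param map a `marker_map` (its `position_cM` column drives
#'   recombination; 1 cM = 1 Mb when built from bp only).
#' @param blocks precomputed [chrom_blocks()] of the map (optional).
#' @return integer gamete haplotype with attributes `n_crossovers` and
#'   `source` (0 = first parental haplotype, 1 = second, per marker; used
#'   to propagate per-marker annotations such as native masks).
#' @export
meiosis <- function(h1, h2, map, blocks = chrom_blocks(map)) {
  gamete <- integer(nrow(map))
  source <- integer(nrow(map))
  n_xo <- 0L
  for (c in seq_along(blocks$start)) {
    idx <- (blocks$start[c] + 1L):(blocks$end[c] + 1L)
    cm <- map$position_cM[idx]
    bp <- sample_breakpoints(cm[1], cm[length(cm)])
    n_xo <- n_xo + length(bp)
    # source haplotype index per marker: start + number of breakpoints passed
    src <- (sample(0:1, 1) + findInterval(cm, bp)) %% 2
    gamete[idx] <- ifelse(src == 0, h1[idx], h2[idx])
    source[idx] <- src
  }
  attr(gamete, "n_crossovers") <- n_xo
  attr(gamete, "source") <- source
  gamete
}

new_generation_panel <- function(map, alleles, prefix, n, sex) {
  haplotype_panel(map, alleles, sprintf("%s_%04d", prefix, seq_len(n)),
                  rep("Angler", n), sex)
}

# Exact-count sex assignment: half male, half female, randomly placed.
assign_sexes <- function(n) {
  sex <- rep(c("M", "F"), length.out = n)
  sample(sex)
}

#' Assemble a base generation from founder genotypes
#'
#' Each base individual receives one gamete from a uniformly sampled (with
#' replacement) male founder and one from a female founder. Sexes are
#' assigned to hit an exact half-and-half split.
#'
#' @param founders `haplotype_panel` containing both sexes.
#' @param n base-population size (default 1000).
#' @param id_prefix prefix for the new individual ids.
#' @param seed integer seed.
#' @return A `haplotype_panel` of `n` individuals.
#' @export
make_base_generation <- function(founders, n = 1000, id_prefix = "G0",
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  males <- which(founders$sex == "M")
  females <- which(founders$sex == "F")
  if (length(males) == 0 || length(females) == 0)
    stop("founders must contain both sexes")
  blocks <- chrom_blocks(founders$map)
  alleles <- matrix(0L, nrow(founders$map), 2 * n)
  for (i in seq_len(n)) {
    s <- sample(males, 1)
    d <- sample(females, 1)
    alleles[, 2 * i - 1] <- meiosis(founders$alleles[, 2 * s - 1],
                                    founders$alleles[, 2 * s],
                                    founders$map, blocks)
    alleles[, 2 * i] <- meiosis(founders$alleles[, 2 * d - 1],
                                founders$alleles[, 2 * d],
                                founders$map, blocks)
  }
  new_generation_panel(founders$map, alleles, id_prefix, n, assign_sexes(n))
}

#' Advance one generation
#'
#' Offspring slots are filled dam by dam (each dam exactly her count) and
#' sires are assigned by a random permutation respecting the requested sire
#' counts; mates are thus allocated randomly. Offspring haplotypes are
#' produced by [meiosis()] from both parents; sexes are assigned
#' half-and-half exactly.
#'
#' @param parents `haplotype_panel` of the current generation.
#' @param counts integer offspring counts per parent
#'   ([contributions_to_counts()]); male counts must sum to the total,
#'   female counts must be equal.
#' @param id_prefix prefix for offspring ids.
#' @param seed integer seed.
#' @param mask optional logical per-marker annotation of the parental
#'   haplotypes (markers x 2 n_parents, e.g. a native mask); it is
#'   propagated through the same meiosis realizations and returned as the
#'   `mask` attribute of the offspring panel.
#' @return A `haplotype_panel` of the offspring generation, with attribute
#'   `pedigree` (data.frame of offspring, sire and dam indices) and, when
#'   `mask` was given, attribute `mask`.
#' @export
advance_generation <- function(parents, counts, id_prefix = "G1",
                               seed = NULL, mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mi <- which(parents$sex == "M")
  fi <- which(parents$sex == "F")
  n_off <- sum(counts[fi])
  if (sum(counts[mi]) != n_off)
    stop("male and female offspring counts must agree")
  if (length(unique(counts[fi])) != 1)
    stop("the equal-dam policy requires identical dam counts")
  dam_of <- rep(fi, counts[fi])
  sire_of <- sample(rep(mi, counts[mi]))
  blocks <- chrom_blocks(parents$map)
  alleles <- matrix(0L, nrow(parents$map), 2 * n_off)
  off_mask <- if (is.null(mask)) NULL else
    matrix(FALSE, nrow(parents$map), 2 * n_off)
  gamete_from <- function(p, col) {
    g <- meiosis(parents$alleles[, 2 * p - 1], parents$alleles[, 2 * p],
                 parents$map, blocks)
    alleles[, col] <<- g
    if (!is.null(mask)) {
      src <- attr(g, "source")
      off_mask[, col] <<- ifelse(src == 0, mask[, 2 * p - 1],
                                 mask[, 2 * p])
    }
  }
  for (i in seq_len(n_off)) {
    gamete_from(sire_of[i], 2 * i - 1)
    gamete_from(dam_of[i], 2 * i)
  }
  off <- new_generation_panel(parents$map, alleles, id_prefix, n_off,
                              assign_sexes(n_off))
  attr(off, "pedigree") <- data.frame(offspring = seq_len(n_off),
                                      sire = sire_of, dam = dam_of)
  if (!is.null(mask)) {
    colnames(off_mask) <- colnames(off$alleles)
    attr(off, "mask") <- off_mask
  }
  off
}
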