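#' Breed model for synthetic admixed populations
#'
#' Describes the statistical structure of the synthetic study system: a
#' focal breed with historical introgression plus several reference breeds.
#' Reference-breed and native-pool allele frequencies follow the
#' Balding-Nichols model around a shared ancestral frequency; focal founder
#' haplotypes are mosaics of native-pool and reference-breed haplotype
#' blocks with exponentially distributed lengths.
#'
#' The default mixture weights follow the estimated composition of the
#' migrant genome of an admixed dual-purpose cattle breed (dominated by the
#' Holstein group, minor Norwegian Red and Fleckvieh shares), and the
#' default target migrant proportion is 0.62.
#'
#' @param ref_breeds reference breed names.
#' @param mix_weights migrant-source mixture weights over `ref_breeds`
#'   (normalized internally).
#' @param mc_target mean migrant proportion of focal founders in \[0, 1\].
#' @param mc_sd between-individual SD of the migrant proportion: each
#'   founder draws its own ancestry level from a Beta distribution with
#'   mean `mc_target` and this SD (0 gives every founder the same
#'   proportion). Individual ancestry variation is what makes the
#'   chromosome components of the breeding values covary and links
#'   migrant contribution to merit across the whole genome.
#' @param block_mean_mb mean mosaic block length in Mb (default 10, so
#'   introgressed blocks comfortably exceed the 2.5 Mb detection
#'   threshold).
#' @param fst_ref Balding-Nichols drift parameter per reference breed.
#' @param fst_native drift parameter of the native pool.
#' @param pool_haplotypes number of distinct native-pool haplotypes the
#'   focal founders are mosaics of; controls within-breed segment sharing
#'   of the focal breed.
#' @param ref_pool_haplotypes per-breed pool size of the reference breeds;
#'   reference panels are mosaics of this pool, so migrant material taken
#'   from a breed is co-ancestral (as when introgression stems from a few
#'   related high-yielding ancestors) and migrant segments occur in the
#'   reference panel at frequency around `1 / ref_pool_haplotypes`.
#' @param beta_shape1,beta_shape2 ancestral allele-frequency Beta
#'   parameters.
#' @param freq_bounds truncation interval for ancestral frequencies.
#' @return An object of class `breed_model`.
#' @export
breed_model <- function(ref_breeds = c("HolsteinFriesian", "RedHolstein",
                                       "NorwegianRed", "Fleckvieh"),
                        mix_weights = c(0.224, 0.224, 0.152, 0.021),
                        mc_target = 0.62,
                        mc_sd = 0.15,
                        block_mean_mb = 10,
                        fst_ref = rep(0.10, length(ref_breeds)),
                        fst_native = 0.10,
                        pool_haplotypes = 40,
                        ref_pool_haplotypes = 10,
                        beta_shape1 = 0.8, beta_shape2 = 0.8,
                        freq_bounds = c(0.05, 0.95)) {
  if (mc_target < 0 || mc_target > 1) stop("mc_target must be in [0, 1]")
  if (mc_sd < 0 || mc_sd^2 >= mc_target * (1 - mc_target) + 1e-12)
    mc_sd <- if (mc_target %in% c(0, 1)) 0 else
      stop("mc_sd too large for the given mc_target")
  if (length(mix_weights) != length(ref_breeds))
    stop("one mixture weight per reference breed")
  if (any(mix_weights < 0) || sum(mix_weights) <= 0)
    stop("mixture weights must be non-negative and not all zero")
  if (any(fst_ref <= 0 | fst_ref >= 1) || fst_native <= 0 || fst_native >= 1)
    stop("drift parameters must be in (0, 1)")
  structure(list(ref_breeds = ref_breeds,
                 mix_weights = mix_weights / sum(mix_weights),
                 mc_target = mc_target, mc_sd = mc_sd,
                 block_mean_mb = block_mean_mb,
                 fst_ref = setNames(fst_ref, ref_breeds),
                 fst_native = fst_native,
                 pool_haplotypes = as.integer(pool_haplotypes),
                 ref_pool_haplotypes = as.integer(ref_pool_haplotypes),
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                 freq_bounds = freq_bounds),
            class = "breed_model")
}

rbeta_trunc <- function(n, s1, s2, lo, hi) {
  p <- stats::rbeta(n, s1, s2)
  bad <- p < lo | p > hi
  while (any(bad)) {
    p[bad] <- stats::rbeta(sum(bad), s1, s2)
    bad <- p < lo | p > hi
  }
  p
}

# Per-founder migrant proportions: Beta with the requested mean and SD
# (both haplotypes of a founder share its ancestry level).
founder_mc_levels <- function(n, mean, sd) {
  if (sd == 0 || mean %in% c(0, 1)) return(rep(mean, n))
  nu <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

balding_nichols <- function(p_anc, fst) {
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  stats::rbeta(length(p_anc), a, b)
}

draw_haps <- function(freq, n_hap) {
  matrix(rbinom(length(freq) * n_hap, 1L, rep(freq, n_hap)),
         nrow = length(freq))
}

# Sample one mosaic haplotype: per chromosome, exponential-length blocks,
# each independently migrant with probability mc_target; block alleles are
# copied from a uniformly chosen source haplotype of the native pool or of
# the chosen reference breed's pool.
mosaic_haplotype <- function(map, blocks, model, pool, ref_pools,
                             mc_prob = model$mc_target) {
  m <- nrow(map)
  hap <- integer(m)
  origin <- logical(m)  # TRUE = migrant
  mean_bp <- model$block_mean_mb * 1e6
  for (c in seq_along(blocks$start)) {
    lo <- blocks$start[c] + 1L
    hi <- blocks$end[c] + 1L
    pos <- map$position_bp[lo:hi]
    at <- pos[1]
    while (at <= pos[length(pos)]) {
      len <- rexp(1, 1 / mean_bp)
      in_block <- (lo:hi)[pos >= at & pos < at + len]
      at <- at + len
      if (length(in_block) == 0) next
      if (runif(1) < mc_prob) {
        b <- sample(length(model$ref_breeds), 1, prob = model$mix_weights)
        src <- ref_pools[[b]][, sample(ncol(ref_pools[[b]]), 1)]
        hap[in_block] <- src[in_block]
        origin[in_block] <- TRUE
      } else {
        src <- pool[, sample(ncol(pool), 1)]
        hap[in_block] <- src[in_block]
      }
    }
  }
  list(hap = hap, origin = origin)
}

# One haplotype copied block-wise from a single pool (within-breed mosaic).
pool_mosaic <- function(map, blocks, mean_bp, pool) {
  m <- nrow(map)
  hap <- integer(m)
  for (c in seq_along(blocks$start)) {
    lo <- blocks$start[c] + 1L
    hi <- blocks$end[c] + 1L
    pos <- map$position_bp[lo:hi]
    at <- pos[1]
    while (at <= pos[length(pos)]) {
      len <- rexp(1, 1 / mean_bp)
      in_block <- (lo:hi)[pos >= at & pos < at + len]
      at <- at + len
      if (length(in_block) == 0) next
      hap[in_block] <- pool[in_block, sample(ncol(pool), 1)]
    }
  }
  hap
}

#' Simulate founder panels for the focal and reference breeds
#'
#' Each reference breed descends from a small pool of haplotypes drawn
#' marker-independently from breed-specific Balding-Nichols frequencies;
#' its panel haplotypes are block mosaics of that pool, which creates
#' realistic within-breed segment sharing. Focal founders are mosaics of
#' native-pool and reference-pool blocks (exponential block lengths, each
#' block migrant with probability `mc_target`, migrant source breed drawn
#' by the mixture weights), so migrant material taken from a breed is
#' co-ancestral with that breed's panel. The true per-marker origin of
#' every focal haplotype is retained as ground truth in the `true_origin`
#' attribute of the returned panel (markers x focal haplotypes, `TRUE` =
#' migrant).
#'
#' @param model a [breed_model()].
#' @param map a `marker_map`.
#' @param n_focal number of focal founders (sexes alternate M/F).
#' @param n_ref integer vector: individuals per reference breed.
#' @param focal_breed name of the focal breed (default `"Angler"`).
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return A [haplotype_panel()] containing the focal breed followed by the
#'   reference breeds, with attribute `true_origin`.
#' @export
simulate_breed_panels <- function(model, map, n_focal,
                                  n_ref = rep(40, length(model$ref_breeds)),
                                  focal_breed = "Angler", seed = NULL) {
  if (nrow(map) == 0) stop("map must be non-empty")
  if (n_focal < 1 || any(n_ref < 1)) stop("at least one individual per breed")
  if (length(n_ref) != length(model$ref_breeds))
    stop("one panel size per reference breed")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  p_anc <- rbeta_trunc(m, model$beta_shape1, model$beta_shape2,
                       model$freq_bounds[1], model$freq_bounds[2])
  blocks <- chrom_blocks(map)
  mean_bp <- model$block_mean_mb * 1e6
  ref_pools <- vector("list", length(model$ref_breeds))
  ref_haps <- vector("list", length(model$ref_breeds))
  for (b in seq_along(model$ref_breeds)) {
    pb <- balding_nichols(p_anc, model$fst_ref[b])
    ref_pools[[b]] <- draw_haps(pb, model$ref_pool_haplotypes)
    ref_haps[[b]] <- sapply(seq_len(2 * n_ref[b]), function(h)
      pool_mosaic(map, blocks, mean_bp, ref_pools[[b]]))
  }
  p_nat <- balding_nichols(p_anc, model$fst_native)
  pool <- draw_haps(p_nat, model$pool_haplotypes)
  focal_alleles <- matrix(0L, m, 2 * n_focal)
  origin <- matrix(FALSE, m, 2 * n_focal)
  mc_ind <- founder_mc_levels(n_focal, model$mc_target, model$mc_sd)
  for (h in seq_len(2 * n_focal)) {
    mh <- mosaic_haplotype(map, blocks, model, pool, ref_pools,
                           mc_prob = mc_ind[ceiling(h / 2)])
    focal_alleles[, h] <- mh$hap
    origin[, h] <- mh$origin
  }
  ids <- c(sprintf("%s_%03d", focal_breed, seq_len(n_focal)),
           unlist(lapply(seq_along(model$ref_breeds), function(b)
             sprintf("%s_%03d", model$ref_breeds[b], seq_len(n_ref[b])))))
  breed <- c(rep(focal_breed, n_focal),
             rep(model$ref_breeds, times = n_ref))
  sex <- unlist(lapply(c(n_focal, n_ref), function(n)
    rep(c("M", "F"), length.out = n)))
  panel <- haplotype_panel(map, cbind(focal_alleles,
                                      do.call(cbind, ref_haps)),
                           ids, breed, sex)
  colnames(origin) <- colnames(panel$alleles)[seq_len(2 * n_focal)]
  attr(panel, "true_origin") <- origin
  panel
}

#' Sample a QTL architecture
#'
#' Samples `n_qtl` distinct markers as QTL. Effect magnitudes are gamma
#' distributed (shape `shape`), signs positive with probability 0.5. The
#' largest positive effects are then re-assigned among the sampled QTL so
#' that they sit on QTL whose mean reference-breed allele frequency most
#' exceeds the focal-breed frequency (rank pairing: k-th largest positive
#' effect on the k-th ranked QTL; negative effects keep a random assignment
#' among the remainder), which makes the migrant genome carry higher merit.
#' Finally all effects are rescaled so that the genic variance of the focal
#' panel equals `target_genic_variance` exactly.
#'
#' @param panel combined founder panel from [simulate_breed_panels()].
#' @param n_qtl number of QTL (default 1500).
#' @param shape gamma shape of effect magnitudes (default 0.4).
#' @param target_genic_variance genic variance of the focal founders after
#'   rescaling (default 0.075).
#' @param focal_breed breed treated as focal.
#' @param seed integer seed.
#' @return An object of class `trait_architecture` with elements
#'   `qtl_indices`, `effects`, `reliability` (set by the caller of
#'   [simulate_ebv()], stored for bookkeeping, default 0.75).
#' @export
sample_trait <- function(panel, n_qtl = 1500, shape = 0.4,
                         target_genic_variance = 0.075,
                         focal_breed = "Angler", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(panel$map)
  if (n_qtl > m) stop("n_qtl exceeds the number of markers")
  qtl <- sort(sample.int(m, n_qtl))
  a <- rgamma(n_qtl, shape = shape, rate = 1) *
    sample(c(-1, 1), n_qtl, replace = TRUE)
  focal <- panel_subset(panel, breed = focal_breed)
  refs <- panel_subset(panel, breed = setdiff(unique(panel$breed),
                                              focal_breed))
  p_focal <- allele_freq(focal)[qtl]
  ref_breeds <- unique(refs$breed)
  p_ref <- rowMeans(sapply(ref_breeds, function(b)
    allele_freq(panel_subset(refs, breed = b))[qtl]))
  rank_qtl <- order(p_ref - p_focal, decreasing = TRUE)
  pos <- which(a > 0)
  effects <- numeric(n_qtl)
  effects[rank_qtl[seq_along(pos)]] <- sort(a[pos], decreasing = TRUE)
  rest <- rank_qtl[-seq_along(pos)]
  effects[rest] <- a[a <= 0][sample.int(length(rest))]
  v <- sum(2 * p_focal * (1 - p_focal) * effects^2)
  if (v <= 0) stop("degenerate architecture: zero genic variance")
  effects <- effects * sqrt(target_genic_variance / v)
  structure(list(qtl_indices = qtl, effects = effects, reliability = 0.75),
            class = "trait_architecture")
}

#' True breeding values
#'
#' TBV of individual j is the sum over QTL of effect times allele dosage.
#'
#' @param panel a `haplotype_panel`.
#' @param arch a `trait_architecture`.
#' @return numeric vector of TBVs, one per individual.
#' @export
compute_tbv <- function(panel, arch) {
  if (max(arch$qtl_indices) > nrow(panel$map))
    stop("QTL indices exceed the panel's markers")
  q <- dosage(panel)[arch$qtl_indices, , drop = FALSE]
  drop(crossprod(q, arch$effects))
}

#' Genic variance
#'
#' Additive variance under linkage equilibrium: sum over QTL of
#' `2 p (1 - p) a^2` with current allele frequencies p.
#'
#' @param panel a `haplotype_panel`.
#' @param arch a `trait_architecture`.
#' @return scalar genic variance.
#' @export
genic_variance <- function(panel, arch) {
  p <- allele_freq(panel)[arch$qtl_indices]
  sum(2 * p * (1 - p) * arch$effects^2)
}

#' Simulate estimated breeding values at a given reliability
#'
#' `EBV_j = mu + r2 * (TBV_j - mu) + E_j` with
#' `E_j ~ N(0, r2 (1 - r2) var(TBV))`, where `mu` is the mean TBV of the
#' supplied generation. The squared correlation between EBV and TBV equals
#' `r2` in expectation.
#'
#' @param tbv numeric vector of true breeding values (length >= 2).
#' @param r2 reliability in \[0, 1\] (default 0.75).
#' @param seed integer seed.
#' @return numeric vector of EBVs.
#' @export
simulate_ebv <- function(tbv, r2 = 0.75, seed = NULL) {
  if (r2 < 0 || r2 > 1) stop("r2 must be in [0, 1]")
  if (length(tbv) < 2) stop("need at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  mu <- mean(tbv)
  s2e <- r2 * (1 - r2) * var(tbv)
  mu + r2 * (tbv - mu) + rnorm(length(tbv), 0, sqrt(s2e))
}

#' Decompose the TBV variance by chromosome
#'
#' Splits each TBV into per-chromosome components (sum of QTL effects on
#' that chromosome). The total TBV variance is the sum of the
#' within-chromosome component variances plus the between-chromosome
#' covariance contribution; in an admixed base population the latter is
#' positive because whole-genome migrant proportion varies between
#' individuals.
#'
#' @param panel a `haplotype_panel`.
#' @param arch a `trait_architecture`.
#' @return list with `total` (variance of TBV), `within` (sum of
#'   per-chromosome variances) and `between` (total minus within, the
#'   covariance contribution of distinct chromosomes).
#' @export
tbv_variance_decomposition <- function(panel, arch) {
  chr <- panel$map$chromosome[arch$qtl_indices]
  q <- dosage(panel)[arch$qtl_indices, , drop = FALSE]
  parts <- sapply(unique(chr), function(cc)
    drop(crossprod(q[chr == cc, , drop = FALSE],
                   arch$effects[chr == cc])))
  total <- var(rowSums(parts))
  within <- sum(apply(parts, 2, var))
  list(total = total, within = within, between = total - within)
}
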