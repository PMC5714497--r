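# Independent brute-force oracles used to validate the fast kernels.
# These deliberately share no code with the implementation: plain rle /
# position-by-position integration / dense grid search.

# All maximal identical runs meeting the criteria, via rle per chromosome.
oracle_segments <- function(h1, h2, map, crit) {
  out <- NULL
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    eq <- h1[idx] == h2[idx]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      s <- idx[starts[k]]
      e <- idx[ends[k]]
      if (e - s + 1 >= crit$min_markers &&
          map$position_bp[e] - map$position_bp[s] >= crit$min_length_mb * 1e6)
        out <- rbind(out, c(s, e))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  storage.mode(out) <- "integer"
  unname(out)
}

# Per-marker indicator: does position m of haplotype pair (h1, h2) lie on a
# qualifying shared segment?
oracle_covered <- function(h1, h2, map, crit) {
  runs <- oracle_segments(h1, h2, map, crit)
  cov <- logical(nrow(map))
  if (nrow(runs) > 0)
    for (k in seq_len(nrow(runs))) cov[runs[k, 1]:runs[k, 2]] <- TRUE
  cov
}

# Position-wise integration oracle for the segment-based kinship matrix.
oracle_fseg <- function(panel, crit, weighting = "length") {
  w <- marker_weights(panel$map, weighting)
  n <- n_individuals(panel)
  F <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      tot <- 0
      for (a in (2 * i - 1):(2 * i)) {
        for (b in (2 * j - 1):(2 * j)) {
          if (a == b) tot <- tot + 1
          else tot <- tot + sum(w[oracle_covered(panel$alleles[, a],
                                                 panel$alleles[, b],
                                                 panel$map, crit)])
        }
      }
      F[i, j] <- F[j, i] <- tot / 4
    }
  }
  F
}

# Position-wise oracle for the native-kinship numerator and denominator.
oracle_fseg_native <- function(panel, mask, crit, weighting = "length") {
  w <- marker_weights(panel$map, weighting)
  n <- n_individuals(panel)
  S <- D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- d <- 0
      for (a in (2 * i - 1):(2 * i)) {
        for (b in (2 * j - 1):(2 * j)) {
          cov <- if (a == b) rep(TRUE, nrow(panel$map)) else
            oracle_covered(panel$alleles[, a], panel$alleles[, b],
                           panel$map, crit)
          both <- mask[, a] & mask[, b]
          s <- s + sum(w[cov & both])
          d <- d + sum(w[both])
        }
      }
      S[i, j] <- S[j, i] <- s / 4
      D[i, j] <- D[j, i] <- d / 4
    }
  }
  list(Snat = S, Dnat = D)
}

# Brute-force native classification for one focal haplotype.
oracle_native_hap <- function(hap, refs, map, crit) {
  native <- rep(TRUE, nrow(map))
  for (b in unique(refs$breed)) {
    cols <- hap_cols(which(refs$breed == b))
    count <- integer(nrow(map))
    for (cc in cols)
      count <- count + oracle_covered(hap, refs$alleles[, cc], map, crit)
    native <- native & (count / length(cols) < crit$max_ref_freq)
  }
  native
}

# Dense grid search over male contributions (step `by`) for OCS problems
# with up to 3 males; evaluates the true constraints including the
# fSEG|N ratio.
oracle_ocs_grid <- function(ebv, kin, sex, ub_fseg = NULL, ub_fsegn = NULL,
                            ub_mc = NULL, by = 0.001) {
  mi <- which(sex == "M")
  fi <- which(sex == "F")
  stopifnot(length(mi) %in% 2:3)
  cf <- rep(0.5 / length(fi), length(fi))
  pts <- seq(0, 0.5, by = by)
  best <- -Inf
  best_c <- NULL
  for (c1 in pts) {
    c2s <- if (length(mi) == 3) seq(0, 0.5 - c1, by = by) else 0.5 - c1
    for (c2 in c2s) {
      cm <- if (length(mi) == 3) c(c1, c2, 0.5 - c1 - c2) else c(c1, c2)
      cc <- numeric(length(sex))
      cc[mi] <- cm
      cc[fi] <- cf
      if (!is.null(ub_fseg) &&
          drop(cc %*% kin$F %*% cc) > ub_fseg + 1e-12) next
      if (!is.null(ub_fsegn)) {
        d <- drop(cc %*% kin$Dnat %*% cc)
        if (drop(cc %*% kin$Snat %*% cc) / d > ub_fsegn + 1e-12) next
      }
      if (!is.null(ub_mc) && sum(cc * kin$mc) > ub_mc + 1e-12) next
      val <- sum(cc * ebv)
      if (val > best) {
        best <- val
        best_c <- cc
      }
    }
  }
  list(objective = best, c = best_c)
}

# A tiny deterministic panel: `n` individuals on `map`, alleles supplied
# column-wise.
toy_panel <- function(map, alleles, sex = NULL, breed = "Angler") {
  n <- ncol(alleles) / 2
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = n)
  haplotype_panel(map, alleles, sprintf("ind%02d", seq_len(n)),
                  rep(breed, n), sex)
}
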