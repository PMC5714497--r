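#' Rate of inbreeding implied by an effective population size
#'
#' `delta_F = 1 / (2 Ne)`.
#'
#' @param ne effective population size.
#' @return per-generation rate of inbreeding.
#' @export
delta_f_from_ne <- function(ne) {
  if (ne <= 0) stop("ne must be positive")
  1 / (2 * ne)
}

#' Effective size of an equal-family-size scheme
#'
#' When every parent leaves exactly the same number of offspring the
#' variance of family sizes is zero and the effective population size is
#' twice the census number of parents.
#'
#' @param n_parents number of parents.
#' @return effective population size `2 * n_parents`.
#' @export
effective_size_equal_family <- function(n_parents) 2 * n_parents

#' Number of sires for a target effective size under truncation selection
#'
#' From `1/Ne = 1/(4 Nsire) + 1/(4 Ndam)`:
#' `Nsire = floor(1 / (4 (1/Ne - 1/(4 Ndam))))`.
#'
#' @param ne_target targeted effective population size.
#' @param n_dams number of dams.
#' @return integer number of sires.
#' @export
n_sires_for_ne <- function(ne_target, n_dams) {
  if (ne_target <= 0 || n_dams <= 0) stop("ne_target and n_dams must be > 0")
  denom <- 1 / ne_target - 1 / (4 * n_dams)
  if (denom <= 0)
    stop("infeasible: ", n_dams, " dams alone exceed the Ne target")
  as.integer(floor(1 / (4 * denom)))
}

#' Truncation selection of sires
#'
#' Selects the sires with the highest EBVs, with the sire number set so
#' that `1/Ne = 1/(4 Nsire) + 1/(4 Ndam)` meets the target effective size.
#' Selected sires receive equal contributions summing to 0.5; all dams
#' receive equal contributions summing to 0.5.
#'
#' @param ebv EBV vector over all candidates.
#' @param sex `"M"`/`"F"` per candidate; all females are used as dams.
#' @param ne_target targeted effective population size (default 100).
#' @return list with `sires` (candidate indices of the selected sires),
#'   `n_sires`, and `c` (the full contribution vector).
#' @export
truncation_select <- function(ebv, sex, ne_target = 100) {
  males <- which(sex == "M")
  dams <- which(sex == "F")
  n_sires <- n_sires_for_ne(ne_target, length(dams))
  if (n_sires > length(males))
    stop("not enough male candidates: need ", n_sires)
  sires <- males[order(ebv[males], decreasing = TRUE)[seq_len(n_sires)]]
  c <- numeric(length(ebv))
  c[sires] <- 0.5 / n_sires
  c[dams] <- 0.5 / length(dams)
  list(sires = sort(sires), n_sires = n_sires, c = c)
}

#' Define an optimum contribution selection problem
#'
#' The objective is to maximize `c'EBV` over male contributions, with
#' females fixed at equal contributions (`0.5 / n_dams` each), subject to
#' `c >= 0`, `c's = 0.5`, and the optional upper bounds.
#'
#' @param ebv EBV vector over all candidates.
#' @param kin a `kinship_set` for the candidates.
#' @param sex `"M"`/`"F"` per candidate.
#' @param ub_fseg optional upper bound on mean kinship `c'Fc`.
#' @param ub_fsegn optional upper bound on mean kinship at native alleles
#'   `(c'Snat c)/(c'Dnat c)`.
#' @param ub_mc optional upper bound on mean migrant contribution `c'm`.
#' @return An object of class `selection_problem`.
#' @export
selection_problem <- function(ebv, kin, sex, ub_fseg = NULL,
                              ub_fsegn = NULL, ub_mc = NULL) {
  n <- length(ebv)
  stopifnot(nrow(kin$F) == n, length(sex) == n)
  if (!any(sex == "M") || !any(sex == "F"))
    stop("need at least one male and one female candidate")
  for (ub in list(ub_fseg, ub_fsegn, ub_mc))
    if (!is.null(ub) && (ub < 0 || ub > 1))
      stop("bounds must be in [0, 1]")
  structure(list(ebv = ebv, kin = kin, sex = sex, ub_fseg = ub_fseg,
                 ub_fsegn = ub_fsegn, ub_mc = ub_mc),
            class = "selection_problem")
}

# Quadratic constraint x'Qx + l'x + r <= 0 in the male block, with the
# female block fixed at cf.
male_quad <- function(M, mi, fi, cf, rhs) {
  list(Q = M[mi, mi, drop = FALSE],
       l = 2 * drop(M[mi, fi, drop = FALSE] %*% cf),
       r = drop(cf %*% M[fi, fi, drop = FALSE] %*% cf) - rhs)
}

#' Solve an optimum contribution selection problem
#'
#' Maximizes `c'EBV` over male contributions under the declared bounds.
#' Kinship constraints are convex quadratics solved by an interior-point
#' barrier method; the fractional `fSEG|N` constraint is handled by a
#' fixed-denominator iteration (set `delta = c'Dnat c` at the previous
#' iterate, impose `c'Snat c <= ub * delta`, re-solve until the
#' denominator converges). All matrices are projected to positive
#' semidefinite with [nearest_psd()] before solving; achieved values are
#' reported on the projected matrices.
#'
#' With no optional bound the problem is linear over the male simplex and
#' the exact vertex solution (all male mass on the highest-EBV male) is
#' returned directly.
#'
#' @param problem a [selection_problem()].
#' @param max_ratio_iter maximum fixed-denominator iterations (default 25).
#' @param ratio_tol relative denominator-change convergence tolerance.
#' @return list with `c` (full contribution vector), `achieved` (list
#'   `fseg`, `fseg_native`, `mc`, `ebv`), `status` (`"optimal"`,
#'   `"infeasible"` or `"max-iter"`) and, when infeasible, `violations`
#'   (per-constraint violation at the least-infeasible point found).
#' @export
solve_ocs <- function(problem, max_ratio_iter = 25, ratio_tol = 1e-6) {
  p <- problem
  mi <- which(p$sex == "M")
  fi <- which(p$sex == "F")
  nm <- length(mi)
  cf <- rep(0.5 / length(fi), length(fi))
  full_c <- function(cm) {
    c <- numeric(length(p$ebv))
    c[mi] <- cm
    c[fi] <- cf
    c
  }
  F <- nearest_psd(p$kin$F)
  S <- nearest_psd(p$kin$Snat)
  D <- nearest_psd(p$kin$Dnat)
  achieved <- function(c) {
    d <- drop(c %*% D %*% c)
    list(fseg = drop(c %*% F %*% c),
         fseg_native = if (d > 0) drop(c %*% S %*% c) / d else NA_real_,
         mc = sum(c * p$kin$mc), ebv = sum(c * p$ebv))
  }
  no_bounds <- is.null(p$ub_fseg) && is.null(p$ub_fsegn) && is.null(p$ub_mc)
  if (no_bounds) {
    best <- mi[p$ebv[mi] == max(p$ebv[mi])]
    cm <- numeric(nm)
    cm[match(best, mi)] <- 0.5 / length(best)
    c <- full_c(cm)
    return(list(c = c, achieved = achieved(c), status = "optimal"))
  }
  lins <- list()
  if (!is.null(p$ub_mc))
    lins <- c(lins, list(list(a = p$kin$mc[mi],
                              b = sum(cf * p$kin$mc[fi]) - p$ub_mc)))
  quads_base <- list()
  if (!is.null(p$ub_fseg))
    quads_base <- c(quads_base, list(male_quad(F, mi, fi, cf, p$ub_fseg)))
  cm <- rep(0.5 / nm, nm)
  aeq <- rep(1, nm)
  status <- "optimal"
  if (is.null(p$ub_fsegn)) {
    res <- solve_qclp(p$ebv[mi], quads_base, lins, aeq, 0.5, cm)
    if (res$status == "infeasible")
      return(list(c = full_c(res$x), achieved = achieved(full_c(res$x)),
                  status = "infeasible", violations = res$violations))
    cm <- res$x
  } else {
    # Fixed-denominator iteration on delta = c'Dnat c, refined by
    # bisection: once the ratio residual g = c'Sc/c'Dc - ub has been seen
    # with both signs, the binding delta* is bracketed and bisection pins
    # it down. (Raw fixed-point updates alone can limit-cycle when the
    # optimum is degenerate across near-equivalent males.)
    delta <- drop(full_c(cm) %*% D %*% full_c(cm))
    converged <- FALSE
    g_tol <- 1e-7
    d_pos <- d_neg <- NA_real_  # bracket endpoints by residual sign
    cm_feas <- NULL             # last solution on the feasible side
    unif <- rep(0.5 / nm, nm)
    for (it in seq_len(max_ratio_iter)) {
      quads <- c(quads_base,
                 list(male_quad(S, mi, fi, cf, p$ub_fsegn * delta)))
      # cold-start every subproblem from the uniform point: the barrier
      # path endpoint is then a deterministic, continuous function of
      # delta, which the fixed-point/bisection scheme requires (warm
      # starts land on different points of a degenerate optimal face)
      res <- solve_qclp(p$ebv[mi], quads, lins, aeq, 0.5, unif)
      if (res$status == "infeasible")
        return(list(c = full_c(res$x), achieved = achieved(full_c(res$x)),
                    status = "infeasible", violations = res$violations))
      cm <- res$x
      cc <- full_c(cm)
      delta_new <- drop(cc %*% D %*% cc)
      g <- drop(cc %*% S %*% cc) / delta_new - p$ub_fsegn
      if (g > 0) d_pos <- delta else {
        d_neg <- delta
        cm_feas <- cm
      }
      # converged when the true fractional constraint is met at the bound
      # (binding case) or the denominator has stabilized (slack case)
      if (abs(g) <= g_tol ||
          (g < 0 &&
           abs(delta_new - delta) <= ratio_tol * max(delta, 1e-300))) {
        converged <- TRUE
        break
      }
      if (!is.na(d_pos) && !is.na(d_neg)) {
        if (abs(d_pos - d_neg) <= 1e-8 * delta) {
          # bracket exhausted: the solution jumps between two optimal
          # faces and no delta makes the ratio bind more closely; return
          # the feasible-side solution (ratio just under the bound)
          if (!is.null(cm_feas)) cm <- cm_feas
          converged <- TRUE
          break
        }
        delta <- (d_pos + d_neg) / 2
      } else {
        delta <- delta_new
      }
    }
    if (!converged) status <- "max-iter"
  }
  c <- full_c(cm)
  list(c = c, achieved = achieved(c), status = status)
}

#' Convert contributions to offspring counts
#'
#' Sire i receives approximately `c_i * 2 * n_offspring` offspring by
#' largest-remainder rounding, with the male counts summing exactly to
#' `n_offspring`; every dam receives exactly `n_offspring / n_dams`
#' offspring (the equal-dam policy). Rounding ties are broken by a seeded
#' shuffle, so counts are reproducible given the seed.
#'
#' @param c contribution vector (male and female halves each sum to 0.5).
#' @param sex `"M"`/`"F"` per candidate.
#' @param n_offspring total number of offspring.
#' @param seed integer seed for tie breaking.
#' @return integer vector of offspring counts per candidate.
#' @export
contributions_to_counts <- function(c, sex, n_offspring, seed = NULL) {
  if (any(c < -1e-9)) stop("contributions must be non-negative")
  mi <- which(sex == "M")
  fi <- which(sex == "F")
  if (abs(sum(c[mi]) - 0.5) > 1e-6 || abs(sum(c[fi]) - 0.5) > 1e-6)
    stop("male and female contributions must each sum to 0.5")
  if (n_offspring %% length(fi) != 0)
    stop("n_offspring must be divisible by the number of dams")
  if (!is.null(seed)) set.seed(seed)
  target <- pmax(c[mi], 0) * 2 * n_offspring
  counts_m <- floor(target)
  short <- n_offspring - sum(counts_m)
  if (short > 0) {
    frac <- target - counts_m
    ord <- order(frac, sample.int(length(frac)), decreasing = TRUE)
    counts_m[ord[seq_len(short)]] <- counts_m[ord[seq_len(short)]] + 1
  }
  counts <- integer(length(c))
  counts[mi] <- as.integer(counts_m)
  counts[fi] <- as.integer(n_offspring / length(fi))
  counts
}
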