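#' Scenario configuration
#'
#' The five selection scenarios compared by the package:
#' \describe{
#'   \item{REF}{no selection; every candidate leaves exactly two
#'     offspring.}
#'   \item{TS}{truncation selection of the highest-EBV sires at a target
#'     effective size.}
#'   \item{OCS-I}{OCS with an upper bound on mean kinship `fSEG` updated by
#'     `ub_{t+1} = mean_t + (1 - mean_t) * delta_F`.}
#'   \item{OCS-II}{OCS-I plus the same recursion on kinship at native
#'     alleles and the requirement that mean migrant contribution not
#'     exceed its base-generation level.}
#'   \item{OCS-III}{as OCS-II but the MC bound decreases each generation
#'     (default: 3 percent relative decay of the previous generation's
#'     mean).}
#' }
#'
#' @param scenario one of `"REF"`, `"TS"`, `"OCS-I"`, `"OCS-II"`,
#'   `"OCS-III"`.
#' @param generations number of generations to simulate (default 10).
#' @param replicates number of replicates (default 5).
#' @param ne_target targeted effective population size (default 100).
#' @param delta_f per-generation rate of inbreeding; defaults to
#'   `1 / (2 ne_target)`.
#' @param mc_decay per-generation MC decay of OCS-III (default 0.03).
#' @param mc_decay_mode `"relative"` (bound = previous mean x
#'   `(1 - mc_decay)`, the default) or `"absolute"` (previous mean minus
#'   `mc_decay`).
#' @param reliability EBV reliability (default 0.75).
#' @param criteria a [segment_criteria()].
#' @param weighting genome weighting for MC and kinship integrals.
#' @param origin_mode `"recompute"` (default): native masks are
#'   recomputed against the fixed reference panels each generation;
#'   `"propagate"`: each offspring marker inherits the origin of the
#'   parental haplotype it came from (an alternative estimator unaffected
#'   by segment splitting).
#' @param seed base seed; replicate r uses a seed derived from `seed`,
#'   r and the generation index.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("REF", "TS", "OCS-I", "OCS-II",
                                         "OCS-III"),
                            generations = 10, replicates = 5,
                            ne_target = 100,
                            delta_f = delta_f_from_ne(ne_target),
                            mc_decay = 0.03,
                            mc_decay_mode = c("relative", "absolute"),
                            reliability = 0.75,
                            criteria = segment_criteria(),
                            weighting = "length",
                            origin_mode = c("recompute", "propagate"),
                            seed = 1) {
  scenario <- match.arg(scenario)
  mc_decay_mode <- match.arg(mc_decay_mode)
  origin_mode <- match.arg(origin_mode)
  if (generations < 1) stop("generations must be >= 1")
  structure(list(scenario = scenario, generations = generations,
                 replicates = replicates, ne_target = ne_target,
                 delta_f = delta_f, mc_decay = mc_decay,
                 mc_decay_mode = mc_decay_mode, reliability = reliability,
                 criteria = criteria, weighting = weighting,
                 origin_mode = origin_mode, seed = seed),
            class = "scenario_config")
}

#' Kinship bound recursion
#'
#' `ub_{t+1} = mean_t + (1 - mean_t) * delta_F`, applied to the realized
#' mean kinship (and, in OCS-II/III, to the realized mean kinship at
#' native alleles) of generation t.
#'
#' @param current_mean realized population mean in \[0, 1\].
#' @param delta_f per-generation rate of inbreeding.
#' @return the next generation's upper bound.
#' @export
update_kinship_bound <- function(current_mean, delta_f) {
  stopifnot(current_mean >= 0, current_mean <= 1,
            delta_f >= 0, delta_f <= 1)
  current_mean + (1 - current_mean) * delta_f
}

#' Migrant-contribution bound per scenario
#'
#' REF, TS and OCS-I leave MC unconstrained. OCS-II holds the bound at the
#' base-generation mean. OCS-III lowers the previous generation's realized
#' mean by `mc_decay` (relative by default).
#'
#' @param scenario scenario name.
#' @param mc_reference base-generation mean MC (OCS-II) or the previous
#'   generation's realized mean MC (OCS-III).
#' @param mc_decay decay parameter (OCS-III).
#' @param mode `"relative"` or `"absolute"` decay.
#' @return upper bound on mean MC, or `NULL` when unconstrained.
#' @export
update_mc_bound <- function(scenario, mc_reference, mc_decay = 0.03,
                            mode = "relative") {
  stopifnot(mc_reference >= 0, mc_reference <= 1)
  switch(scenario,
         "REF" = NULL, "TS" = NULL, "OCS-I" = NULL,
         "OCS-II" = mc_reference,
         "OCS-III" = if (mode == "relative")
           mc_reference * (1 - mc_decay)
         else max(mc_reference - mc_decay, 0),
         stop("unknown scenario ", scenario))
}

#' Per-generation diversity and merit metrics
#'
#' @param panel the generation's `haplotype_panel`.
#' @param arch the `trait_architecture`.
#' @param kin the generation's `kinship_set`.
#' @param ebv the generation's simulated EBVs.
#' @return one-row data.frame with mean EBV, mean TBV, mean MC, mean fSEG,
#'   mean fSEG|N, observed heterozygosity, TBV variance and genic
#'   variance.
#' @export
compute_metrics <- function(panel, arch, kin, ebv) {
  s <- population_summaries(kin)
  tbv <- compute_tbv(panel, arch)
  data.frame(mean_ebv = mean(ebv), mean_tbv = mean(tbv),
             mc = s$mc, fseg = s$fseg, fseg_native = s$fseg_native,
             ho = observed_heterozygosity(panel),
             var_tbv = var(tbv), genic_var = genic_variance(panel, arch))
}

#' Assemble the inputs of the scaled simulation study
#'
#' Builds the complete study system at desk scale: a 3-chromosome,
#' 1500-marker genome (150 Mb, 1 cM = 1 Mb), synthetic founder panels for
#' the admixed focal breed and the four reference breeds, a 300-QTL trait
#' architecture standardized to a founder genic variance of 0.075, and a
#' base generation of 300 individuals (150 males, 150 females) sampled
#' from the founders' gametes.
#'
#' @param seed integer seed; panels, trait and base generation use
#'   `seed`, `seed + 1` and `seed + 2`.
#' @param n_chr,markers_per_chr,spacing_bp genome layout.
#' @param model a [breed_model()].
#' @param n_focal focal founders.
#' @param n_ref individuals per reference breed.
#' @param n_base base-generation size.
#' @param n_qtl number of QTL.
#' @param target_genic_variance founder genic variance after effect
#'   standardization.
#' @return list with `map`, `panel` (all founders), `founders` (focal
#'   breed only, with the `true_origin` ground truth), `refs`, `arch` and
#'   `base`.
#' @export
make_study_population <- function(seed, n_chr = 3, markers_per_chr = 500,
                                  spacing_bp = 1e5, model = breed_model(),
                                  n_focal = 60,
                                  n_ref = c(40, 40, 20, 40),
                                  n_base = 300, n_qtl = 300,
                                  target_genic_variance = 0.075) {
  map <- make_marker_map(n_chr, markers_per_chr, spacing_bp)
  panel <- simulate_breed_panels(model, map, n_focal, n_ref, seed = seed)
  founders <- panel_subset(panel, breed = setdiff(unique(panel$breed),
                                                  model$ref_breeds))
  attr(founders, "true_origin") <- attr(panel, "true_origin")
  refs <- panel_subset(panel, breed = model$ref_breeds)
  arch <- sample_trait(panel, n_qtl = n_qtl,
                       target_genic_variance = target_genic_variance,
                       seed = seed + 1)
  base <- make_base_generation(founders, n = n_base, seed = seed + 2)
  list(map = map, panel = panel, founders = founders, refs = refs,
       arch = arch, base = base)
}

scenario_seed <- function(seed, replicate, generation) {
  (seed + 7919L * replicate + 104729L * generation) %% .Machine$integer.max
}

#' Run a selection scenario
#'
#' Simulates `config$replicates` replicates of `config$generations`
#' generations from a common base population. Each generation: the native
#' mask is recomputed against the fixed reference panels, the kinship set
#' and EBVs are built, the scenario's selection rule is solved,
#' contributions are converted to offspring counts and the population is
#' advanced. Constraint bounds follow the recursions of
#' [update_kinship_bound()] and [update_mc_bound()], always applied to
#' realized generation means.
#'
#' @param config a [scenario_config()].
#' @param base base-generation `haplotype_panel` (G0).
#' @param refs reference-breed `haplotype_panel` (fixed across
#'   generations).
#' @param arch the `trait_architecture`.
#' @return data.frame of per-replicate, per-generation rows: the metrics
#'   of [compute_metrics()], the active bounds, the solver status and the
#'   achieved (predicted offspring) values `pred_fseg`, `pred_fseg_native`,
#'   `pred_mc`.
#' @export
run_scenario <- function(config, base, refs, arch) {
  out <- list()
  for (rep_i in seq_len(config$replicates)) {
    pop <- base
    mask <- NULL
    mc_g0 <- NA_real_
    for (t in 0:config$generations) {
      set.seed(scenario_seed(config$seed, rep_i, t))
      if (config$origin_mode == "propagate" && t > 0)
        mask <- attr(pop, "mask")
      else
        mask <- native_mask(pop, refs, config$criteria)
      kin <- compute_kinship_set(pop, refs, config$criteria,
                                 config$weighting, mask = mask)
      tbv <- compute_tbv(pop, arch)
      ebv <- simulate_ebv(tbv, config$reliability)
      metrics <- compute_metrics(pop, arch, kin, ebv)
      row <- cbind(data.frame(scenario = config$scenario,
                              replicate = rep_i, generation = t),
                   metrics,
                   data.frame(ub_fseg = NA_real_,
                              ub_fseg_native = NA_real_,
                              ub_mc = NA_real_, status = "none",
                              pred_fseg = NA_real_,
                              pred_fseg_native = NA_real_,
                              pred_mc = NA_real_))
      if (t == 0) mc_g0 <- metrics$mc
      if (t < config$generations) {
        n <- n_individuals(pop)
        sel <- select_parents(config, pop, kin, ebv, metrics, mc_g0)
        row$status <- sel$status
        if (sel$status == "infeasible")
          stop("scenario ", config$scenario, " replicate ", rep_i,
               " generation ", t, ": selection problem infeasible")
        row$ub_fseg <- sel$ub_fseg
        row$ub_fseg_native <- sel$ub_fsegn
        row$ub_mc <- sel$ub_mc
        if (!is.null(sel$achieved)) {
          row$pred_fseg <- sel$achieved$fseg
          row$pred_fseg_native <- sel$achieved$fseg_native
          row$pred_mc <- sel$achieved$mc
        }
        counts <- contributions_to_counts(sel$c, pop$sex, n)
        pop <- advance_generation(pop, counts,
                                  id_prefix = paste0("G", t + 1),
                                  mask = mask)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

# One generation's selection decision; bounds derive from the realized
# generation means via the recursions.
select_parents <- function(config, pop, kin, ebv, metrics, mc_g0) {
  scenario <- config$scenario
  none <- list(ub_fseg = NA_real_, ub_fsegn = NA_real_, ub_mc = NA_real_)
  if (scenario == "REF") {
    c <- numeric(n_individuals(pop))
    c[pop$sex == "M"] <- 0.5 / sum(pop$sex == "M")
    c[pop$sex == "F"] <- 0.5 / sum(pop$sex == "F")
    return(c(list(c = c, status = "optimal", achieved = NULL), none))
  }
  if (scenario == "TS") {
    ts <- truncation_select(ebv, pop$sex, config$ne_target)
    return(c(list(c = ts$c, status = "optimal", achieved = NULL), none))
  }
  ub_fseg <- update_kinship_bound(metrics$fseg, config$delta_f)
  ub_fsegn <- NULL
  ub_mc <- NULL
  if (scenario %in% c("OCS-II", "OCS-III")) {
    ub_fsegn <- update_kinship_bound(metrics$fseg_native, config$delta_f)
    ref_mc <- if (scenario == "OCS-II") mc_g0 else metrics$mc
    ub_mc <- update_mc_bound(scenario, ref_mc, config$mc_decay,
                             config$mc_decay_mode)
  }
  prob <- selection_problem(ebv, kin, pop$sex, ub_fseg = ub_fseg,
                            ub_fsegn = ub_fsegn, ub_mc = ub_mc)
  res <- solve_ocs(prob)
  list(c = res$c, status = res$status, achieved = res$achieved,
       ub_fseg = ub_fseg,
       ub_fsegn = if (is.null(ub_fsegn)) NA_real_ else ub_fsegn,
       ub_mc = if (is.null(ub_mc)) NA_real_ else ub_mc)
}

#' Summarize scenario runs across replicates
#'
#' Mean and SD over replicates of every metric, per scenario and
#' generation (the shape of the headline results table).
#'
#' @param runs data.frame from one or several [run_scenario()] calls
#'   (row-bound).
#' @return data.frame with one row per scenario x generation and
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
summarize_runs <- function(runs) {
  metrics <- c("mean_ebv", "mc", "fseg", "fseg_native", "ho", "var_tbv",
               "genic_var")
  groups <- unique(runs[, c("scenario", "generation")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- runs[runs$scenario == groups$scenario[i] &
                  runs$generation == groups$generation[i], ]
    vals <- lapply(metrics, function(m)
      c(mean(sub[[m]]), stats::sd(sub[[m]])))
    row <- data.frame(scenario = groups$scenario[i],
                      generation = groups$generation[i])
    for (k in seq_along(metrics)) {
      row[[paste0(metrics[k], "_mean")]] <- vals[[k]][1]
      row[[paste0(metrics[k], "_sd")]] <- vals[[k]][2]
    }
    row
  })
  do.call(rbind, rows)
}
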