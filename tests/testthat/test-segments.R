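crit_default <- segment_criteria()

test_that("segment criteria validate their fields", {
  expect_error(segment_criteria(min_markers = 1), "min_markers")
  expect_error(segment_criteria(min_length_mb = 0), "min_length_mb")
  expect_error(segment_criteria(max_ref_freq = 1), "max_ref_freq")
})

test_that("full identity and full disagreement are the trivial cases", {
  map <- make_marker_map(1, 30, 1e5)  # 3.0 Mb span >= 2.5 Mb
  h <- rbinom(30, 1, 0.5)
  s <- shared_segments(h, h, map, crit_default)
  expect_equal(nrow(s), 1)
  expect_equal(s$start_marker, 1)
  expect_equal(s$end_marker, 30)
  s2 <- shared_segments(h, 1 - h, map, crit_default)
  expect_equal(nrow(s2), 0)
})

test_that("both qualification thresholds are enforced independently", {
  # chr1: 25 identical markers spanning 2.0 Mb (fails length);
  # chr2: 19 identical markers spanning 3.0 Mb (fails marker count)
  map <- marker_map(paste0("m", 1:44),
                    rep(c("c1", "c2"), c(25, 19)),
                    c(seq(1e5, by = 2e6 / 24, length.out = 25),
                      seq(1e5, by = 3e6 / 18, length.out = 19)))
  h <- rep(0L, 44)
  expect_equal(nrow(shared_segments(h, h, map, crit_default)), 0)
})

test_that("segment detection equals exhaustive run enumeration", {
  map <- make_marker_map(2, 100, 1e5)
  crit <- segment_criteria(min_markers = 10, min_length_mb = 0.9)
  set.seed(11)
  for (i in 1:50) {
    h1 <- rbinom(200, 1, 0.5)
    h2 <- ifelse(rbinom(200, 1, runif(1, 0.75, 0.98)) == 1, h1, 1 - h1)
    got <- as.matrix(shared_segments(h1, h2, map, crit)[
      , c("start_marker", "end_marker")])
    dimnames(got) <- NULL
    expect_identical(got, oracle_segments(h1, h2, map, crit))
    # symmetry in the two haplotypes
    rev <- as.matrix(shared_segments(h2, h1, map, crit)[
      , c("start_marker", "end_marker")])
    dimnames(rev) <- NULL
    expect_identical(got, rev)
  }
})

test_that("tightening criteria never adds segments", {
  map <- make_marker_map(2, 100, 1e5)
  set.seed(12)
  for (i in 1:20) {
    h1 <- rbinom(200, 1, 0.5)
    h2 <- ifelse(rbinom(200, 1, 0.93) == 1, h1, 1 - h1)
    loose <- shared_segments(h1, h2, map,
                             segment_criteria(10, 0.8, 0.01))
    for (crit in list(segment_criteria(15, 0.8, 0.01),
                      segment_criteria(10, 1.6, 0.01))) {
      tight <- shared_segments(h1, h2, map, crit)
      expect_lte(nrow(tight), nrow(loose))
      if (nrow(tight) > 0) {
        key <- paste(tight$start_marker, tight$end_marker)
        expect_true(all(key %in% paste(loose$start_marker,
                                       loose$end_marker)))
      }
    }
  }
})

make_ref_panel <- function(map, haps, breed = "Ref") {
  n <- ncol(haps) / 2
  haplotype_panel(map, haps, sprintf("%s%03d", breed, 1:n),
                  rep(breed, n), rep(c("M", "F"), length.out = n))
}

test_that("native classification applies the strict frequency threshold", {
  map <- make_marker_map(2, 60, 1e5)  # two 5.9 Mb chromosomes
  m <- nrow(map)
  set.seed(13)
  focal_h <- rbinom(m, 1, 0.5)
  focal <- toy_panel(map, cbind(focal_h, rbinom(m, 1, 0.5)))
  # 50 reference individuals = 100 haplotypes, all maximally different
  ref_haps <- matrix(rep(1 - focal_h, 100), m)
  # haplotypes 1 and 2 share focal's chr1 markers 10..45 (3.5 Mb block)
  block <- 10:45
  ref_haps[block, 1] <- focal_h[block]
  ref_haps[block, 2] <- focal_h[block]
  refs <- make_ref_panel(map, ref_haps)
  mask <- native_mask(focal, refs, crit_default)
  # freq 2/100 = 0.02 >= 0.01 on the block -> migrant exactly there
  expect_false(any(mask[block, 1]))
  expect_true(all(mask[-block, 1]))
  expect_equal(mask[, 1], oracle_native_hap(focal_h, refs, map,
                                            crit_default),
               ignore_attr = TRUE)
  # with only one sharer the frequency is 0.01, not < 0.01: still migrant
  ref_haps[block, 2] <- 1 - focal_h[block]
  mask1 <- native_mask(focal, make_ref_panel(map, ref_haps), crit_default)
  expect_false(any(mask1[block, 1]))
  # at 200 haplotypes the single sharer's frequency 0.005 < 0.01: native
  wide <- cbind(ref_haps, matrix(rep(1 - focal_h, 100), m))
  mask2 <- native_mask(focal, make_ref_panel(map, wide), crit_default)
  expect_true(all(mask2[, 1]))
})

test_that("all-native and all-migrant extremes behave as classified", {
  map <- make_marker_map(1, 30, 1e5)
  set.seed(14)
  h <- rbinom(30, 1, 0.5)
  focal <- toy_panel(map, cbind(h, h))
  # no reference haplotype shares anything
  refs_none <- make_ref_panel(map, matrix(rep(1 - h, 10), 30))
  expect_true(all(native_mask(focal, refs_none, crit_default)))
  # identical to 2 of 10 haplotypes genome-wide (freq 0.2)
  refs_all <- make_ref_panel(map, cbind(h, h,
                                        matrix(rep(1 - h, 8), 30)))
  expect_false(any(native_mask(focal, refs_all, crit_default)))
  expect_error(native_mask(focal, panel_subset(refs_none, integer(0))),
               "non-empty")
})

test_that("lowering the frequency threshold never increases the native
           fraction", {
  stud <- make_study_population(331, n_base = 10)
  prev <- NULL
  for (f in c(0.005, 0.01, 0.02)) {
    crit <- segment_criteria(max_ref_freq = f)
    mask <- native_mask(stud$founders, stud$refs, crit)
    if (!is.null(prev)) expect_lte(mean(prev), mean(mask))
    prev <- mask
  }
})

test_that("migrant contribution is the weighted non-native genome share", {
  map <- make_marker_map(2, 20, 1e5)
  m <- nrow(map)
  all_nat <- matrix(TRUE, m, 4)
  expect_equal(migrant_contribution(all_nat, map), c(0, 0),
               ignore_attr = TRUE)
  expect_equal(migrant_contribution(!all_nat, map), c(1, 1),
               ignore_attr = TRUE)
  half <- cbind(rep(TRUE, m), rep(FALSE, m))
  expect_equal(unname(migrant_contribution(half, map)), 0.5)
  set.seed(15)
  mask <- matrix(rbinom(m * 4, 1, 0.5) == 1, m)
  w <- marker_weights(map)
  want <- sapply(1:2, function(i)
    1 - sum(w * (mask[, 2 * i - 1] + mask[, 2 * i]) / 2))
  expect_equal(unname(migrant_contribution(mask, map)), want)
})

test_that("estimated MC tracks the true migrant fraction of fresh
           mosaics", {
  stud <- make_study_population(341, n_base = 10)
  mask <- native_mask(stud$founders, stud$refs)
  est <- migrant_contribution(mask, stud$map)
  true <- true_migrant_fraction(stud$founders)
  expect_lt(abs(mean(est) - mean(true)), 0.05)
})
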