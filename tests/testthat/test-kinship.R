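crit <- segment_criteria(min_markers = 10, min_length_mb = 0.9)

test_that("kinship diagonal and disjoint-pair limits are exact", {
  map <- make_marker_map(1, 30, 1e5)
  h <- rbinom(30, 1, 0.5)
  # one individual with two identical haplotypes
  p1 <- toy_panel(map, cbind(h, h))
  expect_equal(fseg_matrix(p1, crit)[1, 1], 1.0)
  # two individuals sharing nothing
  p2 <- toy_panel(map, cbind(h, h, 1 - h, 1 - h))
  expect_equal(fseg_matrix(p2, crit)[1, 2], 0)
})

test_that("a single half-genome pairing contributes 1/8", {
  # two equal-length chromosomes; only hap1(i) and hap1(j) agree, on chr1
  map <- make_marker_map(2, 30, 1e5)
  set.seed(21)
  a <- rbinom(60, 1, 0.5)
  h_i1 <- a
  h_j1 <- c(a[1:30], 1 - a[31:60])     # shares chr1 only
  h_i2 <- 1 - h_j1                      # shares nothing with anyone
  h_j2 <- c(1 - a[1:30], a[31:60])     # differs from h_i1 and h_i2
  h_j2[seq(1, 60, by = 2)] <- 1 - h_j2[seq(1, 60, by = 2)]
  p <- toy_panel(map, cbind(h_i1, h_i2, h_j1, h_j2))
  F <- fseg_matrix(p, crit)
  expect_equal(F[1, 2], (0.5 + 0 + 0 + 0) / 4, tolerance = 1e-12)
})

test_that("kinship matrices equal the position-wise integration oracle", {
  stud <- make_study_population(351, n_base = 10,
                                markers_per_chr = 100)
  small <- panel_subset(stud$base, 1:8)
  F <- fseg_matrix(small, crit)
  expect_equal(unname(F), oracle_fseg(small, crit), tolerance = 1e-12)
  mask <- native_mask(small, stud$refs, crit)
  nat <- fseg_native_matrices(small, mask, crit)
  want <- oracle_fseg_native(small, mask, crit)
  expect_equal(unname(nat$Snat), want$Snat, tolerance = 1e-12)
  expect_equal(unname(nat$Dnat), want$Dnat, tolerance = 1e-12)
  # structural bounds
  expect_true(all(nat$Snat <= F + 1e-12))
  expect_true(all(nat$Snat <= nat$Dnat + 1e-12))
  expect_true(all(diag(F) >= 0.5))
})

test_that("conditioning on an all-native or all-migrant mask collapses
           correctly", {
  map <- make_marker_map(1, 30, 1e5)
  set.seed(22)
  alleles <- matrix(rbinom(30 * 6, 1, 0.5), 30)
  p <- toy_panel(map, alleles)
  F <- fseg_matrix(p, crit)
  all_nat <- matrix(TRUE, 30, 6)
  nat <- fseg_native_matrices(p, all_nat, crit)
  expect_equal(nat$Snat, F, tolerance = 1e-12)
  expect_true(all(abs(nat$Dnat - 1) < 1e-12))
  mig <- fseg_native_matrices(p, !all_nat, crit)
  expect_true(all(mig$Snat == 0))
  expect_true(all(mig$Dnat == 0))
})

test_that("population summaries equal the direct double sums", {
  F1 <- matrix(1, 1, 1, dimnames = list("a", "a"))
  k1 <- kinship_set(F1, F1, F1, 0.2)
  expect_equal(population_summaries(k1)$fseg, 1)
  # two unrelated non-inbred individuals
  F2 <- matrix(c(0.5, 0, 0, 0.5), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  k2 <- kinship_set(F2, F2, matrix(1, 2, 2, dimnames = dimnames(F2)),
                    c(0, 0))
  expect_equal(population_summaries(k2)$fseg, 0.25)
  set.seed(23)
  F5 <- crossprod(matrix(rnorm(25), 5)) / 10
  dimnames(F5) <- list(paste0("i", 1:5), paste0("i", 1:5))
  S5 <- F5 / 2
  D5 <- matrix(0.8, 5, 5, dimnames = dimnames(F5))
  m5 <- runif(5)
  c5 <- runif(5)
  c5 <- c5 / sum(c5)
  s <- population_summaries(kinship_set(F5, S5, D5, m5), c5)
  loop <- function(M) {
    tot <- 0
    for (i in 1:5) for (j in 1:5) tot <- tot + c5[i] * c5[j] * M[i, j]
    tot
  }
  expect_equal(s$fseg, loop(F5))
  expect_equal(s$fseg_native, loop(S5) / loop(D5))
  expect_equal(s$mc, sum(c5 * m5))
  expect_error(population_summaries(kinship_set(F5, S5, 0 * D5, m5)),
               "native")
})

test_that("breed averages respect symmetry, degenerate breeds and drift
           ordering", {
  map <- make_marker_map(1, 30, 1e5)
  set.seed(24)
  alleles <- matrix(rbinom(30 * 8, 1, 0.5), 30)
  dup <- haplotype_panel(map, cbind(alleles, alleles),
                         c(paste0("a", 1:4), paste0("b", 1:4)),
                         rep(c("X", "Y"), each = 4),
                         rep(c("M", "F"), 4))
  tab <- breed_average_kinship(dup, crit)
  expect_equal(tab["X", "Y"], tab["X", "X"], tolerance = 1e-12)
  # single-individual breeds are well-defined
  solo <- haplotype_panel(map, alleles[, 1:4], c("s1", "s2"),
                          c("P", "Q"), c("M", "F"))
  expect_true(all(is.finite(breed_average_kinship(solo, crit))))
  # synthetic drift structure: within-breed exceeds distant between-breed
  stud <- make_study_population(361, n_base = 10)
  big <- breed_average_kinship(stud$panel)
  expect_gt(big["Angler", "Angler"], big["Angler", "Fleckvieh"])
  expect_gt(big["HolsteinFriesian", "HolsteinFriesian"],
            big["HolsteinFriesian", "Fleckvieh"])
  # the Holstein group is closer to the focal breed than Fleckvieh
  expect_gt(big["Angler", "HolsteinFriesian"], big["Angler", "Fleckvieh"])
  expect_gt(big["Angler", "NorwegianRed"], big["Angler", "Fleckvieh"])
})

test_that("PSD projection floors negative eigenvalues only when needed", {
  A <- diag(3)
  expect_equal(nearest_psd(A), A)
  B <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  Bp <- nearest_psd(B)
  expect_gte(min(eigen(Bp, symmetric = TRUE)$values), -1e-10)
  expect_true(isSymmetric(Bp))
})

test_that("predicted offspring kinship c'Fc matches the realized mean", {
  stud <- make_study_population(371)
  kin <- compute_kinship_set(stud$base, stud$refs)
  n <- n_individuals(stud$base)
  c_unif <- numeric(n)
  c_unif[stud$base$sex == "M"] <- 0.5 / sum(stud$base$sex == "M")
  c_unif[stud$base$sex == "F"] <- 0.5 / sum(stud$base$sex == "F")
  pred <- drop(c_unif %*% kin$F %*% c_unif)
  counts <- contributions_to_counts(c_unif, stud$base$sex, n, seed = 5)
  off <- advance_generation(stud$base, counts, seed = 6)
  realized <- population_summaries(compute_kinship_set(off, stud$refs))$fseg
  expect_lt(abs(realized - pred), 0.015)
})
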