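test_that("meiosis respects Mendelian inheritance and zero-length maps", {
  map <- make_marker_map(2, 50, 1e6)
  set.seed(41)
  h1 <- rbinom(100, 1, 0.5)
  h2 <- rbinom(100, 1, 0.5)
  for (i in 1:20) {
    g <- meiosis(h1, h2, map)
    expect_true(all(g == h1 | g == h2))
  }
  # zero genetic length: the gamete is one intact parental haplotype
  flat <- marker_map(paste0("m", 1:10), rep("1", 10), (1:10) * 1e3,
                     position_cM = rep(1, 10))
  g0 <- meiosis(h1[1:10], h2[1:10], flat)
  expect_true(identical(as.integer(g0), h1[1:10]) ||
                identical(as.integer(g0), h2[1:10]))
  expect_equal(attr(g0, "n_crossovers"), 0L)
})

test_that("crossover counts follow the map length in Morgans", {
  set.seed(42)
  # 1-Morgan chromosome
  n <- rep(0, 10000)
  for (i in seq_along(n)) n[i] <- length(sample_breakpoints(0, 100))
  expect_lt(abs(mean(n) - 1), 0.03)
})

test_that("base generation assembly hits exact sex counts and founder
           alleles", {
  map <- make_marker_map(2, 40, 1e6)
  set.seed(43)
  founders <- toy_panel(map, matrix(rbinom(80 * 8, 1, 0.5), 80),
                        sex = c("M", "M", "F", "F"))
  base <- make_base_generation(founders, n = 100, seed = 44)
  expect_equal(sum(base$sex == "M"), 50)
  expect_equal(sum(base$sex == "F"), 50)
  base2 <- make_base_generation(founders, n = 100, seed = 44)
  expect_identical(base$alleles, base2$alleles)
  # single founder couple: all alleles descend from those 4 haplotypes
  couple <- panel_subset(founders, c(1, 3))
  b <- make_base_generation(couple, n = 20, seed = 45)
  for (m in 1:80) {
    expect_true(all(b$alleles[m, ] %in% couple$alleles[m, ]))
  }
  expect_error(make_base_generation(panel_subset(founders, 1:2), 10),
               "both sexes")
})

test_that("advance_generation realizes requested family sizes exactly", {
  map <- make_marker_map(2, 40, 1e6)
  set.seed(46)
  parents <- toy_panel(map, matrix(rbinom(80 * 40, 1, 0.5), 80),
                       sex = rep(c("M", "F"), 10))
  # equal-family scheme: every parent exactly 2 offspring
  counts <- rep(2L, 20)
  off <- advance_generation(parents, counts, seed = 47)
  ped <- attr(off, "pedigree")
  expect_equal(n_individuals(off), 20)
  expect_true(all(table(ped$sire) == 2))
  expect_true(all(table(ped$dam) == 2))
  # arbitrary sire counts are realized exactly, across seeds
  for (s in 1:3) {
    cm <- c(10L, 6L, 0L, 2L, 0L, 0L, 0L, 0L, 2L, 0L)
    counts2 <- integer(20)
    counts2[parents$sex == "M"] <- cm
    counts2[parents$sex == "F"] <- 2L
    off2 <- advance_generation(parents, counts2, seed = s)
    ped2 <- attr(off2, "pedigree")
    got <- tabulate(ped2$sire, nbins = 20)[parents$sex == "M"]
    expect_equal(got, cm)
  }
  # one sire taking every slot makes him father of all offspring
  counts3 <- integer(20)
  counts3[which(parents$sex == "M")[1]] <- 20L
  counts3[parents$sex == "F"] <- 2L
  off3 <- advance_generation(parents, counts3, seed = 48)
  expect_true(all(attr(off3, "pedigree")$sire ==
                    which(parents$sex == "M")[1]))
  # allele conservation under random counts
  for (m in seq_len(10)) {
    i <- attr(off, "pedigree")[m, ]
    par_alleles <- c(parents$alleles[5, hap_cols(i$sire)],
                     parents$alleles[5, hap_cols(i$dam)])
    expect_true(all(off$alleles[5, hap_cols(m)] %in% par_alleles))
  }
})

test_that("per-marker annotations propagate through the same meioses", {
  map <- make_marker_map(2, 40, 1e6)
  set.seed(49)
  # give the two haplotypes of each parent distinct alleles everywhere so
  # the origin of every gamete marker is identifiable
  h1 <- matrix(rbinom(80 * 10, 1, 0.5), 80)
  alleles <- matrix(0L, 80, 20)
  alleles[, seq(1, 20, 2)] <- h1
  alleles[, seq(2, 20, 2)] <- 1L - h1
  parents <- toy_panel(map, alleles, sex = rep(c("M", "F"), 5))
  mask <- matrix(rep(c(TRUE, FALSE), 10), 80, 20, byrow = TRUE)
  counts <- rep(2L, 10)
  off <- advance_generation(parents, counts, seed = 50, mask = mask)
  off_mask <- attr(off, "mask")
  ped <- attr(off, "pedigree")
  for (k in seq_len(n_individuals(off))) {
    sire <- ped$sire[k]
    # paternal gamete: mask TRUE exactly where the allele came from hap 1
    from_h1 <- off$alleles[, 2 * k - 1] == parents$alleles[, 2 * sire - 1]
    expect_equal(off_mask[, 2 * k - 1], from_h1, ignore_attr = TRUE)
  }
})

test_that("bound recursions reproduce the closed forms", {
  expect_equal(update_kinship_bound(1, 0.005), 1)
  expect_equal(update_kinship_bound(0.048, 0.005), 0.05276)
  x <- 0.048
  for (t in 1:10) x <- update_kinship_bound(x, 0.005)
  expect_equal(x, 1 - 0.952 * 0.995^10, tolerance = 1e-12)
  expect_null(update_mc_bound("OCS-I", 0.62))
  expect_null(update_mc_bound("REF", 0.62))
  expect_equal(update_mc_bound("OCS-II", 0.62), 0.62)
  expect_equal(update_mc_bound("OCS-III", 0.600, 0.03), 0.582)
  expect_equal(update_mc_bound("OCS-III", 0.600, 0.03, mode = "absolute"),
               0.570)
})

test_that("diversity metrics are exact on constructed populations", {
  map <- make_marker_map(1, 30, 1e5)
  # all individuals heterozygous everywhere
  het <- matrix(rep(c(1L, 0L), each = 30), 30, 4)
  het[, 3] <- 1L
  het[, 4] <- 0L
  p_het <- toy_panel(map, het)
  expect_equal(observed_heterozygosity(p_het), 1)
  arch1 <- structure(list(qtl_indices = 5L, effects = 1,
                          reliability = 0.75),
                     class = "trait_architecture")
  # p = 0.5 at the QTL -> genic variance 2 * 0.5 * 0.5 * 1 = 0.5
  expect_equal(genic_variance(p_het, arch1), 0.5)
  # fixed loci: zero genic variance and zero heterozygosity
  fixed <- toy_panel(map, matrix(1L, 30, 4))
  expect_equal(genic_variance(fixed, arch1), 0)
  expect_equal(observed_heterozygosity(fixed), 0)
})
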