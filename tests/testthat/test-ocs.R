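# a hand-built kinship set over nm males and nf females
toy_kinship <- function(F, mc, Snat = F / 2,
                        Dnat = matrix(0.8, nrow(F), nrow(F))) {
  ids <- paste0("i", seq_len(nrow(F)))
  dimnames(F) <- dimnames(Snat) <- dimnames(Dnat) <- list(ids, ids)
  kinship_set(F, Snat, Dnat, mc)
}

test_that("inbreeding-rate and sire-number formulas give the printed
           values", {
  expect_equal(delta_f_from_ne(100), 0.005)
  expect_equal(n_sires_for_ne(100, 500), 26L)
  expect_equal(n_sires_for_ne(1000, 500), 500L)
  expect_error(n_sires_for_ne(100, 20), "infeasible")
})

test_that("truncation selection picks the top-EBV males with equal
           shares", {
  set.seed(31)
  ebv <- rnorm(60)
  sex <- rep(c("M", "F"), 30)
  ts <- truncation_select(ebv, sex, ne_target = 40)
  males <- which(sex == "M")
  k <- ts$n_sires
  expect_equal(sort(ts$sires),
               sort(males[order(ebv[males],
                                decreasing = TRUE)][seq_len(k)]))
  expect_equal(sum(ts$c[ts$sires]), 0.5)
  expect_equal(length(unique(ts$c[ts$sires])), 1)
  expect_equal(sum(ts$c[sex == "F"]), 0.5)
})

test_that("without bounds the optimum is the single best male", {
  set.seed(32)
  n <- 10
  F <- diag(n) * 0.5
  ebv <- rnorm(n)
  sex <- rep(c("M", "F"), each = 5)
  prob <- selection_problem(ebv, toy_kinship(F, runif(n)), sex)
  r <- solve_ocs(prob)
  best <- which.max(ebv[1:5])
  expect_equal(r$c[best], 0.5)
  expect_equal(sum(r$c[1:5]), 0.5)
  expect_equal(r$status, "optimal")
})

test_that("kinship-constrained optimum matches a dense grid search and
           binds the bound", {
  set.seed(33)
  # 3 males, 4 females; hand-built PSD kinship
  sex <- c("M", "M", "M", "F", "F", "F", "F")
  A <- matrix(rnorm(49), 7)
  F <- crossprod(A) / 40 + diag(7) * 0.3
  mc <- runif(7, 0.4, 0.8)
  ebv <- c(3, 2, 1, rnorm(4))
  kin <- toy_kinship(F, mc)
  ub <- 0.12
  prob <- selection_problem(ebv, kin, sex, ub_fseg = ub)
  r <- solve_ocs(prob)
  expect_equal(r$status, "optimal")
  grid <- oracle_ocs_grid(ebv, kin, sex, ub_fseg = ub, by = 0.001)
  expect_lt(abs(r$achieved$ebv - grid$objective), 1e-3)
  # the kinship bound binds at the optimum
  expect_lt(abs(r$achieved$fseg - ub), 1e-6)
})

test_that("ratio and MC constraints agree with the grid oracle and are
           respected", {
  set.seed(34)
  sex <- c("M", "M", "M", "F", "F", "F")
  A <- matrix(rnorm(36), 6)
  F <- crossprod(A) / 30 + diag(6) * 0.3
  S <- crossprod(matrix(rnorm(36), 6)) / 60 + diag(6) * 0.05
  D <- matrix(0.5, 6, 6) + diag(6) * 0.1
  mc <- c(0.8, 0.5, 0.3, 0.6, 0.6, 0.6)
  ebv <- c(3, 2, 1, 0, 0, 0)
  kin <- toy_kinship(F, mc, Snat = S, Dnat = D)
  prob <- selection_problem(ebv, kin, sex, ub_fsegn = 0.14, ub_mc = 0.55)
  r <- solve_ocs(prob)
  expect_equal(r$status, "optimal")
  expect_lte(r$achieved$fseg_native, 0.14 + 1e-6)
  expect_lte(r$achieved$mc, 0.55 + 1e-6)
  grid <- oracle_ocs_grid(ebv, kin, sex, ub_fsegn = 0.14, ub_mc = 0.55,
                          by = 0.001)
  expect_lt(abs(r$achieved$ebv - grid$objective), 2e-3)
})

test_that("inactive bounds reproduce the unconstrained optimum and
           relaxing bounds never hurts", {
  set.seed(35)
  sex <- c("M", "M", "M", "F", "F", "F")
  F <- crossprod(matrix(rnorm(36), 6)) / 30 + diag(6) * 0.3
  mc <- runif(6, 0.3, 0.7)
  ebv <- c(1, 2, 3, 0, 0, 0)
  kin <- toy_kinship(F, mc)
  free <- solve_ocs(selection_problem(ebv, kin, sex))
  # bounds placed at the unconstrained achieved values stay inactive
  again <- solve_ocs(selection_problem(
    ebv, kin, sex, ub_fseg = free$achieved$fseg + 1e-9,
    ub_mc = free$achieved$mc + 1e-9))
  expect_lt(abs(again$achieved$ebv - free$achieved$ebv), 1e-5)
  # objective is monotone in the kinship bound
  vals <- sapply(c(0.10, 0.13, 0.2), function(ub)
    solve_ocs(selection_problem(ebv, kin, sex,
                                ub_fseg = ub))$achieved$ebv)
  expect_true(all(diff(vals) > -1e-8))
})

test_that("an unsatisfiable bound set is reported infeasible with
           violations", {
  sex <- c("M", "M", "F", "F")
  F <- diag(4) * 0.5
  kin <- toy_kinship(F, c(0.9, 0.8, 0.9, 0.9))
  prob <- selection_problem(c(1, 2, 0, 0), kin, sex, ub_mc = 0.2)
  r <- solve_ocs(prob)
  expect_equal(r$status, "infeasible")
  expect_true(any(r$violations > 0))
})

test_that("contribution-to-count rounding is exact largest-remainder", {
  sex <- rep(c("M", "F"), c(3, 500))
  c <- c(0.3, 0.15, 0.05, rep(0.5 / 500, 500))
  counts <- contributions_to_counts(c, sex, 1000, seed = 1)
  expect_equal(counts[1:3], c(600L, 300L, 100L))
  expect_equal(sum(counts[1:3]), 1000L)
  expect_true(all(counts[-(1:3)] == 2L))
  # equal male contributions give equal counts; zero gives zero
  sex2 <- rep(c("M", "F"), each = 50)
  c2 <- c(rep(0.5 / 50, 50), rep(0.5 / 50, 50))
  expect_true(all(contributions_to_counts(c2, sex2, 100, seed = 2) == 2L))
  c3 <- c(0.5, rep(0, 49), rep(0.5 / 50, 50))
  counts3 <- contributions_to_counts(c3, sex2, 100, seed = 3)
  expect_equal(counts3[1], 100L)
  expect_true(all(counts3[2:50] == 0L))
  expect_error(contributions_to_counts(c3, sex2, 99), "divisible")
})
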