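test_that("directional min-max standardization maps the optimum to one", {
  x <- cbind(up = c(2, 4, 6), down = c(2, 4, 6))
  s <- gra_standardize(x, c("larger_better", "smaller_better"))
  expect_equal(s$standardized[, "up"], c(0, 0.5, 1))
  expect_equal(s$standardized[, "down"], c(1, 0.5, 0))
  expect_equal(s$reference, c(1, 1))
  # every standardized column attains both 0 and 1
  set.seed(31)
  x <- matrix(rnorm(40), 8, 5)
  s <- gra_standardize(x, rep("larger_better", 5))
  expect_equal(apply(s$standardized, 2, min), rep(0, 5))
  expect_equal(apply(s$standardized, 2, max), rep(1, 5))

  expect_error(gra_standardize(cbind(a = c(1, 1, 1)), "larger_better"),
               "constant indicator.*a")
})

test_that("deviation extrema scan all entities and indicators", {
  set.seed(32)
  s <- gra_standardize(matrix(rnorm(20), 4, 5), rep("larger_better", 5))
  expect_equal(unname(deviation_extrema(s)), c(0, 1))

  hand <- structure(list(
    standardized = matrix(1 - c(0.2, 0.7, 0.4, 0.1), 2, 2),
    reference = c(1, 1)), class = "gra_sequences")
  expect_equal(unname(deviation_extrema(hand)), c(0.1, 0.7))

  self <- structure(list(standardized = matrix(1, 1, 3),
                         reference = rep(1, 3)), class = "gra_sequences")
  expect_equal(unname(deviation_extrema(self)), c(0, 0))
})

test_that("relational coefficients follow the rho-weighted contrast formula", {
  # deviations 0, 0.5, 1 with extrema (0, 1) and rho = 0.5
  s <- structure(list(standardized = matrix(c(1, 0.5, 0), 3, 1),
                      reference = 1), class = "gra_sequences")
  eta <- relational_coefficients(s, rho = 0.5)
  expect_equal(as.numeric(eta), c(1, 0.5, 1 / 3), tolerance = 1e-12)

  # entity identical to the reference: all coefficients one
  self <- structure(list(standardized = matrix(1, 2, 3),
                         reference = rep(1, 3)), class = "gra_sequences")
  expect_equal(as.numeric(relational_coefficients(self, 0.5)), rep(1, 6))
  # rho = 0 with exact agreement: guarded, still one
  expect_equal(as.numeric(relational_coefficients(self, 0)), rep(1, 6))
})

test_that("relational grades average coefficients per entity", {
  expect_equal(relational_grade(rep(1, 5)), 1.0)
  expect_equal(relational_grade(c(1, 1 / 3)), 0.6667, tolerance = 5e-5)
  expect_error(relational_grade(numeric(0)), "no coefficients")
})

test_that("pipeline grades equal a straight-line naive reimplementation", {
  set.seed(33)
  for (i in 1:100) {
    x <- matrix(runif(40, 1, 100), 4, 10)
    directions <- sample(c("larger_better", "smaller_better"), 10,
                         replace = TRUE)
    rows <- x[rep(1:4, each = 1), , drop = FALSE]
    m <- matrix_fixture(rows, treatments = c("T1", "T2", "T3", "T4"),
                        replicates = 1, directions = directions)
    res <- gra_pipeline(m)
    expect_equal(unname(res$grades),
                 naive_gra_grades(x, 0.5, directions),
                 tolerance = 1e-12)
    expect_true(all(res$coefficients >= 1 / 3 - 1e-12 &
                      res$coefficients <= 1 + 1e-12))
    expect_true(all(res$grades >= 1 / 3 - 1e-12 & res$grades <= 1 + 1e-12))
  }
})

test_that("grades are invariant to indicator order and entity labels", {
  m <- generate_experiment(seed = 9)
  res <- gra_pipeline(m)
  spec <- attr(m, "spec")
  set.seed(36)
  perm <- sample(length(spec))
  ind_names <- vapply(spec, `[[`, "", "name")
  df <- as.data.frame(m)[, c("treatment", "replicate", ind_names[perm])]
  m_perm <- indicator_matrix(df, spec[perm])
  res_perm <- gra_pipeline(m_perm)
  expect_equal(res_perm$grades, res$grades, tolerance = 1e-12)
  expect_identical(res_perm$ranking, res$ranking)
})

test_that("a treatment dominating every indicator grades 1 and ranks first", {
  x <- rbind(best = c(9, 9, 1), mid = c(5, 4, 5), worst = c(1, 2, 9))
  m <- matrix_fixture(x, treatments = c("best", "mid", "worst"),
                      replicates = 1,
                      directions = c("larger_better", "larger_better",
                                     "smaller_better"))
  res <- gra_pipeline(m)
  expect_equal(unname(res$grades["best"]), 1.0)
  expect_identical(res$ranking[1], "best")
})

test_that("raising rho compresses coefficients toward one", {
  set.seed(34)
  x <- matrix(runif(40), 4, 10)
  s <- gra_standardize(x, rep("larger_better", 10))
  eta_lo <- relational_coefficients(s, rho = 0.1)
  eta_hi <- relational_coefficients(s, rho = 0.9)
  nonzero <- abs(s$standardized - 1) > 1e-9
  expect_true(all(eta_hi[nonzero] >= eta_lo[nonzero]))
  # deviation ordering is preserved for any fixed rho
  for (rho in c(0.1, 0.5, 0.9)) {
    eta <- relational_coefficients(s, rho)
    dev <- abs(s$standardized - 1)
    o <- order(dev)
    expect_true(all(diff(eta[o]) <= 1e-12))
  }
})

test_that("favorable moves never lower an entity's grade", {
  set.seed(35)
  for (i in 1:20) {
    x <- matrix(runif(24, 10, 20), 4, 6)
    # entity 2, indicator 3 moves toward the column maximum while the
    # attaining extremes stay put
    target <- which.max(x[, 3])
    if (target == 2) next
    x2 <- x
    x2[2, 3] <- x[2, 3] + 0.5 * (max(x[, 3]) - x[2, 3])
    g1 <- naive_gra_grades(x)
    g2 <- naive_gra_grades(x2)
    expect_gte(g2[2] + 1e-12, g1[2])
  }
})
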