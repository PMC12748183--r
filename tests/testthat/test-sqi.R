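test_that("correlation PCA matches closed forms and an independent oracle", {
  # two indicators correlated at r -> eigenvalues (1 + r, 1 - r)
  set.seed(21)
  z <- rnorm(400)
  for (r_target in c(0.3, 0.6, 0.9)) {
    x <- cbind(z, r_target * z + sqrt(1 - r_target^2) * rnorm(400))
    r_emp <- cor(x)[1, 2]
    p <- correlation_pca(x)
    expect_equal(p$eigenvalues, c(1 + r_emp, 1 - r_emp), tolerance = 1e-10)
  }

  # duplicated indicator pair: eigenvalues (2, 0)
  x <- cbind(a = z, b = z)
  p <- correlation_pca(x)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-10)

  # independent indicators at large n: all eigenvalues near 1
  set.seed(22)
  x <- matrix(rnorm(5000 * 4), ncol = 4)
  expect_equal(correlation_pca(x)$eigenvalues, rep(1, 4), tolerance = 0.1)

  # eigenvalues match prcomp on standardized data (independent route)
  set.seed(23)
  for (i in 1:20) {
    x <- matrix(rnorm(30 * 6), ncol = 6) %*% matrix(runif(36, -1, 1), 6)
    p <- correlation_pca(x)
    expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-10)
    expect_equal(p$eigenvalues, prcomp(x, scale. = TRUE)$sdev^2,
                 tolerance = 1e-10)
    h <- communalities(p, seq_len(6))
    expect_true(all(h >= 0 & h <= 1 + 1e-12))
    expect_equal(unname(h), rep(1, 6), tolerance = 1e-8)  # full rank: all 1
  }

  x_bad <- cbind(rnorm(10), rep(2, 10))
  colnames(x_bad) <- c("ok", "flat")
  expect_error(correlation_pca(x_bad), "zero-variance.*flat")
})

test_that("Kaiser retention is inclusive at the threshold", {
  p <- structure(list(eigenvalues = c(3.2, 1.0, 0.8)),
                 class = "indicator_pca")
  expect_identical(retain_components(p), c(1L, 2L))
  p$eigenvalues <- c(0.99, 0.6)
  expect_error(retain_components(p), "no component")
})

test_that("the 10% loading window and redundancy rule follow the arithmetic", {
  fake_pca <- function(loadings1) {
    l <- cbind(PC1 = loadings1)
    rownames(l) <- paste0("V", seq_along(loadings1))
    structure(list(eigenvalues = c(2), loadings = l), class = "indicator_pca")
  }
  expect_identical(candidate_indicators(fake_pca(c(0.90, 0.82, 0.30)), 1),
                   c("V1", "V2"))  # 0.82 >= 0.81
  expect_identical(candidate_indicators(fake_pca(c(0.90, 0.80, 0.30)), 1),
                   "V1")           # 0.80 < 0.81
  expect_identical(candidate_indicators(fake_pca(c(0.7)), 1), "V1")

  corr <- diag(3)
  dimnames(corr) <- list(paste0("V", 1:3), paste0("V", 1:3))
  h <- c(V1 = 0.9, V2 = 0.7, V3 = 0.5)
  l <- c(V1 = 0.9, V2 = 0.8, V3 = 0.7)

  corr2 <- corr; corr2["V1", "V2"] <- corr2["V2", "V1"] <- 0.95
  expect_identical(resolve_redundancy(c("V1", "V2"), corr2, h, l), "V1")

  corr3 <- corr; corr3["V1", "V2"] <- corr3["V2", "V1"] <- 0.30
  expect_setequal(resolve_redundancy(c("V1", "V2"), corr3, h, l),
                  c("V1", "V2"))

  corr4 <- corr
  corr4[upper.tri(corr4)] <- c(0.7, 0.65, 0.8)
  corr4[lower.tri(corr4)] <- t(corr4)[lower.tri(corr4)]
  expect_length(resolve_redundancy(c("V1", "V2", "V3"), corr4, h, l), 1L)

  # negative correlation also counts as redundancy (absolute value)
  corr5 <- corr; corr5["V1", "V2"] <- corr5["V2", "V1"] <- -0.8
  expect_identical(resolve_redundancy(c("V1", "V2"), corr5, h, l), "V1")
})

test_that("communality weights normalize to one", {
  l <- cbind(PC1 = c(sqrt(0.8), sqrt(0.2), 0.5, 0.5),
             PC2 = c(0, 0, 0.5, 0.5))
  rownames(l) <- paste0("V", 1:4)
  p <- structure(list(eigenvalues = c(2, 1), loadings = l),
                 class = "indicator_pca")
  w <- communality_weights(p, c("V1", "V2"), components = 1L)
  expect_equal(unname(w), c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(communality_weights(p, "V1", 1L)), 1.0)
  w4 <- communality_weights(p, paste0("V", 3:4), components = 1:2)
  expect_equal(unname(w4), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("piecewise linear scoring honors direction and thresholds", {
  up <- scoring_function("larger_better", 2, 6)
  expect_equal(piecewise_linear_score(6, up), 1.0)
  expect_equal(piecewise_linear_score(8, up), 1.0)   # clamped above
  expect_equal(piecewise_linear_score(4, up), 0.5)
  expect_equal(piecewise_linear_score(2, up), 0.0)
  expect_equal(piecewise_linear_score(0, up), 0.0)   # clamped below

  down <- scoring_function("smaller_better", 2, 6)   # e.g. pH, PAD
  expect_equal(piecewise_linear_score(2, down), 1.0)
  expect_equal(piecewise_linear_score(6, down), 0.0)
  expect_equal(piecewise_linear_score(4, down), 0.5)
  expect_error(scoring_function("larger_better", 5, 5))
})

test_that("the weighted index is a convex combination of scores", {
  expect_equal(compute_sqi(rep(1, 4), rep(0.25, 4)), 1.0)
  expect_equal(compute_sqi(rep(0, 4), rep(0.25, 4)), 0.0)
  expect_equal(compute_sqi(c(1, 0.5, 0, 0.5), c(0.3, 0.2, 0.3, 0.2)), 0.5)
  expect_error(compute_sqi(c(1, 0), c(1)), "length")
})

test_that("the SQI pipeline is bounded, normalized and direction-monotone", {
  for (s in 1:10) {
    m <- generate_experiment(seed = s)
    res <- sqi_pipeline(m)
    expect_equal(sum(res$weights), 1, tolerance = 1e-12)
    expect_true(all(res$weights >= 0))
    expect_true(all(res$sqi >= -1e-12 & res$sqi <= 1 + 1e-12))
    expect_true(all(res$scores >= -1e-12 & res$scores <= 1 + 1e-12))
    expect_true(all(res$mds %in% rownames(res$pca$loadings)))
  }

  # improving one MDS indicator in its favorable direction, with MDS,
  # thresholds and weights held fixed, never lowers the index
  m <- generate_experiment(seed = 4)
  res <- sqi_pipeline(m)
  for (ind in res$mds) {
    f <- res$scoring[[ind]]
    sc <- res$scores[1, ]
    x0 <- (f$lower + f$upper) / 2
    better <- if (f$direction == "larger_better") x0 * 1.05 else x0 * 0.95
    sc_new <- sc
    sc_new[ind] <- piecewise_linear_score(better, f)
    expect_gte(compute_sqi(sc_new, res$weights) + 1e-12,
               compute_sqi(replace(sc, ind, piecewise_linear_score(x0, f)),
                           res$weights))
  }
})

test_that("a treatment dominating every indicator gets the top SQI", {
  # noise-free: treatment B beats the rest on all larger-better indicators
  # and has the lowest value of the smaller-better one
  directions <- c(rep("larger_better", 3), "smaller_better")
  x <- rbind(
    A = c(1.0, 2.0, 3.0, 10),
    B = c(2.0, 3.5, 4.1, 4),
    C = c(1.5, 2.5, 3.3, 8),
    D = c(1.2, 3.0, 3.6, 9)
  )
  # three replicates with tiny deterministic jitter to keep variance nonzero
  jit <- c(-0.01, 0, 0.01)
  rows <- do.call(rbind, lapply(1:3, function(j) x + jit[j]))
  m <- matrix_fixture(rows[order(rep(1:4, 3)), ],
                      treatments = c("A", "B", "C", "D"), replicates = 3,
                      directions = directions)
  res <- sqi_pipeline(m)
  expect_identical(names(which.max(res$treatment_sqi)), "B")
})

test_that("planted-block data: covered blocks are recovered exactly once", {
  # when every latent block reaches some component's loading window, the
  # pipeline must select exactly one indicator per block; block coverage
  # itself is limited by eigenvector rotation among the equal-eigenvalue
  # blocks, so it is measured, not assumed
  covered_runs <- 0L
  for (s in 1:30) {
    m <- generate_planted_blocks(planted_block_design(), seed = s)
    blocks <- attr(m, "blocks")
    p <- correlation_pca(m)
    ret <- retain_components(p)
    cand <- unique(unlist(lapply(ret, function(pc)
      candidate_indicators(p, pc))))
    res <- sqi_pipeline(m)
    if (length(unique(blocks[cand])) == 4L) {
      covered_runs <- covered_runs + 1L
      expect_length(res$mds, 4L)
      expect_identical(sort(unname(blocks[res$mds])), 1:4)
    }
    # never two indicators from one block (they correlate above 0.60)
    expect_false(anyDuplicated(blocks[res$mds]) > 0)
  }
  expect_gt(covered_runs, 15L)  # coverage is the common case
})
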