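# Shared fixtures and independent oracles for the test suite.

# a 4-treatment design matching the pot experiment
pot_design <- function() {
  experiment_design(c("CK", "DI", "BA", "DB"), control = "CK")
}

# small indicator spec: k larger-better indicators named V1..Vk
simple_spec <- function(k, directions = rep("larger_better", k)) {
  lapply(seq_len(k), function(i)
    indicator_spec(paste0("V", i), direction = directions[i]))
}

# indicator matrix from a numeric treatments x replicates x indicator array
# laid out as a sample x indicator matrix
matrix_fixture <- function(x, treatments, replicates,
                           directions = rep("larger_better", ncol(x))) {
  k <- ncol(x)
  colnames(x) <- paste0("V", seq_len(k))
  df <- data.frame(
    treatment = rep(treatments, each = replicates),
    replicate = rep(seq_len(replicates), times = length(treatments))
  )
  indicator_matrix(cbind(df, as.data.frame(x)), simple_spec(k, directions))
}

# independent straight-line GRA reimplementation: explicit loops, no shared
# code with the package internals. Entities in rows, all larger-better
# unless directions given.
naive_gra_grades <- function(x, rho = 0.5,
                             directions = rep("larger_better", ncol(x))) {
  n_e <- nrow(x); n_k <- ncol(x)
  s <- matrix(NA_real_, n_e, n_k)
  for (k in seq_len(n_k)) {
    lo <- min(x[, k]); hi <- max(x[, k])
    for (i in seq_len(n_e)) {
      s[i, k] <- if (directions[k] == "larger_better") {
        (x[i, k] - lo) / (hi - lo)
      } else {
        (hi - x[i, k]) / (hi - lo)
      }
    }
  }
  dev <- matrix(NA_real_, n_e, n_k)
  for (i in seq_len(n_e)) for (k in seq_len(n_k)) dev[i, k] <- abs(s[i, k] - 1)
  dmin <- Inf; dmax <- -Inf
  for (i in seq_len(n_e)) for (k in seq_len(n_k)) {
    if (dev[i, k] < dmin) dmin <- dev[i, k]
    if (dev[i, k] > dmax) dmax <- dev[i, k]
  }
  grades <- numeric(n_e)
  for (i in seq_len(n_e)) {
    eta <- numeric(n_k)
    for (k in seq_len(n_k)) {
      eta[k] <- (dmin + rho * dmax) / (dev[i, k] + rho * dmax)
    }
    grades[i] <- sum(eta) / n_k
  }
  grades
}

# random valid sieve composition on the default 4-class scheme
random_composition <- function(mode = "dry") {
  w <- stats::runif(4, 0.01, 1)
  sieve_composition(w, mode = mode)
}
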