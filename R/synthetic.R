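## Seeded synthetic experiments.
##
## Three generators: (i) a four-treatment pot experiment with per-indicator
## baselines, multiplicative treatment shifts and Gaussian replicate noise;
## (ii) planted correlation-block data for exercising minimum-data-set
## recovery; (iii) random sieve compositions on the four-class simplex with
## a wet-mode fines shift. All are pure functions of (parameters, seed).

## internal: stable 31-ary string hash, kept under 2^31 - 1
label_hash <- function(label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  h
}

## internal: derive an independent stream seed from the root seed and a
## label, so adding an indicator or treatment does not perturb the draws of
## the others
stream_seed <- function(seed, label) {
  (as.numeric(seed) %% 2147483647 + label_hash(label)) %% 2147483647
}

#' Treatment-effect profile for the synthetic pot experiment
#'
#' @param baseline named numeric vector: control mean per indicator.
#' @param shift treatment x indicator matrix of multiplicative shifts
#'   relative to the control baseline (control row = 1).
#' @param noise_sd named numeric vector: Gaussian replicate noise sd per
#'   indicator, on the measurement scale.
#' @param directions named character vector of indicator directions.
#' @param layer named character vector of indicator layers (defaults to
#'   `"soil"`).
#' @param positive_only named logical: indicators that cannot be negative
#'   (drawn by truncation-by-resampling).
#' @return object of class `effect_profile`.
#' @export
effect_profile <- function(baseline, shift, noise_sd, directions,
                           layer = NULL, positive_only = NULL) {
  ind <- names(baseline)
  stopifnot(!is.null(ind), all(baseline > 0),
            identical(colnames(shift), ind),
            identical(names(noise_sd), ind),
            all(noise_sd >= 0), all(shift > 0),
            all(ind %in% names(directions)))
  if (is.null(layer)) layer <- stats::setNames(rep("soil", length(ind)), ind)
  if (is.null(positive_only)) {
    positive_only <- stats::setNames(rep(TRUE, length(ind)), ind)
  }
  structure(list(baseline = baseline, shift = shift, noise_sd = noise_sd,
                 directions = directions[ind], layer = layer[ind],
                 positive_only = positive_only[ind]),
            class = "effect_profile")
}

#' Default soil effect profile of the four-treatment pot experiment
#'
#' Emulates the published pot experiment on the twelve soil indicators used
#' by the Soil Quality Index (SWC, MWD, GMD, PAD, pH, SOC, TN, TP, AN, AP,
#' SC, UE). Physical-indicator baselines, shifts and noise come directly
#' from the published treatment means and standard deviations
#' ([pot_experiment_means()]); chemical and enzymatic baselines use the
#' reported initial-soil values of the source site (pH 7.03, SOC 13.89 g/kg,
#' TN 1.14 g/kg, TP 110.38 mg/kg) with field-typical alkaline-N, available-P
#' and enzyme-activity levels, and shifts follow the published
#' percentage changes and treatment orderings: the diatom crust raises SOC,
#' AN (+12.8%), AP (+48.0%) and sucrase (+47.9%) most and lowers pH most;
#' the Bacillus crust raises TN and urease (+190%) most; the mixed crust
#' improves structure but depletes nutrients and enzyme activity.
#'
#' @return an [effect_profile()] over treatments CK, DI, BA, DB.
#' @export
default_soil_profile <- function() {
  ind <- c("SWC", "MWD", "GMD", "PAD", "pH", "SOC",
           "TN", "TP", "AN", "AP", "SC", "UE")
  baseline <- stats::setNames(
    c(14.27, 1.89, 1.10, 19.60, 7.03, 13.89,
      1.14, 110.38, 60, 10, 20, 0.50), ind)
  noise_sd <- stats::setNames(
    c(0.77, 0.06, 0.05, 2.13, 0.05, 0.60,
      0.05, 5.0, 3.0, 0.80, 1.50, 0.05), ind)
  shift <- rbind(
    CK = rep(1, 12),
    DI = c(16.68 / 14.27, 2.19 / 1.89, 1.48 / 1.10, 8.12 / 19.60,
           0.96, 1.21, 1.15, 1.05, 1.128, 1.48, 1.479, 1.50),
    BA = c(16.87 / 14.27, 2.31 / 1.89, 1.69 / 1.10, 16.74 / 19.60,
           0.97, 1.15, 1.30, 1.02, 1.05, 0.90, 1.20, 2.90),
    DB = c(17.35 / 14.27, 2.85 / 1.89, 2.03 / 1.10, 23.64 / 19.60,
           1.00, 0.97, 0.90, 0.98, 0.95, 0.95, 0.85, 1.30)
  )
  colnames(shift) <- ind
  directions <- stats::setNames(
    ifelse(ind %in% c("PAD", "pH"), "smaller_better", "larger_better"), ind)
  effect_profile(baseline, shift, noise_sd, directions)
}

## internal: one Gaussian draw, resampled while negative for positive-only
## indicators (truncation by resampling keeps the mean undistorted for the
## small truncation probabilities used here); retry cap 100
draw_cell <- function(n, mean, sd, positive_only) {
  v <- stats::rnorm(n, mean, sd)
  if (positive_only && sd > 0) {
    for (i in which(v < 0)) {
      tries <- 0L
      while (v[i] < 0) {
        tries <- tries + 1L
        if (tries > 100L) {
          stop("could not draw a non-negative value after 100 retries",
               call. = FALSE)
        }
        v[i] <- stats::rnorm(1L, mean, sd)
      }
    }
  }
  v
}

#' Generate a synthetic pot experiment
#'
#' Replicate values are `baseline * shift + Gaussian noise`, drawn from an
#' independent seeded stream per (treatment, indicator) cell so the output is
#' deterministic given the seed and unaffected by adding other indicators.
#'
#' @param profile an [effect_profile()] (default [default_soil_profile()]).
#' @param design an [experiment_design()]; its treatments must match the
#'   profile's shift rows.
#' @param seed integer root seed.
#' @return an [indicator_matrix()] with the profile's directions attached.
#' @export
generate_experiment <- function(profile = default_soil_profile(),
                                design = experiment_design(
                                  c("CK", "DI", "BA", "DB"), control = "CK"),
                                seed = 1L) {
  stopifnot(inherits(profile, "effect_profile"),
            inherits(design, "experiment_design"),
            all(design$treatments %in% rownames(profile$shift)))
  ind <- names(profile$baseline)
  reps <- design$replicates
  rows <- expand.grid(replicate = seq_len(reps),
                      treatment = design$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("treatment", "replicate")]
  for (k in ind) rows[[k]] <- NA_real_
  for (tr in design$treatments) {
    for (k in ind) {
      mu <- profile$baseline[[k]] * profile$shift[tr, k]
      set.seed(stream_seed(seed, paste(tr, k, sep = "\r")))
      v <- draw_cell(reps, mu, profile$noise_sd[[k]],
                     profile$positive_only[[k]])
      rows[rows$treatment == tr, k] <- v
    }
  }
  spec <- lapply(ind, function(k)
    indicator_spec(k, direction = profile$directions[[k]],
                   layer = profile$layer[[k]]))
  indicator_matrix(rows, spec)
}

#' Planted correlation-block design
#'
#' @param n_blocks number of latent factors (default 4).
#' @param per_block indicators per factor (default 3).
#' @param within_r target within-block correlation in (0, 1) (default 0.85).
#' @param noise_sd idiosyncratic noise sd; default `sqrt(1 - within_r)` so
#'   the within-block correlation equals `within_r` exactly in expectation.
#' @param n sample count (default 40); must be at least the indicator count
#'   plus 2.
#' @return object of class `planted_block_design`.
#' @export
planted_block_design <- function(n_blocks = 4L, per_block = 3L,
                                 within_r = 0.85, noise_sd = NULL,
                                 n = 40L) {
  stopifnot(n_blocks >= 1L, per_block >= 1L,
            within_r > 0, within_r < 1,
            n >= n_blocks * per_block + 2L)
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - within_r)
  structure(list(n_blocks = as.integer(n_blocks),
                 per_block = as.integer(per_block),
                 within_r = within_r, noise_sd = noise_sd,
                 n = as.integer(n)),
            class = "planted_block_design")
}

#' Generate planted correlation-block data
#'
#' Each indicator is `sqrt(within_r) * latent-factor draw + noise_sd *
#' independent noise`: indicators sharing a factor correlate at
#' `within_r` (with the default noise), indicators in different blocks are
#' uncorrelated in expectation. Block membership is attached as ground truth
#' in attribute `blocks`.
#'
#' @param d a [planted_block_design()].
#' @param seed integer seed.
#' @return an [indicator_matrix()] (single pseudo-treatment, one sample per
#'   replicate) with attribute `blocks`: named integer vector of true block
#'   memberships.
#' @export
generate_planted_blocks <- function(d = planted_block_design(), seed = 1L) {
  stopifnot(inherits(d, "planted_block_design"))
  set.seed(stream_seed(seed, "planted-blocks"))
  p <- d$n_blocks * d$per_block
  factors <- matrix(stats::rnorm(d$n * d$n_blocks), d$n, d$n_blocks)
  lambda <- sqrt(d$within_r)
  x <- matrix(NA_real_, d$n, p)
  blocks <- integer(p)
  for (b in seq_len(d$n_blocks)) {
    for (j in seq_len(d$per_block)) {
      col <- (b - 1L) * d$per_block + j
      x[, col] <- lambda * factors[, b] + d$noise_sd * stats::rnorm(d$n)
      blocks[col] <- b
    }
  }
  ind <- sprintf("V%02d", seq_len(p))
  colnames(x) <- ind
  names(blocks) <- ind
  df <- data.frame(treatment = "sample", replicate = seq_len(d$n))
  df <- cbind(df, as.data.frame(x))
  spec <- lapply(ind, indicator_spec)
  m <- indicator_matrix(df, spec)
  attr(m, "blocks") <- blocks
  m
}

#' Generate random sieve-composition pairs
#'
#' Dry compositions are symmetric Dirichlet draws on the four-class simplex;
#' the paired wet composition moves a random Beta-distributed share of the
#' >0.25 mm mass into the two fine classes, so the percentage of aggregate
#' destruction is positive on average.
#'
#' @param n number of dry/wet pairs.
#' @param scheme a [sieve_scheme()].
#' @param alpha symmetric Dirichlet concentration (default 2).
#' @param seed integer seed.
#' @return list of `n` elements, each `list(dry = , wet = )` of
#'   [sieve_composition()] objects.
#' @export
generate_sieve_compositions <- function(n, scheme = sieve_scheme(),
                                        alpha = 2, seed = 1L) {
  stopifnot(n >= 1L, inherits(scheme, "sieve_scheme"))
  set.seed(stream_seed(seed, "sieve-compositions"))
  k <- scheme$n_class
  cut <- which(abs(scheme$boundaries - 0.25) < 1e-9)
  stopifnot(length(cut) == 1L)
  coarse <- seq_len(cut)
  fine <- setdiff(seq_len(k), coarse)
  lapply(seq_len(n), function(i) {
    g <- stats::rgamma(k, shape = alpha)
    w_dry <- g / sum(g)
    f <- stats::rbeta(1L, 2, 5)  # share of coarse mass destroyed by wetting
    moved <- f * w_dry[coarse]
    w_wet <- w_dry
    w_wet[coarse] <- w_dry[coarse] - moved
    w_wet[fine] <- w_dry[fine] + sum(moved) / length(fine)
    list(dry = sieve_composition(w_dry, scheme, "dry"),
         wet = sieve_composition(w_wet, scheme, "wet"))
  })
}
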