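## Grey Relational Analysis.
##
## Ranks entities (here: biocrust treatments) by their closeness to an ideal
## reference built from each indicator's optimal value. After directional
## min-max standardization the reference is the all-ones sequence; relational
## coefficients contrast each deviation against the global deviation extrema
## with a distinguishing coefficient rho, and the relational grade is the
## unweighted mean coefficient per entity.

#' Directional min-max standardization of an entity x indicator table
#'
#' Larger-is-better indicators map linearly so the column maximum becomes 1
#' and the minimum 0; smaller-is-better indicators are mirrored so the
#' minimum becomes 1. The ideal reference sequence is therefore all ones.
#'
#' @param x numeric entity x indicator matrix (rows named by entity).
#' @param directions character vector (or named vector covering the columns
#'   of `x`) of `"larger_better"` / `"smaller_better"`.
#' @return object of class `gra_sequences`: list with `standardized`
#'   (entity x indicator, values in [0, 1]) and `reference` (all ones).
#' @export
gra_standardize <- function(x, directions) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 1L, ncol(x) >= 1L)
  if (!is.null(names(directions)) && !is.null(colnames(x))) {
    directions <- directions[colnames(x)]
  }
  stopifnot(length(directions) == ncol(x),
            all(directions %in% c("larger_better", "smaller_better")))
  s <- x
  for (k in seq_len(ncol(x))) {
    lo <- min(x[, k]); hi <- max(x[, k])
    if (hi == lo) {
      stop(sprintf("constant indicator across entities: '%s'",
                   if (is.null(colnames(x))) k else colnames(x)[k]),
           call. = FALSE)
    }
    s[, k] <- if (directions[k] == "larger_better") {
      (x[, k] - lo) / (hi - lo)
    } else {
      (hi - x[, k]) / (hi - lo)
    }
  }
  structure(list(standardized = s,
                 reference = rep(1, ncol(x))),
            class = "gra_sequences")
}

#' Global deviation extrema
#'
#' Minimum and maximum of |X_i(k) - X_0(k)| over all entities i and
#' indicators k. After min-max standardization with at least two distinct
#' values per indicator these are 0 and 1.
#'
#' @param s a `gra_sequences` object.
#' @return named numeric vector `c(dmin = ..., dmax = ...)`.
#' @export
deviation_extrema <- function(s) {
  stopifnot(inherits(s, "gra_sequences"))
  dev <- abs(sweep(s$standardized, 2L, s$reference))
  c(dmin = min(dev), dmax = max(dev))
}

#' Grey relational coefficients
#'
#' \eqn{\eta_i(k) = (\Delta_{min} + \rho\Delta_{max}) /
#' (\Delta_i(k) + \rho\Delta_{max})} with distinguishing coefficient
#' \eqn{\rho \in [0, 1]} (default 0.5). If every deviation is zero (an entity
#' set identical to the reference) all coefficients are 1 by convention.
#'
#' @param s a `gra_sequences` object.
#' @param rho distinguishing coefficient in [0, 1].
#' @return entity x indicator matrix of coefficients in (0, 1].
#' @export
relational_coefficients <- function(s, rho = 0.5) {
  stopifnot(inherits(s, "gra_sequences"), rho >= 0, rho <= 1)
  dev <- abs(sweep(s$standardized, 2L, s$reference))
  dmin <- min(dev); dmax <- max(dev)
  if (dmax == 0) {
    eta <- dev; eta[] <- 1
    return(eta)
  }
  denom <- dev + rho * dmax
  eta <- (dmin + rho * dmax) / denom
  # rho = 0 leaves exact-agreement cells 0/0: perfect agreement scores 1
  eta[dev == 0 & denom == 0] <- 1
  eta
}

#' Grey relational grade of one entity
#'
#' Unweighted arithmetic mean of the entity's relational coefficients over
#' the indicators.
#'
#' @param eta numeric vector of coefficients for one entity.
#' @return the grade.
#' @export
relational_grade <- function(eta) {
  if (!length(eta)) stop("no coefficients supplied", call. = FALSE)
  mean(eta)
}

#' Full Grey Relational Analysis of an experiment
#'
#' Entities are treatments; by default each treatment's comparative sequence
#' is its replicate mean per indicator (`entity_mode = "treatment_means"`),
#' matching the one-grade-per-treatment presentation; with
#' `entity_mode = "per_replicate"` every pot is an entity, which yields
#' within-treatment dispersion of grades.
#'
#' @param m an [indicator_matrix()]; directions come from its spec.
#' @param rho distinguishing coefficient (default 0.5).
#' @param entity_mode `"treatment_means"` or `"per_replicate"`.
#' @param indicators optional subset of indicator names to analyse.
#' @return object of class `gra_result`: list with `sequences`,
#'   `deviations`, `extrema`, `coefficients`, `grades` (named, per entity)
#'   and `ranking` (entity names, best first).
#' @export
gra_pipeline <- function(m, rho = 0.5,
                         entity_mode = c("treatment_means", "per_replicate"),
                         indicators = NULL) {
  stopifnot(inherits(m, "indicator_matrix"))
  entity_mode <- match.arg(entity_mode)
  spec <- attr(m, "spec")
  directions <- spec_directions(spec)
  use <- if (is.null(indicators)) spec_names(spec) else indicators
  stopifnot(all(use %in% spec_names(spec)))

  df <- as.data.frame(m)
  if (entity_mode == "treatment_means") {
    x <- sapply(use, function(ind)
      tapply(df[[ind]], df$treatment, mean)[attr(m, "treatments")])
    x <- matrix(x, nrow = length(attr(m, "treatments")),
                dimnames = list(attr(m, "treatments"), use))
  } else {
    x <- as.matrix(df[, use, drop = FALSE])
    rownames(x) <- paste(df$treatment, df$replicate, sep = ".")
  }

  s <- gra_standardize(x, directions[use])
  dev <- abs(sweep(s$standardized, 2L, s$reference))
  extrema <- deviation_extrema(s)
  eta <- relational_coefficients(s, rho)
  grades <- apply(eta, 1L, relational_grade)
  structure(list(
    sequences = s, deviations = dev, extrema = extrema,
    coefficients = eta, grades = grades,
    ranking = names(sort(grades, decreasing = TRUE))
  ), class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat("grey relational grades (best first):\n")
  g <- sort(x$grades, decreasing = TRUE)
  for (i in seq_along(g)) {
    cat(sprintf("  %d. %s  %.3f\n", i, names(g)[i], g[i]))
  }
  invisible(x)
}
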