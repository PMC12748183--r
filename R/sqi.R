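## Minimum-data-set Soil Quality Index.
##
## The pipeline: correlation-matrix PCA over all indicators -> retain
## components by the Kaiser criterion -> per retained component, candidate
## indicators within 10% of the maximum absolute loading -> collapse
## candidate groups correlated at |r| >= 0.60 to a single representative ->
## weight the selected minimum data set (MDS) by normalized communalities ->
## score each indicator with a piecewise linear more/less-is-better function
## -> SQI = sum(W_i * S_i), in [0, 1].
##
## Indicator direction enters only at the scoring stage; PCA sees the
## z-scored raw values unflipped.

#' Principal component analysis on the indicator correlation matrix
#'
#' Eigendecomposition of the Pearson correlation matrix of the sample x
#' indicator data. Loadings are eigenvectors scaled by the square root of
#' their eigenvalue, so the communality of an indicator over a component set
#' is the sum of its squared loadings. Each loading column is oriented so its
#' largest-magnitude entry is positive; selection rules use absolute values,
#' so results do not depend on this sign convention.
#'
#' @param m an [indicator_matrix()] or a numeric sample x indicator matrix.
#' @return object of class `indicator_pca`: list with `eigenvalues`
#'   (descending), `loadings` (indicator x component), `proportion`,
#'   `cumulative` (variance shares), and `correlation` (the input
#'   correlation matrix).
#' @export
correlation_pca <- function(m) {
  x <- if (inherits(m, "indicator_matrix")) indicator_values(m) else as.matrix(m)
  stopifnot(is.numeric(x), ncol(x) >= 2L, nrow(x) >= 3L)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance indicator(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  load <- eig$vectors %*% diag(sqrt(ev), nrow = length(ev))
  # orient: largest-|entry| positive per column
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  structure(list(
    eigenvalues = ev,
    loadings = load,
    proportion = ev / sum(ev),
    cumulative = cumsum(ev) / sum(ev),
    correlation = r
  ), class = "indicator_pca")
}

#' @export
print.indicator_pca <- function(x, ...) {
  cat("correlation-matrix PCA\n eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  cat(sprintf(" components with eigenvalue >= 1: %d (%.1f%% of variance)\n",
              sum(x$eigenvalues >= 1),
              100 * x$cumulative[max(1L, sum(x$eigenvalues >= 1))]))
  invisible(x)
}

#' Retain components by the Kaiser criterion
#'
#' @param pca an `indicator_pca` object.
#' @param threshold minimum eigenvalue for retention (default 1.0,
#'   inclusive).
#' @return integer vector of retained component indices, in order.
#' @export
retain_components <- function(pca, threshold = 1.0) {
  stopifnot(inherits(pca, "indicator_pca"))
  keep <- which(pca$eigenvalues >= threshold)
  if (!length(keep)) {
    stop("no component reaches the retention threshold; pipeline aborted",
         call. = FALSE)
  }
  keep
}

#' Communalities over a component set
#'
#' Share of each indicator's (unit) variance explained by the given
#' components: row sums of squared loadings.
#'
#' @param pca an `indicator_pca` object.
#' @param components component indices (typically from
#'   [retain_components()]).
#' @return named numeric vector in [0, 1] per indicator.
#' @export
communalities <- function(pca, components) {
  stopifnot(inherits(pca, "indicator_pca"), length(components) >= 1L)
  h <- rowSums(pca$loadings[, components, drop = FALSE]^2)
  pmin(h, 1)
}

#' Candidate indicators on one component
#'
#' Indicators whose absolute loading on the component is within 10% of the
#' component's maximum absolute loading (i.e. >= 0.9 x max by default).
#'
#' @param pca an `indicator_pca` object.
#' @param component single component index.
#' @param window relative window below the maximum absolute loading
#'   (default 0.10).
#' @return character vector of indicator names.
#' @export
candidate_indicators <- function(pca, component, window = 0.10) {
  stopifnot(inherits(pca, "indicator_pca"), length(component) == 1L)
  l <- stats::setNames(abs(pca$loadings[, component]),
                       rownames(pca$loadings))
  names(l)[l >= (1 - window) * max(l)]
}

#' Collapse correlated candidates to one representative
#'
#' Within one component's candidate set, indicators connected by pairwise
#' |r| >= `r_threshold` form a redundancy group; each group contributes a
#' single indicator — the member with the largest communality over the
#' retained components (ties broken by larger absolute loading on the
#' proposing component, then input order). Candidates uncorrelated with all
#' others are kept as-is.
#'
#' @param candidates character vector of indicator names on one component.
#' @param corr full indicator correlation matrix.
#' @param communality named communality vector over retained components.
#' @param loading named absolute-loading vector on the proposing component.
#' @param r_threshold redundancy correlation threshold (default 0.60).
#' @return character vector: one indicator per redundancy group.
#' @export
resolve_redundancy <- function(candidates, corr, communality, loading,
                               r_threshold = 0.60) {
  stopifnot(length(candidates) >= 1L)
  if (length(candidates) == 1L) return(candidates)
  # connected components of the |r| >= threshold graph (union-find by sweep)
  adj <- abs(corr[candidates, candidates, drop = FALSE]) >= r_threshold
  diag(adj) <- TRUE
  group <- seq_along(candidates)
  repeat {
    changed <- FALSE
    for (i in seq_along(candidates)) {
      linked <- which(adj[i, ])
      g <- min(group[linked])
      if (any(group[linked] != g)) {
        group[linked] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- character(0L)
  for (g in unique(group)) {
    members <- candidates[group == g]
    h <- communality[members]
    best <- members[h == max(h)]
    if (length(best) > 1L) {
      l <- abs(loading[best])
      best <- best[l == max(l)]
    }
    keep <- c(keep, best[1L])
  }
  keep
}

#' Communality weights for the minimum data set
#'
#' \eqn{W_i = h_i / \sum_j h_j} over the MDS indicators; weights are
#' non-negative and sum to one.
#'
#' @param pca an `indicator_pca` object.
#' @param mds character vector of MDS indicator names.
#' @param components retained component indices used for the communalities.
#' @return named weight vector summing to 1.
#' @export
communality_weights <- function(pca, mds, components) {
  h <- communalities(pca, components)[mds]
  if (sum(h) <= 0) {
    stop("degenerate weights: all MDS communalities are zero", call. = FALSE)
  }
  h / sum(h)
}

#' Piecewise linear scoring function
#'
#' @param direction `"larger_better"` or `"smaller_better"`.
#' @param lower,upper scoring thresholds, `lower < upper`. For
#'   larger-is-better indicators the score is 0 at or below `lower`, 1 at or
#'   above `upper`, linear between; smaller-is-better mirrors this.
#' @return object of class `scoring_function`.
#' @export
scoring_function <- function(direction = c("larger_better", "smaller_better"),
                             lower, upper) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  structure(list(direction = direction, lower = lower, upper = upper),
            class = "scoring_function")
}

#' Score values with a piecewise linear function
#'
#' @param x numeric values.
#' @param f a [scoring_function()].
#' @return scores in [0, 1], same length as `x`.
#' @export
piecewise_linear_score <- function(x, f) {
  stopifnot(inherits(f, "scoring_function"))
  s <- (x - f$lower) / (f$upper - f$lower)
  s <- pmin(pmax(s, 0), 1)
  if (f$direction == "smaller_better") s <- 1 - s
  s
}

#' Weighted soil quality index
#'
#' \eqn{SQI = \sum_i W_i S_i} with scores in [0, 1] and weights summing to
#' one, so the index itself lies in [0, 1].
#'
#' @param scores indicator scores S_i in [0, 1].
#' @param weights weights W_i, non-negative, summing to 1.
#' @return the index value.
#' @export
compute_sqi <- function(scores, weights) {
  if (length(scores) != length(weights)) {
    stop("scores and weights differ in length", call. = FALSE)
  }
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-8,
            all(scores >= -1e-12), all(scores <= 1 + 1e-12))
  sum(weights * scores)
}

#' Full minimum-data-set SQI pipeline
#'
#' Runs PCA, Kaiser retention, the 10% loading rule, redundancy resolution
#' at |r| >= 0.60, communality weighting, piecewise linear scoring and the
#' weighted index, recording which component proposed each MDS indicator. An
#' indicator within the loading window of several retained components is
#' assigned to the component where its absolute loading is largest and
#' counted once. Scoring thresholds default to the observed minimum and
#' maximum of each MDS indicator across all samples; fixed agronomic
#' thresholds can be supplied via `thresholds`.
#'
#' @param m an [indicator_matrix()] (directions taken from its spec).
#' @param kaiser_threshold eigenvalue retention threshold (default 1.0).
#' @param loading_window relative loading window (default 0.10).
#' @param redundancy_r redundancy correlation threshold (default 0.60).
#' @param thresholds optional named list of `c(lower, upper)` per indicator,
#'   overriding observed-range scoring.
#' @param per_replicate if `TRUE` (default) the SQI is computed per sample
#'   and then averaged by treatment; if `FALSE` it is computed once per
#'   treatment from the treatment means.
#' @return object of class `sqi_result`: list with `pca`, `retained`,
#'   `candidates` (per component), `mds`, `proposed_by`, `weights`,
#'   `scoring` (per MDS indicator), `scores` (sample x MDS), `sqi`
#'   (per sample) and `treatment_sqi` (named means).
#' @export
sqi_pipeline <- function(m, kaiser_threshold = 1.0, loading_window = 0.10,
                         redundancy_r = 0.60, thresholds = NULL,
                         per_replicate = TRUE) {
  stopifnot(inherits(m, "indicator_matrix"))
  spec <- attr(m, "spec")
  directions <- spec_directions(spec)
  x <- indicator_values(m)

  pca <- correlation_pca(x)
  retained <- retain_components(pca, kaiser_threshold)
  h <- communalities(pca, retained)

  cand <- lapply(retained, function(pc)
    candidate_indicators(pca, pc, loading_window))
  names(cand) <- paste0("PC", retained)

  # assign multi-component candidates to their strongest component
  all_cand <- unique(unlist(cand))
  owner <- vapply(all_cand, function(ind) {
    pcs <- retained[vapply(cand, function(s) ind %in% s, logical(1L))]
    pcs[which.max(abs(pca$loadings[ind, pcs]))]
  }, numeric(1L))
  cand_owned <- lapply(retained, function(pc) all_cand[owner == pc])
  names(cand_owned) <- paste0("PC", retained)

  # components are processed in variance order; a candidate group of a later
  # component that is already represented in the MDS (some member correlates
  # at |r| >= redundancy_r with a selected indicator) contributes nothing,
  # which is how a retained component can end up with no MDS indicator
  mds <- character(0L)
  proposed_by <- integer(0L)
  for (i in seq_along(retained)) {
    pc <- retained[i]
    cands <- cand_owned[[i]]
    if (!length(cands)) next
    kept <- resolve_redundancy(cands, pca$correlation, h,
                               stats::setNames(abs(pca$loadings[, pc]),
                                               rownames(pca$loadings)),
                               redundancy_r)
    for (ind in kept) {
      covered <- length(mds) &&
        any(abs(pca$correlation[ind, mds]) >= redundancy_r)
      if (!covered) {
        mds <- c(mds, ind)
        proposed_by <- c(proposed_by, pc)
      }
    }
  }
  names(proposed_by) <- mds

  w <- communality_weights(pca, mds, retained)

  scoring <- lapply(mds, function(ind) {
    thr <- if (!is.null(thresholds) && !is.null(thresholds[[ind]])) {
      thresholds[[ind]]
    } else {
      range(x[, ind])
    }
    if (thr[1L] >= thr[2L]) {
      stop(sprintf("degenerate scoring range for indicator '%s'", ind),
           call. = FALSE)
    }
    scoring_function(directions[[ind]], thr[1L], thr[2L])
  })
  names(scoring) <- mds

  values <- if (per_replicate) {
    x
  } else {
    df <- as.data.frame(m)
    v <- sapply(spec_names(spec), function(ind)
      tapply(df[[ind]], df$treatment, mean)[attr(m, "treatments")])
    matrix(v, nrow = length(attr(m, "treatments")),
           dimnames = list(attr(m, "treatments"), spec_names(spec)))
  }
  scores <- sapply(mds, function(ind)
    piecewise_linear_score(values[, ind], scoring[[ind]]))
  scores <- matrix(scores, ncol = length(mds),
                   dimnames = list(NULL, mds))
  sqi <- as.numeric(scores %*% w)

  treatment_sqi <- if (per_replicate) {
    tapply(sqi, as.data.frame(m)$treatment, mean)[attr(m, "treatments")]
  } else {
    stats::setNames(sqi, attr(m, "treatments"))
  }

  structure(list(
    pca = pca, retained = retained, candidates = cand, mds = mds,
    proposed_by = proposed_by, weights = w, scoring = scoring,
    scores = scores, sqi = sqi,
    treatment_sqi = treatment_sqi
  ), class = "sqi_result")
}

#' @export
print.sqi_result <- function(x, ...) {
  cat(sprintf("minimum data set (%d of %d indicators): %s\n",
              length(x$mds), nrow(x$pca$loadings),
              paste(x$mds, collapse = ", ")))
  cat(" weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = " "),
      "\n per-treatment SQI:",
      paste(sprintf("%s=%.3f", names(x$treatment_sqi), x$treatment_sqi),
            collapse = " "), "\n")
  invisible(x)
}
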