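## Control-relative treatment effects.

#' Control-relative percent change
#'
#' Signed relative change of a treatment mean against the control mean,
#' \eqn{100 (t - c) / c}. Vectorized.
#'
#' @param treatment_mean treatment mean(s).
#' @param control_mean control mean(s); must be nonzero.
#' @return signed percentage change.
#' @export
#' @examples
#' relative_change(6.08, 4.45)  # +36.6% crust roughness
relative_change <- function(treatment_mean, control_mean) {
  stopifnot(is.numeric(treatment_mean), is.numeric(control_mean))
  if (any(control_mean == 0)) {
    stop("relative change undefined: control mean is zero", call. = FALSE)
  }
  100 * (treatment_mean - control_mean) / control_mean
}

## internal: effect table from a long means data.frame
## (indicator, treatment, mean)
effect_table_from_means <- function(means, control) {
  stopifnot(all(c("indicator", "treatment", "mean") %in% names(means)))
  if (!control %in% means$treatment) {
    stop("control treatment '", control, "' not present", call. = FALSE)
  }
  others <- setdiff(unique(means$treatment), control)
  rows <- lapply(unique(means$indicator), function(ind) {
    sub <- means[means$indicator == ind, ]
    cm <- sub$mean[sub$treatment == control]
    data.frame(
      indicator = ind,
      treatment = others,
      treatment_mean = sub$mean[match(others, sub$treatment)],
      control_mean = cm,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$pct_change <- relative_change(out$treatment_mean, out$control_mean)
  out$magnitude <- abs(out$pct_change)
  out$direction <- ifelse(out$pct_change > 0, "increase",
                          ifelse(out$pct_change < 0, "decrease", "none"))
  rownames(out) <- NULL
  out
}

#' Effect table for an experiment
#'
#' One row per (indicator, non-control treatment) with the treatment mean,
#' control mean, signed percent change, its magnitude, and the direction of
#' change. Values are carried at full precision; rounding is a presentation
#' concern.
#'
#' @param m an [indicator_matrix()].
#' @param design an [experiment_design()] naming the control.
#' @return data.frame with columns `indicator`, `treatment`,
#'   `treatment_mean`, `control_mean`, `pct_change`, `magnitude`,
#'   `direction`.
#' @export
effect_table <- function(m, design) {
  stopifnot(inherits(m, "indicator_matrix"),
            inherits(design, "experiment_design"))
  tm <- treatment_means(m)
  effect_table_from_means(tm, design$control)
}

#' Published pot-experiment summary data
#'
#' Treatment means and standard deviations (n = 3 pots) of the physical
#' indicators measured in a published greenhouse pot experiment that applied
#' diatom (DI), Bacillus megaterium (BA) and mixed (DB) biocrust inocula to
#' coal-mining subsidence soil against an untreated control (CK). The
#' `"crust"` layer carries crust hardness (Pa), chain-method roughness CR
#' (percent), saturated water content SWC (percent), aggregate MWD/GMD and
#' their water-stable variants (mm) and PAD (percent); the `"soil"` layer
#' carries the same aggregate and water indicators for the 0--10 cm soil
#' beneath the crust.
#'
#' @param layer `"crust"` or `"soil"`.
#' @return data.frame with columns `indicator`, `treatment`, `mean`, `sd`.
#' @export
pot_experiment_means <- function(layer = c("crust", "soil")) {
  layer <- match.arg(layer)
  path <- system.file("extdata",
                      sprintf("pot_experiment_%s_means.csv", layer),
                      package = "biocrustr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Effect table for the bundled pot-experiment summary data
#'
#' Recomputes the control-relative percentage changes from the published
#' treatment means as bundled by [pot_experiment_means()] — e.g. the +36.6%
#' crust-roughness gain and the -58.6% soil PAD change under the diatom
#' crust. Percentages are computed from the printed (rounded) means, which is
#' how such tables are conventionally reported.
#'
#' @param layer `"crust"` or `"soil"`.
#' @param control control treatment label (default `"CK"`).
#' @return effect table as in [effect_table()].
#' @export
reference_effects <- function(layer = c("crust", "soil"), control = "CK") {
  means <- pot_experiment_means(match.arg(layer))
  effect_table_from_means(means, control)
}
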