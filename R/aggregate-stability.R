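## Aggregate-stability indices from sieve-fraction data.
##
## Dry sieving gives the mechanically stable size distribution, wet sieving
## the water-stable one. MWD and GMD summarise a distribution; PAD compares
## the >0.25 mm content across the two modes.

#' Define a sieve size-class scheme
#'
#' @param boundaries class boundaries in mm, strictly decreasing; the scheme
#'   has `length(boundaries) + 1` classes (open-topped above the first
#'   boundary, open-bottomed below the last). Default is the four-class
#'   scheme >2, 2--0.25, 0.25--0.053, <0.053 mm.
#' @param diameters representative mean diameter of each class in mm, one per
#'   class. Defaults use bound midpoints for interior classes, 1.5x the lower
#'   bound for the open top class, and half the upper bound for the open
#'   bottom class.
#' @return an object of class `sieve_scheme`.
#' @export
#' @examples
#' sieve_scheme()  # the standard 4-class aggregate scheme
sieve_scheme <- function(boundaries = c(2, 0.25, 0.053),
                         diameters = NULL) {
  stopifnot(is.numeric(boundaries), length(boundaries) >= 1L,
            all(boundaries > 0), all(diff(boundaries) < 0))
  n_class <- length(boundaries) + 1L
  if (is.null(diameters)) {
    diameters <- numeric(n_class)
    diameters[1L] <- 1.5 * boundaries[1L]
    if (n_class > 2L) {
      for (i in 2:(n_class - 1L)) {
        diameters[i] <- (boundaries[i - 1L] + boundaries[i]) / 2
      }
    }
    diameters[n_class] <- boundaries[n_class - 1L] / 2
  }
  stopifnot(length(diameters) == n_class, all(diameters > 0))
  structure(list(boundaries = boundaries, diameters = diameters,
                 n_class = n_class),
            class = "sieve_scheme")
}

#' A measured sieve composition
#'
#' @param fractions non-negative mass per class, coarsest first. Accepted as
#'   raw masses, percentages or fractions; always renormalized to sum 1
#'   before any index is computed.
#' @param scheme a [sieve_scheme()].
#' @param mode `"dry"` (mechanical sieving) or `"wet"` (water-stable).
#' @return an object of class `sieve_composition` with normalized `w`.
#' @export
sieve_composition <- function(fractions, scheme = sieve_scheme(),
                              mode = c("dry", "wet")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "sieve_scheme"),
            is.numeric(fractions), length(fractions) == scheme$n_class,
            all(is.finite(fractions)), all(fractions >= 0))
  total <- sum(fractions)
  if (total <= 0) {
    stop("undefined composition: all class masses are zero", call. = FALSE)
  }
  structure(list(w = fractions / total, scheme = scheme, mode = mode),
            class = "sieve_composition")
}

#' Mean weight diameter (MWD)
#'
#' Mass-weighted arithmetic mean of the class mean diameters,
#' \eqn{\mathrm{MWD} = \sum_i X_i W_i}, in mm.
#'
#' @param comp a [sieve_composition()].
#' @return MWD in mm.
#' @export
compute_mwd <- function(comp) {
  stopifnot(inherits(comp, "sieve_composition"))
  sum(comp$scheme$diameters * comp$w)
}

#' Geometric mean diameter (GMD)
#'
#' Mass-weighted geometric mean of the class mean diameters,
#' \eqn{\mathrm{GMD} = \exp(\sum_i W_i \ln X_i)}, in mm. Requires all class
#' diameters to be positive; by the weighted AM--GM inequality GMD <= MWD.
#'
#' @param comp a [sieve_composition()].
#' @return GMD in mm.
#' @export
compute_gmd <- function(comp) {
  stopifnot(inherits(comp, "sieve_composition"))
  x <- comp$scheme$diameters
  if (any(x <= 0)) stop("class diameters must be positive", call. = FALSE)
  exp(sum(comp$w * log(x)))
}

#' Content of aggregates larger than 0.25 mm (R0.25)
#'
#' Percentage of mass in classes whose lower bound is at or above 0.25 mm.
#' The scheme must contain a 0.25 mm boundary.
#'
#' @param comp a [sieve_composition()].
#' @return percentage in [0, 100].
#' @export
compute_r025 <- function(comp) {
  stopifnot(inherits(comp, "sieve_composition"))
  b <- comp$scheme$boundaries
  cut <- which(abs(b - 0.25) < 1e-9)
  if (length(cut) != 1L) {
    stop("scheme has no 0.25 mm boundary; R0.25 undefined", call. = FALSE)
  }
  100 * sum(comp$w[seq_len(cut)])
}

#' Percentage of aggregate destruction (PAD)
#'
#' \eqn{\mathrm{PAD} = (DR_{0.25} - WR_{0.25})/DR_{0.25} \times 100}, the
#' relative loss of >0.25 mm aggregates from dry to wet sieving. Negative
#' values (wet content exceeding dry) are reported as computed, not clamped.
#'
#' @param dr025 dry-sieving >0.25 mm content, percent; must be > 0.
#' @param wr025 wet-sieving >0.25 mm content, percent.
#' @return PAD in percent (<= 100; may be negative).
#' @export
compute_pad <- function(dr025, wr025) {
  stopifnot(is.numeric(dr025), is.numeric(wr025))
  if (any(dr025 <= 0)) {
    stop("PAD undefined: dry-sieving R0.25 must be positive", call. = FALSE)
  }
  (dr025 - wr025) / dr025 * 100
}

#' Bundle the stability indices for one sample
#'
#' Computes MWD and GMD in both sieving modes plus the two R0.25 contents and
#' PAD. Following the conventional table layout, dry-mode MWD/GMD are the
#' headline values and wet-mode ones are reported as the "water-stable"
#' variants.
#'
#' @param dry,wet [sieve_composition()] objects sharing one scheme.
#' @return object of class `stability_indices`: list with `mwd`, `gmd`,
#'   `ws_mwd`, `ws_gmd` (mm), `r025_dry`, `r025_wet`, `pad` (percent).
#' @export
stability_indices <- function(dry, wet) {
  stopifnot(inherits(dry, "sieve_composition"),
            inherits(wet, "sieve_composition"))
  if (dry$mode != "dry" || wet$mode != "wet") {
    stop("arguments must be a dry and a wet composition, in that order",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(dry$scheme, wet$scheme))) {
    stop("dry and wet compositions use different sieve schemes",
         call. = FALSE)
  }
  r_dry <- compute_r025(dry)
  r_wet <- compute_r025(wet)
  structure(list(
    mwd = compute_mwd(dry), gmd = compute_gmd(dry),
    ws_mwd = compute_mwd(wet), ws_gmd = compute_gmd(wet),
    r025_dry = r_dry, r025_wet = r_wet,
    pad = compute_pad(r_dry, r_wet)
  ), class = "stability_indices")
}

#' @export
print.stability_indices <- function(x, ...) {
  cat(sprintf(paste0("aggregate stability: MWD %.2f mm, GMD %.2f mm, ",
                     "ws-MWD %.2f mm, ws-GMD %.2f mm, PAD %.2f%%%s\n"),
              x$mwd, x$gmd, x$ws_mwd, x$ws_gmd, x$pad,
              if (x$pad < 0) " [negative: wet exceeds dry]" else ""))
  invisible(x)
}
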