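#' Chain-method crust surface roughness
#'
#' A chain of original length L1 laid over the crust surface shortens in
#' horizontal projection to L2 as it follows the microrelief; the roughness
#' index is \eqn{C_r = (1 - L_2/L_1) \times 100} percent. A perfectly flat
#' surface gives 0; rougher surfaces give larger values, strictly decreasing
#' in L2 at fixed L1 and invariant to rescaling both lengths.
#'
#' Several chain placements on the same pot are summarised with
#' [mean_chain_roughness()].
#'
#' @param l1 original chain length, mm (> 0). The field default here is a
#'   43.0 mm chain.
#' @param l2 horizontal projected length, mm; must satisfy 0 < l2 <= l1.
#' @return roughness percentage in [0, 100). Vectorized over both arguments.
#' @export
#' @examples
#' chain_roughness(43, 38.7)  # 10%
chain_roughness <- function(l1, l2) {
  stopifnot(is.numeric(l1), is.numeric(l2))
  if (any(l1 <= 0)) stop("chain length l1 must be positive", call. = FALSE)
  if (any(l2 <= 0)) stop("projected length l2 must be positive", call. = FALSE)
  if (any(l2 > l1 + 1e-9)) {
    stop("measurement error: projected length l2 exceeds chain length l1",
         call. = FALSE)
  }
  (1 - pmin(l2 / l1, 1)) * 100
}

#' Mean roughness over repeated chain placements
#'
#' @param l1,l2 vectors of paired chain measurements for one pot.
#' @return arithmetic mean of the per-placement roughness values.
#' @export
mean_chain_roughness <- function(l1, l2) {
  stopifnot(length(l1) == length(l2), length(l1) >= 1L)
  mean(chain_roughness(l1, l2))
}
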