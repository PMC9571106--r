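#' Remaining litter dry mass, in percent of the initial mass
#'
#' @param initial_g Initial dry mass of the litterbag content, in grams.
#' @param final_g Dry mass recovered at sampling, in grams.
#' @return `100 * final_g / initial_g`, in `[0, 100]`. Vectorized.
#' @examples
#' remaining_mass_pct(10, 5)
#' @seealso [mass_loss_pct()]
#' @export
remaining_mass_pct <- function(initial_g, final_g) {
  .check_masses(initial_g, final_g)
  100 * final_g / initial_g
}

#' Litter mass loss, in percent of the initial mass
#'
#' The exact complement of [remaining_mass_pct()]:
#' `mass_loss_pct + remaining_mass_pct == 100` for every record.
#'
#' @inheritParams remaining_mass_pct
#' @return `100 - 100 * final_g / initial_g`, in `[0, 100]`. Vectorized.
#' @examples
#' mass_loss_pct(10, 5)
#' @export
mass_loss_pct <- function(initial_g, final_g) {
  .check_masses(initial_g, final_g)
  100 - 100 * final_g / initial_g
}

.check_masses <- function(initial_g, final_g) {
  bad <- !is.finite(initial_g) | initial_g <= 0
  if (any(bad)) {
    stop("invalid record(s) ", paste(which(bad), collapse = ", "),
         ": initial_dry_mass_g must be > 0")
  }
  bad <- !is.finite(final_g) | final_g < 0 | final_g > initial_g
  if (any(bad)) {
    stop("invalid record(s) ", paste(which(bad), collapse = ", "),
         ": final_dry_mass_g must lie in [0, initial_dry_mass_g]")
  }
  invisible(TRUE)
}

#' Water holding capacity of litter
#'
#' WHC is the wet/dry mass ratio of soaked-then-drained litter, times 100;
#' values above 100 are the norm (litter holds its own weight in water).
#' A wet weight below the dry weight is physically anomalous but can occur
#' with field material (drainage artefacts), so it warns rather than errs.
#'
#' @param wet_weight_g Mass after 24 h soaking and draining, grams.
#' @param dry_weight_g Mass after oven drying, grams.
#' @return `100 * wet / dry`, in percent.
#' @examples
#' whc_pct(12, 10)
#' @export
whc_pct <- function(wet_weight_g, dry_weight_g) {
  if (any(!is.finite(dry_weight_g) | dry_weight_g <= 0)) {
    stop("dry_weight_g must be > 0")
  }
  if (any(!is.finite(wet_weight_g) | wet_weight_g <= 0)) {
    stop("wet_weight_g must be > 0")
  }
  if (any(wet_weight_g < dry_weight_g)) {
    warning("wet weight below dry weight; returning the computed WHC anyway")
  }
  100 * wet_weight_g / dry_weight_g
}

#' Specific leaf area
#'
#' @param leaf_area_cm2 Projected leaf area, cm^2.
#' @param leaf_dry_mass_g Leaf dry mass, grams.
#' @return Area per unit dry mass, cm^2 g^-1.
#' @examples
#' sla_cm2_per_g(100, 2)
#' @export
sla_cm2_per_g <- function(leaf_area_cm2, leaf_dry_mass_g) {
  if (any(!is.finite(leaf_area_cm2) | leaf_area_cm2 <= 0) ||
      any(!is.finite(leaf_dry_mass_g) | leaf_dry_mass_g <= 0)) {
    stop("leaf area and dry mass must be > 0")
  }
  leaf_area_cm2 / leaf_dry_mass_g
}
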