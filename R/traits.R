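# Trait statistics: relative fitness, end-point conjugation rate, Miller
# units, swarming index.

#' Relative fitness from competition counts
#'
#' The ratio of Malthusian parameters of two competing strains over a
#' competition period: `W = ln(a_final/a_initial) / ln(b_final/b_initial)`.
#'
#' @param a_initial,a_final Densities of the focal strain (> 0).
#' @param b_initial,b_final Densities of the reference strain (> 0).
#' @return Relative fitness W (vectorised). `W = 1` is neutrality; `W < 0`
#'   means the focal strain declined while the reference grew.
#' @examples
#' relative_fitness(1e5, 1e8, 1e5, 1e7) # 1.5
#' @export
relative_fitness <- function(a_initial, a_final, b_initial, b_final) {
  if (any(c(a_initial, a_final, b_initial, b_final) <= 0)) {
    abort("all counts must be > 0")
  }
  denom <- log(b_final / b_initial)
  if (any(denom == 0)) {
    abort("reference strain growth ratio of 1: relative fitness undefined")
  }
  log(a_final / a_initial) / denom
}

#' End-point conjugation rate estimate
#'
#' The Simonsen-type end-point estimator of the per-cell, per-mL plasmid
#' transfer rate from a single final measurement of donors (D), recipients
#' (R), transconjugants (T) and total density:
#' `psi = ln(N/N0) / t` (population Malthusian rate, with `N = D + R + T`)
#' and `gamma = psi * ln(1 + T*N / (R*D)) / (N - N0)`.
#' Replicates with `T = 0` return `gamma = 0` flagged below detection;
#' such replicates are conventionally excluded from aggregate means.
#'
#' @param n0 Total initial density (CFU/mL), > 0.
#' @param d,r,t_count Final donor, recipient, transconjugant densities
#'   (CFU/mL); `d`, `r` > 0, `t_count` >= 0.
#' @param hours Elapsed time (h), > 0.
#' @param n Total final density; defaults to `d + r + t_count`.
#' @return Tibble (vectorised over replicates): `psi` (per h), `gamma`
#'   (mL per cell per h), `below_detection`.
#' @examples
#' conjugation_rate(1e6, 5e8, 5e8, 1e6, 24) # gamma ~ 1.15e-12
#' @export
conjugation_rate <- function(n0, d, r, t_count, hours, n = d + r + t_count) {
  if (any(d <= 0) || any(r <= 0)) abort("`d` and `r` must be > 0")
  if (any(t_count < 0)) abort("`t_count` must be >= 0")
  if (any(n <= n0)) {
    abort("final density must exceed initial density for the end-point estimator")
  }
  psi <- log(n / n0) / hours
  gamma <- psi * log(1 + (t_count * n) / (r * d)) / (n - n0)
  tibble(
    psi = psi,
    gamma = ifelse(t_count == 0, 0, gamma),
    below_detection = t_count == 0
  )
}

#' Miller units of beta-galactosidase activity
#'
#' The standard calculation
#' `MU = 1000 * (A420 - 1.75 * A550) / (t * v * OD600)`, where t is the
#' reaction time in minutes, v the culture volume in mL and A550 corrects
#' for cell debris scattering. A negative corrected absorbance is reported
#' as-is with a below-background warning.
#'
#' @param a420,a550 Absorbances (>= 0).
#' @param minutes Reaction time (min), > 0.
#' @param ml Culture volume (mL), > 0.
#' @param od600 Culture density, > 0.
#' @return Miller units (vectorised).
#' @examples
#' miller_units(0.6, 0, 15, 0.1, 0.4) # 1000
#' @export
miller_units <- function(a420, a550, minutes, ml, od600) {
  if (any(minutes <= 0) || any(ml <= 0) || any(od600 <= 0)) {
    abort("`minutes`, `ml` and `od600` must be > 0")
  }
  if (any(c(a420, a550) < 0)) abort("absorbances must be >= 0")
  corrected <- a420 - 1.75 * a550
  if (any(corrected < -1e-12)) {
    warn("corrected absorbance below background (A420 < 1.75 * A550)")
  }
  1000 * corrected / (minutes * ml * od600)
}

#' Swarming index
#'
#' Colony diameter at its widest, as a fraction of the plate diameter.
#'
#' @param colony_diameter,plate_diameter Same units; `0 < colony <= plate`.
#' @return Ratio in (0, 1] (vectorised).
#' @examples
#' swarming_index(20, 90)
#' @export
swarming_index <- function(colony_diameter, plate_diameter) {
  if (any(colony_diameter <= 0) || any(plate_diameter <= 0)) {
    abort("diameters must be > 0")
  }
  if (any(colony_diameter > plate_diameter)) {
    abort("colony diameter cannot exceed plate diameter")
  }
  colony_diameter / plate_diameter
}
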