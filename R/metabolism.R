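#' Photosynthesis parameters
#'
#' Parameters of the Michaelis-Menten relation between plant mass M (g)
#' and daily photosynthetic rate Q (g/day),
#' \deqn{Q = Q_M M / (k_{QM} + \vartheta M),}
#' with defaults derived for non-woody plants. Q saturates at
#' `QM / theta` (~34.9 g/day at the defaults) for very large plants.
#'
#' @param QM maximal-rate parameter (g/day).
#' @param kQM half-saturation-like parameter (g).
#' @param theta mass-saturation parameter (dimensionless).
#' @return An object of class `photo_params`.
#' @export
photo_params <- function(QM = 32.8, kQM = 1.06, theta = 0.94) {
  if (!(QM > 0 && kQM > 0 && theta > 0))
    stop("photosynthesis parameters QM, kQM, theta must all be positive")
  structure(list(QM = QM, kQM = kQM, theta = theta), class = "photo_params")
}

#' Daily photosynthetic demand of a plant
#'
#' Evaluates the mass-dependent photosynthetic rate
#' `Q = QM * M / (kQM + theta * M)`. This is the amount of nutrients an
#' individual attempts to consume in one day; it does not itself depend on
#' nutrient availability (the effective rate is limited by what the cell
#' can grant, see [serve_consumption()]). Strictly increasing in mass and
#' bounded above by `QM / theta`.
#'
#' @param mass plant mass M in grams; vectorized, must be non-negative.
#' @param params a [photo_params()] object.
#' @return Q in g/day, same length as `mass`.
#' @examples
#' photosynthetic_demand(1.0)  # 32.8 / (1.06 + 0.94) = 16.4
#' @export
photosynthetic_demand <- function(mass, params = photo_params()) {
  if (any(mass < 0)) stop("`mass` must be non-negative")
  params$QM * mass / (params$kQM + params$theta * mass)
}

#' Energy allocation profile of a cytotype
#'
#' Encodes the fixed BMR:SOMA:REB split of daily photosynthetic production
#' ("metabolic efficiency"). The diploid reference is 36:54:10. A reduction
#' in metabolic efficiency shifts allocation from the reproductive energy
#' budget (REB) to basal metabolism (BMR), leaving somatic growth (SOMA)
#' untouched: `bmr = 0.36 + 0.10 * reduction`,
#' `reb = 0.10 * (1 - reduction)`. So `reduction = 0.10` gives the
#' 37:54:9 profile, a 10% reduction in efficiency relative to the
#' reference.
#'
#' @param reduction fractional efficiency reduction; `0` reproduces the
#'   reference profile. Must not drive the REB fraction below zero
#'   (i.e. `reduction <= 1`).
#' @param base reference fractions, a numeric vector
#'   `c(bmr, soma, reb)` summing to 1.
#' @return An object of class `allocation_profile`: a named numeric vector
#'   `c(bmr = , soma = , reb = )` summing to 1.
#' @examples
#' allocation_profile(0)     # 0.36 0.54 0.10
#' allocation_profile(0.10)  # 0.37 0.54 0.09
#' @export
allocation_profile <- function(reduction = 0,
                               base = c(bmr = 0.36, soma = 0.54, reb = 0.10)) {
  if (length(base) != 3L || any(base < 0) || any(base > 1))
    stop("`base` must be three fractions in [0, 1]")
  if (abs(sum(base) - 1) > 1e-12)
    stop("`base` allocation fractions must sum to 1")
  if (!is.numeric(reduction) || length(reduction) != 1L || is.na(reduction))
    stop("`reduction` must be a single number")
  if (reduction < 0)
    stop("`reduction` must be non-negative")
  reb <- base[[3L]] * (1 - reduction)
  if (reb < -1e-12)
    stop(sprintf(
      "`reduction` = %g drives the REB fraction below zero (max allowed: 1)",
      reduction))
  structure(c(bmr = base[[1L]] + base[[3L]] * reduction,
              soma = base[[2L]],
              reb = max(reb, 0)),
            class = "allocation_profile")
}

#' Allocate one day's granted energy by strict priority
#'
#' Splits the nutrients actually granted to an individual among basal
#' metabolism, somatic growth, and the reproductive energy budget, in that
#' strict priority order. With demands `B = bmr * Q`, `S = soma * Q`,
#' `R = reb * Q`: BMR is paid first; the remainder goes to SOMA, then REB.
#' If the grant does not even cover BMR, the deficit is recorded as
#' `mass_loss` (paid from body mass gram-for-gram); an unmet REB demand has
#' no immediate consequence beyond the reduced REB gain.
#'
#' All arguments are vectorized over individuals.
#'
#' @param Q_demand the day's photosynthetic demand (g).
#' @param granted nutrients actually obtained (g); must satisfy
#'   `0 <= granted <= Q_demand`.
#' @param profile an [allocation_profile()].
#' @return A data frame with columns `consumed`, `bmr_spent`, `soma_gain`,
#'   `reb_gain`, `mass_loss`; `consumed = bmr_spent + soma_gain + reb_gain`
#'   exactly (energy closure).
#' @examples
#' allocate_energy(10, 5, allocation_profile(0))
#' @export
allocate_energy <- function(Q_demand, granted, profile = allocation_profile(0)) {
  if (any(Q_demand < 0) || any(granted < 0))
    stop("`Q_demand` and `granted` must be non-negative")
  if (any(granted > Q_demand + 1e-9))
    stop("`granted` cannot exceed `Q_demand`")
  B <- profile[["bmr"]] * Q_demand
  S <- profile[["soma"]] * Q_demand
  R <- profile[["reb"]] * Q_demand
  bmr_spent <- pmin(granted, B)
  rem <- granted - bmr_spent
  soma_gain <- pmin(rem, S)
  reb_gain <- pmin(rem - soma_gain, R)
  data.frame(consumed = granted,
             bmr_spent = bmr_spent,
             soma_gain = soma_gain,
             reb_gain = reb_gain,
             mass_loss = B - bmr_spent)
}

#' Apply a daily allocation to individuals
#'
#' Updates mass and REB from an [allocate_energy()] result: mass changes by
#' `soma_gain - mass_loss` (floored at zero), REB accumulates `reb_gain`.
#' An individual whose mass reaches zero dies of starvation.
#'
#' @param individuals a data frame with numeric columns `mass` and `reb`
#'   (one row per individual), as used throughout the engine.
#' @param allocation the matching [allocate_energy()] result.
#' @return `individuals` with updated `mass`, `reb` and a logical column
#'   `alive` (`FALSE` for starvation deaths).
#' @export
apply_allocation <- function(individuals, allocation) {
  stopifnot(nrow(individuals) == nrow(allocation))
  m <- individuals$mass + allocation$soma_gain - allocation$mass_loss
  individuals$alive <- m > 0
  individuals$mass <- pmax(m, 0)
  individuals$reb <- individuals$reb + allocation$reb_gain
  individuals
}

#' @export
print.allocation_profile <- function(x, ...) {
  cat(sprintf("<allocation_profile> BMR:SOMA:REB = %g:%g:%g\n",
              100 * x[["bmr"]], 100 * x[["soma"]], 100 * x[["reb"]]))
  invisible(x)
}
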