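#' Age-specific birth rate
#'
#' An individual reproduces at constant intensity `i_b` during its
#' fertility span `[0, x_b)` and not at all afterwards. A non-positive
#' `x_b` means the individual is sterile.
#'
#' @param age Age(s), >= 0.
#' @param x_b End of the fertility span (may be negative: sterile).
#' @param i_b Birth intensity while fertile.
#' @return Numeric vector of birth rates.
#' @export
birth_rate <- function(age, x_b, i_b = 1) {
  if (any(age < 0, na.rm = TRUE)) stop("`age` must be >= 0", call. = FALSE)
  ifelse(x_b > 0 & age < x_b, i_b, 0)
}

#' Age-specific death rate
#'
#' The intrinsic mortality hazard is a step function: 0 before
#' `max(x_d, 0)` and `i_d` after (a negative `x_d` means the hazard is
#' active from birth). Logistic competition adds `c * (n_alive - 1)`:
#' every individual feels the same pressure from all other living
#' individuals, across both lineages.
#'
#' @param age Age(s), >= 0.
#' @param x_d Onset of intrinsic mortality (clamped at 0 when negative).
#' @param i_d Intrinsic death intensity.
#' @param c Logistic competition coefficient.
#' @param n_alive Number of living individuals including the focal one
#'   (>= 1).
#' @return Numeric vector of death rates.
#' @export
death_rate <- function(age, x_d, i_d = 1, c = 0, n_alive = 1) {
  if (any(age < 0, na.rm = TRUE)) stop("`age` must be >= 0", call. = FALSE)
  if (any(n_alive < 1)) stop("`n_alive` must be >= 1", call. = FALSE)
  i_d * (age >= pmax(x_d, 0)) + c * (n_alive - 1)
}

#' Mutate offspring traits
#'
#' At each birth, each gene of the trait pair independently receives,
#' with probability `p`, an additive Gaussian increment of mean 0 and
#' standard deviation `sigma`; otherwise it is copied exactly. The trait
#' space is unbounded: increments are never reflected or clamped.
#'
#' @param traits Data frame with columns `x_b` and `x_d` (one row per
#'   offspring).
#' @param p Per-gene mutation probability.
#' @param sigma Gaussian increment standard deviation.
#' @return A tibble with mutated `x_b`, `x_d` (other columns preserved).
#' @export
mutate_traits <- function(traits, p, sigma) {
  stopifnot(is.data.frame(traits), all(c("x_b", "x_d") %in% names(traits)))
  check_number(p, "p", 0, 1)
  check_number(sigma, "sigma", 0)
  n <- nrow(traits)
  out <- tibble::as_tibble(traits)
  if (n == 0 || p == 0 || sigma == 0) {
    # degenerate kernels copy the parental trait exactly
    return(out)
  }
  hit_b <- stats::runif(n) < p
  out$x_b[hit_b] <- out$x_b[hit_b] + stats::rnorm(sum(hit_b), 0, sigma)
  hit_d <- stats::runif(n) < p
  out$x_d[hit_d] <- out$x_d[hit_d] + stats::rnorm(sum(hit_d), 0, sigma)
  out
}

#' Apply the Lansing transgenerational rule to offspring traits
#'
#' If the rule is enabled and the parent is "physiologically old" --
#' its trait satisfies `x_d < x_b` and its age at reproduction exceeds
#' its own `x_d` -- the offspring's (post-mutation) `x_d` is scaled by
#' `1 - magnitude`. At magnitude 1 the inherited `x_d` is exactly 0,
#' so exact zeros exist in the population. In every other configuration
#' (young parent, menopause-like trait with `x_d >= x_b`, rule disabled)
#' the offspring trait is returned unchanged.
#'
#' @param child Data frame of offspring traits (`x_b`, `x_d`), already
#'   mutated.
#' @param parent Data frame of parental traits (`x_b`, `x_d`), row-aligned
#'   with `child`.
#' @param parent_age Parental age(s) at the birth event, >= 0.
#' @param magnitude Lansing magnitude in `[0, 1]`.
#' @param enabled Whether the rule is active.
#' @return A tibble of adjusted offspring traits.
#' @export
apply_lansing <- function(child, parent, parent_age, magnitude = 1,
                          enabled = TRUE) {
  stopifnot(is.data.frame(child), is.data.frame(parent),
            nrow(child) == nrow(parent))
  if (any(parent_age < 0)) stop("`parent_age` must be >= 0", call. = FALSE)
  check_number(magnitude, "magnitude", 0, 1)
  out <- tibble::as_tibble(child)
  if (!enabled || magnitude == 0 || nrow(out) == 0) return(out)
  old <- parent$x_d < parent$x_b & parent_age > parent$x_d
  out$x_d[old] <- (1 - magnitude) * out$x_d[old]
  out
}
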