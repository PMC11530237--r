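#' Model parameters for the two-gene birth-death model
#'
#' Bundles the demographic intensities, the logistic competition
#' coefficient, the Gaussian mutation kernel and the Lansing-effect rule
#' into a single validated parameter object consumed by [simulate_bd()],
#' the fitness solvers and the experiment drivers.
#'
#' Each individual carries a heritable trait pair `(x_b, x_d)`: `x_b` is
#' the age at which its fertility span ends and `x_d` the age at which its
#' intrinsic mortality hazard switches on. While fertile (age in
#' `[0, x_b)`) an individual gives birth at rate `i_b`; past
#' `max(x_d, 0)` it dies at intrinsic rate `i_d`, plus a competition
#' term `c * (N - 1)` shared by every living individual.
#'
#' @param i_b Birth intensity while fertile (births per unit time), >= 0.
#' @param i_d Intrinsic death intensity past `x_d` (per unit time), >= 0.
#'   Fitness solvers require `i_d > 0`.
#' @param c Logistic competition coefficient, >= 0. Adds `c * (N - 1)` to
#'   every individual's death rate, imposing a carrying capacity.
#' @param p Per-gene mutation probability at birth, in `[0, 1]`. Each gene
#'   mutates independently.
#' @param sigma Standard deviation of the additive Gaussian mutation
#'   increment, >= 0.
#' @param lansing Logical; whether Lansing-capable lineages express the
#'   transgenerational effect.
#' @param magnitude Strength of the Lansing effect in `[0, 1]`: the
#'   offspring of a physiologically old parent (age > parental `x_d`,
#'   with `x_d < x_b`) inherits `x_d` scaled by `1 - magnitude`.
#'   At 1 the inherited `x_d` is exactly 0; at 0 the rule is inert.
#'
#' @return An object of class `bd_params` (a named list).
#' @examples
#' bd_params(i_b = 1, i_d = 1, c = 9e-4, p = 0.1, sigma = 0.05)
#' @export
bd_params <- function(i_b = 1, i_d = 1, c = 0, p = 0, sigma = 0,
                      lansing = FALSE, magnitude = 1) {
  check_number(i_b, "i_b", lower = 0)
  check_number(i_d, "i_d", lower = 0)
  check_number(c, "c", lower = 0)
  check_number(p, "p", lower = 0, upper = 1)
  check_number(sigma, "sigma", lower = 0)
  check_number(magnitude, "magnitude", lower = 0, upper = 1)
  if (!is.logical(lansing) || length(lansing) != 1L || is.na(lansing)) {
    stop("`lansing` must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(i_b = as.numeric(i_b), i_d = as.numeric(i_d), c = as.numeric(c),
         p = as.numeric(p), sigma = as.numeric(sigma), lansing = lansing,
         magnitude = as.numeric(magnitude)),
    class = "bd_params"
  )
}

#' @export
print.bd_params <- function(x, ...) {
  cat("<bd_params>\n")
  cat(sprintf("  intensities : i_b = %g, i_d = %g\n", x$i_b, x$i_d))
  cat(sprintf("  competition : c = %g\n", x$c))
  cat(sprintf("  mutation    : p = %g, sigma = %g\n", x$p, x$sigma))
  cat(sprintf("  lansing     : %s (magnitude %g)\n",
              if (x$lansing) "on" else "off", x$magnitude))
  invisible(x)
}

# single finite number in [lower, upper]; names the offending field
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

lineage_levels <- c("non_lansing", "lansing")

as_lineage <- function(x) {
  x <- as.character(x)
  bad <- !x %in% lineage_levels
  if (any(bad)) {
    stop("`lineage` must be 'lansing' or 'non_lansing'", call. = FALSE)
  }
  x
}
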