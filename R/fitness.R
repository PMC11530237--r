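# Euler-Lotka machinery.
#
# For a fixed trait (x_b, x_d) with intensities (i_b, i_d) the renewal
# (Euler-Lotka) identity is
#
#   i_b * integral_0^{x_b} S(a) exp(-lambda a) da = 1,
#
# with survivorship S(a) = 1 for a < max(x_d, 0) and
# exp(-i_d (a - max(x_d, 0))) after. Both pieces are exponentials, so the
# integral and all its partial derivatives have closed forms; the lambda
# -> 0 and lambda -> -i_d singularities are handled by analytic limits,
# never by numerical perturbation.

# int_0^L exp(-k a) da, stable at k = 0
intexp <- function(k, L) {
  if (L <= 0) return(0)
  if (k == 0) return(L)
  -expm1(-k * L) / k
}

# int_0^L a exp(-k a) da, stable near k = 0
intaexp <- function(k, L) {
  if (L <= 0) return(0)
  x <- k * L
  if (abs(x) < 1e-5) {
    # series of (1 - (1 + x) e^{-x}) / k^2
    return(L^2 / 2 - k * L^3 / 3 + k^2 * L^4 / 8)
  }
  (1 - (1 + x) * exp(-x)) / k^2
}

# renewal residual F(lambda) = i_b * integral - 1 for one trait,
# plus its closed-form partials (used by Newton and by the gradients)
renewal_terms <- function(lambda, x_b, x_d, i_b, i_d) {
  if (x_b <= 0) {
    return(list(F = -1, dF_dlambda = 0, dF_dxb = 0, dF_dxd = 0))
  }
  w <- min(max(x_d, 0), x_b)    # hazard-free part of the fertile window
  g <- x_b - w                  # hazard-exposed part
  I1 <- intexp(lambda, w)
  I2 <- exp(-lambda * w) * intexp(lambda + i_d, g)
  J1 <- intaexp(lambda, w)
  J2 <- exp(-lambda * w) * (intaexp(lambda + i_d, g) + w * intexp(lambda + i_d, g))
  surv_xb <- if (g > 0) exp(-i_d * g) else 1
  list(
    F = i_b * (I1 + I2) - 1,
    dF_dlambda = -i_b * (J1 + J2),
    dF_dxb = i_b * surv_xb * exp(-lambda * x_b),
    # hazard onset only matters strictly inside the window
    dF_dxd = if (x_d > 0 && x_d < x_b) i_b * i_d * I2 else 0
  )
}

#' Renewal-equation residual
#'
#' Evaluates `i_b * integral_0^{x_b} S(a) exp(-lambda * a) da - 1`, the
#' Euler-Lotka mismatch whose unique root in `lambda` is the Malthusian
#' parameter. At `lambda = 0` the value is `R0 - 1` (net reproduction
#' number minus one). Traits with `x_b <= 0` cannot reproduce and return
#' -1 for every `lambda`.
#'
#' @param lambda Candidate growth rate(s).
#' @param x_b,x_d Trait pair (recycled against `lambda`).
#' @param i_b,i_d Demographic intensities; `i_d > 0`.
#' @return Numeric vector of residuals.
#' @export
renewal_residual <- function(lambda, x_b, x_d, i_b = 1, i_d = 1) {
  check_number(i_d, "i_d", lower = 1e-12)
  check_number(i_b, "i_b", lower = 0)
  n <- max(length(lambda), length(x_b), length(x_d))
  lambda <- rep_len(lambda, n); x_b <- rep_len(x_b, n); x_d <- rep_len(x_d, n)
  vapply(seq_len(n), function(i) {
    renewal_terms(lambda[i], x_b[i], x_d[i], i_b, i_d)$F
  }, numeric(1))
}

# Newton root of the renewal residual. F is strictly decreasing and
# convex in lambda, so Newton from any start converges monotonically
# upward; a bisection fallback guards pathological steps.
solve_renewal <- function(x_b, x_d, i_b, i_d,
                          tol = 1e-10, max_iter = 100L) {
  if (x_b <= 0) return(list(lambda = -Inf, residual = -1, iterations = 0L))
  R0 <- renewal_terms(0, x_b, x_d, i_b, i_d)$F + 1
  lambda <- max(0, i_b * (1 - 1 / max(R0, 1 + 1e-12)))
  for (it in seq_len(max_iter)) {
    tm <- renewal_terms(lambda, x_b, x_d, i_b, i_d)
    if (abs(tm$F) < tol) {
      return(list(lambda = lambda, residual = tm$F, iterations = it))
    }
    step <- -tm$F / tm$dF_dlambda
    if (!is.finite(step)) break
    lambda <- lambda + step
    if (!is.finite(lambda)) break
  }
  # bracketing/bisection fallback
  lo <- -i_d + 1e-12; hi <- i_b + 1
  while (renewal_terms(lo, x_b, x_d, i_b, i_d)$F < 0) lo <- lo - (hi - lo)
  for (it2 in seq_len(200L)) {
    mid <- (lo + hi) / 2
    Fm <- renewal_terms(mid, x_b, x_d, i_b, i_d)$F
    if (abs(Fm) < tol || (hi - lo) < 1e-14) {
      return(list(lambda = mid, residual = Fm, iterations = max_iter + it2))
    }
    if (Fm > 0) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "renewal solver failed to converge (last residual %.3e)",
    renewal_terms(lambda, x_b, x_d, i_b, i_d)$F), call. = FALSE)
}

# one-trait Malthusian parameter with branch bookkeeping
malthusian_one <- function(x_b, x_d, i_b, i_d, lineage) {
  if (lineage == "non_lansing" || x_d >= x_b) {
    s <- solve_renewal(x_b, x_d, i_b, i_d)
    branch <- if (lineage == "lansing") "overlapping" else "normal"
    return(list(lambda = s$lambda, residual = s$residual,
                branch = branch, iterations = s$iterations))
  }
  # Lansing genotype below the diagonal: two-type system. "Normal"
  # individuals beget normal offspring only while a < x_d (afterwards
  # their progeny is born with x_d = 0); the x_d = 0 subtree feeds only
  # itself. Long-run growth is the dominant of the two autonomous roots.
  w <- min(max(x_d, 0), x_b)
  sN <- if (w > 0) solve_renewal(w, w, i_b, i_d) else
    list(lambda = -Inf, residual = -1, iterations = 0L)
  sL <- solve_renewal(x_b, 0, i_b, i_d)
  if (sN$lambda >= sL$lambda) {
    list(lambda = sN$lambda, residual = sN$residual,
         branch = "normal", iterations = sN$iterations)
  } else {
    list(lambda = sL$lambda, residual = sL$residual,
         branch = "lansing_subtree", iterations = sL$iterations)
  }
}

#' Malthusian parameter of a trait
#'
#' Computes the asymptotic exponential growth rate lambda (the fitness
#' surrogate) for each trait row, by Newton root-finding of the
#' Euler-Lotka renewal equation in closed piecewise-exponential form.
#'
#' For the `"lansing"` lineage with `x_d < x_b`, the genotype founds a
#' two-type population: physiologically young parents produce copies of
#' themselves, old parents (age > `x_d`) produce offspring with
#' `x_d = 0`, and the `x_d = 0` subtree is self-contained. The returned
#' lambda is the dominant of the two branch roots (`branch` records
#' which); for `x_d >= x_b` the rule never fires and the Lansing value
#' coincides with the non-Lansing one (`branch = "overlapping"`).
#' Non-viable traits return the (non-positive) root of the full
#' equation; sterile traits (`x_b <= 0`) return `-Inf`.
#'
#' @param traits Data frame with columns `x_b`, `x_d`.
#' @param i_b,i_d Intensities; `i_d` must be positive.
#' @param lineage `"non_lansing"` (default) or `"lansing"`.
#' @return The input as a tibble with columns `lambda`, `residual`,
#'   `branch`, `iterations` appended.
#' @examples
#' malthusian(tibble::tibble(x_b = 2.45, x_d = 1.05))
#' malthusian(tibble::tibble(x_b = 2.45, x_d = 1.05), lineage = "lansing")
#' @export
malthusian <- function(traits, i_b = 1, i_d = 1,
                       lineage = c("non_lansing", "lansing")) {
  stopifnot(is.data.frame(traits), all(c("x_b", "x_d") %in% names(traits)))
  check_number(i_d, "i_d", lower = 1e-12)
  check_number(i_b, "i_b", lower = 0)
  lineage <- match.arg(lineage)
  out <- tibble::as_tibble(traits)
  res <- purrr::pmap(list(out$x_b, out$x_d), function(xb, xd) {
    malthusian_one(xb, xd, i_b, i_d, lineage)
  })
  out$lambda <- purrr::map_dbl(res, "lambda")
  out$residual <- purrr::map_dbl(res, "residual")
  out$branch <- purrr::map_chr(res, "branch")
  out$iterations <- purrr::map_int(res, ~ as.integer(.x$iterations))
  out
}

#' Selection gradient of the Malthusian parameter
#'
#' Partial derivatives of lambda with respect to both genes, by implicit
#' differentiation of the renewal equation (closed-form partials divided
#' by the closed-form lambda-derivative). Both components are
#' nonnegative: enlarging the fertility span or delaying the mortality
#' onset never decreases fitness. For the Lansing lineage below the
#' diagonal the gradient is that of the dominant branch (the inactive
#' gene of that branch contributes 0).
#'
#' @inheritParams malthusian
#' @return The input as a tibble with `lambda`, `dlambda_dxb`,
#'   `dlambda_dxd` appended.
#' @export
fitness_gradient <- function(traits, i_b = 1, i_d = 1,
                             lineage = c("non_lansing", "lansing")) {
  stopifnot(is.data.frame(traits), all(c("x_b", "x_d") %in% names(traits)))
  lineage <- match.arg(lineage)
  check_number(i_d, "i_d", lower = 1e-12)
  out <- tibble::as_tibble(traits)
  grads <- purrr::pmap(list(out$x_b, out$x_d), function(xb, xd) {
    if (xb <= 0) stop("gradient undefined for sterile trait (x_b <= 0)",
                      call. = FALSE)
    fit <- malthusian_one(xb, xd, i_b, i_d, lineage)
    if (fit$branch %in% c("normal", "overlapping") &&
        !(lineage == "lansing" && xd < xb)) {
      tm <- renewal_terms(fit$lambda, xb, xd, i_b, i_d)
      return(c(fit$lambda,
               -tm$dF_dxb / tm$dF_dlambda,
               -tm$dF_dxd / tm$dF_dlambda))
    }
    if (fit$branch == "normal") {
      # dominant branch is the truncated normal->normal subsystem: its
      # renewal equation depends on x_d alone (window [0, x_d), no hazard)
      w <- min(max(xd, 0), xb)
      tm <- renewal_terms(fit$lambda, w, w, i_b, i_d)
      c(fit$lambda, 0, -tm$dF_dxb / tm$dF_dlambda)
    } else {
      # x_d = 0 subtree: depends on x_b alone
      tm <- renewal_terms(fit$lambda, xb, 0, i_b, i_d)
      c(fit$lambda, -tm$dF_dxb / tm$dF_dlambda, 0)
    }
  })
  out$lambda <- purrr::map_dbl(grads, 1)
  out$dlambda_dxb <- purrr::map_dbl(grads, 2)
  out$dlambda_dxd <- purrr::map_dbl(grads, 3)
  out
}

#' Fitness landscape over a trait grid
#'
#' Evaluates the Malthusian parameter of both lineages on a rectangular
#' `(x_b, x_d)` grid. Above the diagonal (`x_d >= x_b`) the two surfaces
#' coincide; strictly below it the Lansing surface lies strictly under
#' the non-Lansing one wherever both are viable.
#'
#' @param x_b,x_d Numeric vectors of grid coordinates, or length-2
#'   ranges used with `n` points each.
#' @param n Grid resolution per axis when ranges are given.
#' @param i_b,i_d Intensities.
#' @return A tibble of class `bd_landscape` with columns `x_b`, `x_d`,
#'   `lambda_non_lansing`, `lambda_lansing`.
#' @examples
#' fitness_landscape(c(0.5, 4), c(0.5, 4), n = 11)
#' @export
fitness_landscape <- function(x_b, x_d, n = 25, i_b = 1, i_d = 1) {
  expand_axis <- function(v) {
    if (length(v) == 2) seq(v[1], v[2], length.out = n) else as.numeric(v)
  }
  if (length(x_b) == 0 || length(x_d) == 0) {
    stop("grid ranges must be nonempty", call. = FALSE)
  }
  grid <- tidyr::expand_grid(x_b = expand_axis(x_b), x_d = expand_axis(x_d))
  grid$lambda_non_lansing <-
    malthusian(grid, i_b, i_d, "non_lansing")$lambda
  grid$lambda_lansing <-
    malthusian(grid, i_b, i_d, "lansing")$lambda
  attr(grid, "i_b") <- i_b
  attr(grid, "i_d") <- i_d
  class(grid) <- c("bd_landscape", class(grid))
  grid
}

#' Minimal fertility span compatible with positive growth
#'
#' The net reproduction number is bounded by `i_b * x_b`, so positive
#' growth requires `i_b * x_b > 1`: no trait with `x_b <= 1 / i_b` is
#' viable, whatever `x_d`. At `i_b = 0.01` the threshold is a fertility
#' span of 100 time units.
#'
#' @param i_b Birth intensity, > 0.
#' @return `1 / i_b`.
#' @export
viability_threshold <- function(i_b) {
  if (!is.numeric(i_b) || any(i_b <= 0)) {
    stop("no viable trait exists when `i_b` is not positive", call. = FALSE)
  }
  1 / i_b
}
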