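# Independent oracles used across the suite. They deliberately avoid
# the package's closed forms: survivorship is integrated by adaptive
# quadrature and roots are found by uniroot bisection, so agreement
# with the package's Newton/piecewise-exponential path is a real check.

oracle_survivorship <- function(a, x_d, i_d) {
  ifelse(a < pmax(x_d, 0), 1, exp(-i_d * (a - pmax(x_d, 0))))
}

oracle_residual <- function(lam, x_b, x_d, i_b = 1, i_d = 1) {
  if (x_b <= 0) return(-1)
  i_b * stats::integrate(
    function(a) oracle_survivorship(a, x_d, i_d) * exp(-lam * a),
    0, x_b, rel.tol = 1e-12)$value - 1
}

# bisection root of the renewal identity (lambda < i_b always)
oracle_lambda <- function(x_b, x_d, i_b = 1, i_d = 1) {
  lo <- -i_d + 1e-9
  while (oracle_residual(lo, x_b, x_d, i_b, i_d) < 0) lo <- lo - 1
  stats::uniroot(oracle_residual, c(lo, i_b), x_b = x_b, x_d = x_d,
                 i_b = i_b, i_d = i_d, tol = 1e-12)$root
}

# two-type Lansing growth rate through the oracle root-finder
oracle_lambda_lansing <- function(x_b, x_d, i_b = 1, i_d = 1) {
  if (x_d >= x_b) return(oracle_lambda(x_b, x_d, i_b, i_d))
  w <- min(max(x_d, 0), x_b)
  lam_n <- if (w > 0) oracle_lambda(w, w, i_b, i_d) else -Inf
  max(lam_n, oracle_lambda(x_b, 0, i_b, i_d))
}

# brute-force fine-time-step discretization of the birth-death process
# (no mutation); returns totals and ages at death
oracle_discrete_sim <- function(founders, params, horizon, dt = 0.002) {
  x_b <- founders$x_b
  x_d <- founders$x_d
  age <- -founders$birth_time
  births <- 0L
  death_ages <- numeric(0)
  for (step in seq_len(ceiling(horizon / dt))) {
    n <- length(age)
    if (n == 0) break
    rb <- birth_rate(age, x_b, params$i_b)
    rd <- death_rate(age, x_d, params$i_d, params$c, n)
    b <- stats::runif(n) < rb * dt
    d <- stats::runif(n) < rd * dt
    births <- births + sum(b)
    death_ages <- c(death_ages, age[d])
    nb <- sum(b)
    parent_xb <- x_b[b]
    parent_xd <- x_d[b]
    keep <- !d
    x_b <- c(x_b[keep], parent_xb)
    x_d <- c(x_d[keep], parent_xd)
    age <- c(age[keep] + dt, rep(0, nb))
  }
  list(births = births, deaths = length(death_ages),
       death_ages = death_ages, n_final = length(age))
}
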