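# Independent quadrature oracle for the Rician mean: E|X| for X Rician with
# non-centrality nu and scale sigma, integrating x * f(x) with the density
# written in an overflow-safe form using the exponentially scaled Bessel I0.
rician_mean_quadrature <- function(nu, sigma) {
  integrand <- function(x) {
    z <- x * nu / sigma^2
    x * (x / sigma^2) * exp(-(x - nu)^2 / (2 * sigma^2)) *
      besselI(z, 0, expon.scaled = TRUE)
  }
  upper <- nu + 12 * sigma
  stats::integrate(integrand, 0, upper, rel.tol = 1e-12,
                   subdivisions = 400L)$value
}

# From-scratch 2x2 chi-square (no continuity correction) for the Mood test
chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Brute-force grid search over the bounded (S0, T2) box for the SSR of a
# given model function; used as an oracle for boundary optima and bias signs
grid_best_t2 <- function(te, y, model, s0_grid = seq(0, 2500, length.out = 161),
                         t2_grid = seq(5, 500, length.out = 321)) {
  best <- c(NA, NA); best_ssr <- Inf
  for (t2 in t2_grid) {
    decay <- exp(-te / t2)
    for (s0 in s0_grid) {
      r <- model(s0, decay) - y
      ssr <- sum(r * r)
      if (ssr < best_ssr) { best_ssr <- ssr; best <- c(s0, t2) }
    }
  }
  list(s0 = best[1], t2 = best[2], ssr = best_ssr)
}
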