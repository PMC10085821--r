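# Independent oracles used to cross-check the package's estimators.

# Exhaustive grid minimization of the pinball objective for a single-animal
# design (two free parameters: offset beta, slope alpha on z = 1/(t+1)).
grid_pinball_fit <- function(t_h, y, tau, beta_lim = c(-5, 5),
                             alpha_lim = c(-6, 6), step = 0.01) {
  z <- 1 / (t_h + 1)
  u <- log(y)
  betas <- seq(beta_lim[1], beta_lim[2], by = step)
  alphas <- seq(alpha_lim[1], alpha_lim[2], by = step)
  best <- list(obj = Inf)
  for (a in alphas) {
    r <- outer(u - a * z, betas, "-")
    obj <- colSums(r * (tau - (r < 0)))
    k <- which.min(obj)
    if (obj[k] < best$obj) best <- list(beta = betas[k], alpha = a, obj = obj[k])
  }
  best
}

pinball_objective <- function(t_h, y, tau, beta, alpha) {
  r <- log(y) - beta - alpha / (t_h + 1)
  sum(r * (tau - (r < 0)))
}

# Independent two-phase OLS segmented-regression oracle: for every interior
# candidate, fit with stats::lm (a different code path from the package's
# .lm.fit grid) and return the SSR-minimizing breakpoint.
twophase_ols_oracle <- function(x, y, min_seg = 2) {
  ux <- unique(x)
  cand <- ux[vapply(ux, function(p) {
    sum(x < p) >= min_seg && sum(x > p) >= min_seg
  }, TRUE)]
  best <- list(ssr = Inf)
  for (p in cand) {
    m <- lm(y ~ x + I(pmax(x - p, 0)))
    ssr <- sum(resid(m)^2)
    if (ssr < best$ssr - 1e-12) {
      best <- list(psi = p, ssr = ssr, coef = unname(coef(m)))
    }
  }
  best
}

# Small labelled entropy pipeline used by several breakpoint tests.
step_label_series <- function(seed, t_star = 12, n_animals = 10,
                              duration_h = 100, tN = 40, T_h = 80, ...) {
  sc <- dive_scenario(n_animals = n_animals, duration_h = duration_h,
                      t_star = t_star, ...)
  dv <- simulate_dives(sc, seed = seed)
  h <- hourly_distributions(dv$dives)
  sch <- build_schedule(dv$record_ends_h, tN)
  ror <- region_of_recovery(h, sch, T_h)
  es <- entropy_series(h, reference_distribution(h, sch))
  label_series(es[es$hour <= T_h, ], ror)
}

null_label_series <- function(seed, ...) {
  step_label_series(seed, t_star = 0, pi0 = c(0.4, 0.35, 0.25),
                    pi_base = c(0.4, 0.35, 0.25), ...)
}
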