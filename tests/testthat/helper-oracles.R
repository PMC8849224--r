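# Independent oracles used across the suite. These never call the code
# paths they check.

# numerical ODE solution of the linear cascade gut -> parent -> metabolite
ode_oracle <- function(times, dose, params) {
  rhs <- function(t, y, p) {
    list(c(-p$ka * y[1],
           p$ka * y[1] - p$ke * y[2],
           p$fm * p$ke * y[2] - p$km * y[3]))
  }
  out <- deSolve::lsoda(y = c(G = dose, P = 0, M = 0),
                        times = c(0, times), func = rhs, parms = params,
                        rtol = 1e-10, atol = 1e-12)
  out <- out[-1, , drop = FALSE]
  list(parent = out[, "P"] / params$v_parent,
       metab = out[, "M"] / params$v_metab)
}

# closed-form normal-equations OLS of y on x (slope, se, two-sided p)
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# brute-force step-up FDR adjustment: q_(i) = min_{j >= i} p_(j) * m / j
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

random_params <- function() {
  pk_params(ka = runif(1, 0.5, 6),
            ke = runif(1, 0.05, 0.6),
            km = runif(1, 0.03, 0.4),
            fm = runif(1, 0.3, 1),
            v_parent = runif(1, 20, 60),
            v_metab = runif(1, 10, 40))
}
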