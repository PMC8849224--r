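# Closed-form solutions of the linear gut -> parent -> metabolite cascade.
#
# The concentration terms are inverse Laplace transforms of
# 1 / prod_i (s + lambda_i). When rate constants (nearly) coincide the
# generic partial-fraction form is numerically unstable, so the analytic
# repeated-root limits are evaluated instead. Rates are treated as equal
# when they differ by less than `tol` in relative terms.

RATE_TOL <- 1e-8

near_equal <- function(a, b, tol = RATE_TOL) {
  abs(a - b) <= tol * max(abs(a), abs(b))
}

# inverse Laplace of 1/((s+l1)(s+l2)), vectorised over t (t >= 0)
bateman2 <- function(t, l1, l2, tol = RATE_TOL) {
  if (near_equal(l1, l2, tol)) {
    lb <- (l1 + l2) / 2
    t * exp(-lb * t)
  } else {
    (exp(-l1 * t) - exp(-l2 * t)) / (l2 - l1)
  }
}

# inverse Laplace of 1/((s+l1)(s+l2)(s+l3)), with repeated-root limits
bateman3 <- function(t, l1, l2, l3, tol = RATE_TOL) {
  e12 <- near_equal(l1, l2, tol)
  e13 <- near_equal(l1, l3, tol)
  e23 <- near_equal(l2, l3, tol)
  if (e12 && e13 && e23) {
    mu <- (l1 + l2 + l3) / 3
    return(t^2 / 2 * exp(-mu * t))
  }
  if (e12 || e13 || e23) {
    if (e12) { mu <- (l1 + l2) / 2; la <- l3 }
    else if (e13) { mu <- (l1 + l3) / 2; la <- l2 }
    else { mu <- (l2 + l3) / 2; la <- l1 }
    d <- mu - la
    return(exp(-la * t) / d^2 - exp(-mu * t) / d^2 + t * exp(-mu * t) / (la - mu))
  }
  exp(-l1 * t) / ((l2 - l1) * (l3 - l1)) +
    exp(-l2 * t) / ((l1 - l2) * (l3 - l2)) +
    exp(-l3 * t) / ((l1 - l3) * (l2 - l3))
}

#' Single-dose parent (caffeine) concentration
#'
#' Salivary parent concentration after one oral dose under first-order
#' absorption and elimination:
#' \deqn{C(t) = \frac{D}{V_p} \frac{k_a}{k_a - k_e}
#'   \left(e^{-k_e t} - e^{-k_a t}\right)}
#' with the analytic limit \eqn{(D/V_p)\, k_a t\, e^{-k_a t}} when
#' \eqn{k_a \approx k_e}. Times at or before the dose return 0.
#'
#' @param t Time since the dose (h); vectorised.
#' @param dose Dose (mg), a single non-negative number.
#' @param params A [pk_params()] object.
#' @return Concentration (ug/ml), same length as `t`.
#' @seealso [metabolite_conc()], [simulate_profiles()]
#' @examples
#' parent_conc(seq(0, 12, by = 2), dose = 150, params = pk_params())
#' @export
parent_conc <- function(t, dose, params = pk_params()) {
  params <- as_pk_params(params)
  stopifnot(is.numeric(t), is.numeric(dose), length(dose) == 1L, dose >= 0)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    out[pos] <- dose * params$ka / params$v_parent *
      bateman2(t[pos], params$ka, params$ke)
  }
  out
}

#' Single-dose metabolite (paraxanthine) concentration
#'
#' Salivary metabolite concentration after one oral dose of the parent: the
#' triple-exponential solution of the linear cascade gut -> parent ->
#' metabolite, in which a fraction `fm` of eliminated parent is converted:
#' \deqn{C_m(t) = \frac{f_m D\, k_a k_e}{V_m} \sum_{i}
#'   \frac{e^{-\lambda_i t}}{\prod_{j \ne i} (\lambda_j - \lambda_i)}}
#' over \eqn{\lambda \in \{k_a, k_e, k_m\}}. Repeated-root limits are used
#' when any two rate constants nearly coincide. The terminal decline is
#' governed by the slower of \eqn{k_e} and \eqn{k_m} (flip-flop kinetics).
#'
#' @inheritParams parent_conc
#' @return Concentration (ug/ml), same length as `t`; non-negative.
#' @examples
#' metabolite_conc(seq(0, 24, by = 4), dose = 150, params = pk_params())
#' @export
metabolite_conc <- function(t, dose, params = pk_params()) {
  params <- as_pk_params(params)
  stopifnot(is.numeric(t), is.numeric(dose), length(dose) == 1L, dose >= 0)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    out[pos] <- params$fm * dose * params$ka * params$ke / params$v_metab *
      bateman3(t[pos], params$ka, params$ke, params$km)
  }
  pmax(out, 0)
}
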