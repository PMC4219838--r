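#' Mean-field states
#'
#' On a complete graph the local concentration of adopted agents equals the
#' global one, so the dynamics close on one or two scalar concentrations and
#' the model admits deterministic evolution equations (the mean-field
#' approach).  A mean-field state carries the concentrations — `(c_I, c_C)`
#' for the person variant (adopted independents / adopted conformists, both
#' relative to the whole system size N), a single `c` for the situation
#' variant — together with the parameters `(p, f, q)` and the
#' elementary-step scale `1/n`.
#'
#' Invariant boxes: person `0 <= c_I <= p`, `0 <= c_C <= 1 - p`; situation
#' `0 <= c <= 1`.
#'
#' @param c_I,c_C,c concentrations (see above).
#' @param p,f,q model parameters as in [model_config()].
#' @param n step scale: one elementary step advances time by `1/n`.
#' @return an object of class `"qv_mfstate"`.
#' @export
mf_state_person <- function(c_I, c_C, p, f, q = 4L, n = 1000L) {
  st <- structure(list(variant = "person", c_I = c_I, c_C = c_C,
                       p = p, f = f, q = as.integer(q), n = n),
                  class = "qv_mfstate")
  validate_mf_state(st)
}

#' @rdname mf_state_person
#' @export
mf_state_situation <- function(c, p, f, q = 4L, n = 1000L) {
  st <- structure(list(variant = "situation", c = c,
                       p = p, f = f, q = as.integer(q), n = n),
                  class = "qv_mfstate")
  validate_mf_state(st)
}

validate_mf_state <- function(st) {
  eps <- 1e-12
  if (st$p < 0 || st$p > 1 || st$f < 0 || st$f > 1 || st$q < 1)
    stop("domain error: invalid parameters (need p, f in [0,1], q >= 1)")
  if (st$variant == "person") {
    if (st$c_I < -eps || st$c_I > st$p + eps ||
        st$c_C < -eps || st$c_C > 1 - st$p + eps)
      stop("domain error: person state outside 0 <= c_I <= p, 0 <= c_C <= 1-p")
  } else {
    if (st$c < -eps || st$c > 1 + eps)
      stop("domain error: situation state outside 0 <= c <= 1")
  }
  st
}

#' @export
print.qv_mfstate <- function(x, ...) {
  if (x$variant == "person")
    cat(sprintf("<qv_mfstate person> c_I=%.6g c_C=%.6g (c=%.6g)  p=%g f=%g q=%d\n",
                x$c_I, x$c_C, x$c_I + x$c_C, x$p, x$f, x$q))
  else
    cat(sprintf("<qv_mfstate situation> c=%.6g  p=%g f=%g q=%d\n",
                x$c, x$p, x$f, x$q))
  invisible(x)
}

#' Mean-field drift (per unit time)
#'
#' The expected change of the concentrations per elementary step, multiplied
#' by N.  Person variant (derived by bookkeeping the gain/loss of adopted
#' independents and adopted conformists):
#' \deqn{\dot c_I = f\,[(p - c_I) - c_I], \qquad
#'       \dot c_C = (1 - p - c_C)\,c^q - c_C\,(1 - c)^q,\quad c = c_I + c_C.}
#' Situation variant:
#' \deqn{\dot c = p f (1 - 2c) + (1 - p)\,[(1 - c)\,c^q - c\,(1 - c)^q].}
#' The `c^q` terms are the large-N approximation of the exact unanimity
#' probability, see [group_unanimity_prob()].
#'
#' @param state a `qv_mfstate`.
#' @return named numeric vector: `c(c_I = , c_C = )` for person, `c(c = )`
#'   for situation.
#' @export
mf_drift <- function(state) {
  q <- state$q; p <- state$p; f <- state$f
  if (state$variant == "person") {
    cc <- state$c_I + state$c_C
    c(c_I = f * ((p - state$c_I) - state$c_I),
      c_C = (1 - p - state$c_C) * cc^q - state$c_C * (1 - cc)^q)
  } else {
    cc <- state$c
    c(c = p * f * (1 - 2 * cc) +
        (1 - p) * ((1 - cc) * cc^q - cc * (1 - cc)^q))
  }
}

#' One mean-field elementary step
#'
#' Advances the recursion by one elementary step of size `inv_n`
#' (state + inv_n * drift).  `mf_step_person()` requires a person state,
#' `mf_step_situation()` a situation state.
#'
#' @param state a `qv_mfstate` of the matching variant.
#' @param inv_n step size; defaults to `1/state$n`.
#' @return the updated `qv_mfstate`.
#' @export
mf_step_person <- function(state, inv_n = 1 / state$n) {
  stopifnot(inherits(state, "qv_mfstate"), state$variant == "person")
  validate_mf_state(state)
  d <- mf_drift(state)
  state$c_I <- state$c_I + inv_n * d[["c_I"]]
  state$c_C <- state$c_C + inv_n * d[["c_C"]]
  state
}

#' @rdname mf_step_person
#' @export
mf_step_situation <- function(state, inv_n = 1 / state$n) {
  stopifnot(inherits(state, "qv_mfstate"), state$variant == "situation")
  validate_mf_state(state)
  d <- mf_drift(state)
  state$c <- state$c + inv_n * d[["c"]]
  state
}

#' Probability that a q-group is unanimously adopted
#'
#' Probability that `q` agents drawn without replacement from the
#' `n_total - 1` agents other than the (unadopted) target are all adopted.
#' `mode = "exact"` evaluates the finite-N product
#' \eqn{\prod_{k=0}^{q-1} (n_{up} - k) / (n_{total} - 1 - k)};
#' `mode = "approx"` the large-N power \eqn{(n_{up}/n_{total})^q} used by
#' the mean-field recursions.
#'
#' @param n_up number of adopted agents.
#' @param n_total system size (> q).
#' @param q group size.
#' @param mode `"exact"` or `"approx"`.
#' @return a probability.
#' @export
#' @examples
#' group_unanimity_prob(4, 5, 4, "exact")   # 1: the four others are adopted
#' group_unanimity_prob(4, 5, 4, "approx")  # 0.8^4
group_unanimity_prob <- function(n_up, n_total, q = 4L,
                                 mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  if (q >= n_total) stop("invalid: need n_total > q")
  if (n_up < 0 || n_up > n_total) stop("invalid: need 0 <= n_up <= n_total")
  if (mode == "approx") return((n_up / n_total)^q)
  k <- seq_len(q) - 1
  prod(pmax(n_up - k, 0) / (n_total - 1 - k))
}

mf_initial <- function(variant, p, f, q, c0) {
  # scalar c0 is split so both subpopulations start at the same adoption
  # fraction: c_I0 = p*c0, c_C0 = (1-p)*c0 (c0 = 0, 1/2, 1 map onto the
  # all-down, symmetric and all-up states respectively)
  if (variant == "person") c(p * c0, (1 - p) * c0) else c(c0, 0)
}

mf_iterate <- function(variant, p, f, q, c0, n, tol, max_iter) {
  init <- mf_initial(variant, p, f, q, c0)
  vcode <- if (variant == "person") 0L else 1L
  res <- cpp_mf_iterate(vcode, p, f, as.integer(q), init[1], init[2],
                        1 / n, tol, max_iter)
  if (variant == "person")
    list(c_I = res$c_I, c_C = res$c_C, c_star = res$c_I + res$c_C,
         iterations = res$iterations, converged = res$converged)
  else
    list(c_I = NA_real_, c_C = NA_real_, c_star = res$c_I,
         iterations = res$iterations, converged = res$converged)
}

#' Stationary state of the mean-field recursion
#'
#' Iterates the elementary-step map of the requested variant from `c0`
#' until every drift component falls below `tol` (drift is measured per
#' unit time, i.e. N times the per-step change).  From `c0 = 0` this
#' reaches the lower stable branch that the all-down Monte Carlo start
#' converges to.  For the person variant the scalar start is split as
#' `c_I0 = p * c0`, `c_C0 = (1 - p) * c0`.
#'
#' Non-convergence within `max_iter` (expected only in a narrow window
#' around the critical point, where relaxation times diverge) raises an
#' error of class `"qv_nonconvergence"` carrying the last state in
#' `condition$data`.
#'
#' @param variant `"person"` or `"situation"`.
#' @param p,f,q model parameters.
#' @param c0 scalar initial concentration in \[0, 1\].
#' @param n step scale N (default 1000).
#' @param tol drift tolerance (default 1e-8).
#' @param max_iter iteration cap (default 5e6).
#' @return list with `c_star`, `c_I`, `c_C` (`NA` for situation),
#'   `iterations`, `converged`, `stable` (local stability of the reached
#'   fixed point, see Details), and the call parameters.
#' @details Stability is classified numerically: the Jacobian of the drift
#'   at the fixed point is estimated by central differences (h = 1e-6) and
#'   the point is stable when every eigenvalue has negative real part.
#' @export
#' @examples
#' mf_stationary("situation", p = 0.5, f = 0.5, c0 = 0)$c_star  # 1/2
mf_stationary <- function(variant = c("person", "situation"), p, f, q = 4L,
                          c0 = 0, n = 1000L, tol = 1e-8, max_iter = 5e6) {
  variant <- match.arg(variant)
  if (c0 < 0 || c0 > 1) stop("domain error: c0 must lie in [0, 1]")
  if (p < 0 || p > 1 || f < 0 || f > 1) stop("domain error: p, f in [0, 1]")
  res <- mf_iterate(variant, p, f, q, c0, n, tol, max_iter)
  if (!res$converged) {
    cond <- structure(
      class = c("qv_nonconvergence", "error", "condition"),
      list(message = sprintf(
             "mean-field iteration did not converge in %g steps (variant=%s, p=%g, f=%g, c reached %g); expected only near the critical point",
             max_iter, variant, p, f, res$c_star),
           call = sys.call(-1), data = res))
    stop(cond)
  }
  res$stable <- mf_is_stable(variant, p, f, q, res)
  c(res, list(variant = variant, p = p, f = f, q = as.integer(q), n = n))
}

mf_drift_at <- function(variant, p, f, q, x) {
  if (variant == "person") {
    cc <- x[1] + x[2]
    c(f * ((p - x[1]) - x[1]),
      (1 - p - x[2]) * cc^q - x[2] * (1 - cc)^q)
  } else {
    cc <- x[1]
    p * f * (1 - 2 * cc) + (1 - p) * ((1 - cc) * cc^q - cc * (1 - cc)^q)
  }
}

# Numeric Jacobian of the drift (central differences) and stability flag.
mf_is_stable <- function(variant, p, f, q, res, h = 1e-6) {
  x <- if (variant == "person") c(res$c_I, res$c_C) else res$c_star
  k <- length(x)
  jac <- matrix(0, k, k)
  for (j in seq_len(k)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    jac[, j] <- (mf_drift_at(variant, p, f, q, xp) -
                 mf_drift_at(variant, p, f, q, xm)) / (2 * h)
  }
  all(Re(eigen(jac, only.values = TRUE)$values) < 0)
}

#' Critical independence level
#'
#' The smallest `p` at which the symmetric (status-quo) state `c = 1/2`
#' becomes stable, computed by linear stability: the derivative of the
#' one-step map at the symmetric fixed point is estimated by a central
#' difference (h = 1e-6) and its root in `p` located by bisection
#' (`uniroot`, tolerance 1e-12).  For the person variant the governing mode
#' is the conformist one (the independent concentration relaxes to `p/2`
#' autonomously at rate `2f`), so the result does not depend on `f`; for
#' the situation variant it does.  Closed forms recovered numerically:
#' person `p* = 1 - 1/q`; situation `p* = A / (2f + A)` with
#' `A = (q - 1) / 2^(q-1)`.
#'
#' @param variant `"person"` or `"situation"`.
#' @param f flexibility; the situation variant requires `f > 0` (at `f = 0`
#'   the dynamics is frozen and no transition exists).
#' @param q group size (>= 2).
#' @return the critical level `p*` in (0, 1).
#' @export
#' @examples
#' critical_p("person", f = 0.5)           # 0.75 for q = 4
#' critical_p("situation", f = 0.5)        # 3/11
critical_p <- function(variant = c("person", "situation"), f, q = 4L) {
  variant <- match.arg(variant)
  q <- as.integer(q)
  if (q < 2L) stop("invalid: critical-point analysis needs q >= 2")
  if (f < 0 || f > 1) stop("domain error: f in [0, 1]")
  if (variant == "situation" && f == 0)
    stop("undefined: the situation variant with f = 0 is frozen, ",
         "no phase transition exists")
  h <- 1e-6
  slope <- if (variant == "person") {
    function(p) {
      cs <- (1 - p) / 2  # symmetric point, c_I at its fixed value p/2
      (mf_drift_at("person", p, f, q, c((p) / 2, cs + h))[2] -
       mf_drift_at("person", p, f, q, c((p) / 2, cs - h))[2]) / (2 * h)
    }
  } else {
    function(p) {
      (mf_drift_at("situation", p, f, q, 0.5 + h) -
       mf_drift_at("situation", p, f, q, 0.5 - h)) / (2 * h)
    }
  }
  stats::uniroot(slope, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Bifurcation-scan estimate of the critical point
#'
#' Independent numeric oracle for [critical_p()]: classifies the stability
#' of the symmetric state by actually iterating the recursion from a small
#' perturbation `c = 1/2 - eps` (person: `c_C = (1-p)/2 - eps` with
#' `c_I = p/2`) for a fixed number of steps and checking whether the
#' perturbation shrank; the stability boundary is then located by bisection
#' in `p` down to `resolution`.
#'
#' @inheritParams critical_p
#' @param resolution bisection stopping width in `p` (default 1e-3).
#' @param n step scale (default 1000).
#' @param eps perturbation size (default 1e-3).
#' @param k_iter iterations per classification (default `200 * n`).
#' @return estimate of `p*` accurate to `resolution`.
#' @export
critical_p_scan <- function(variant = c("person", "situation"), f, q = 4L,
                            resolution = 1e-3, n = 1000L, eps = 1e-3,
                            k_iter = 200 * n) {
  variant <- match.arg(variant)
  if (variant == "situation" && f == 0)
    stop("undefined: the situation variant with f = 0 is frozen")
  vcode <- if (variant == "person") 0L else 1L
  symmetric_stable <- function(p) {
    if (variant == "person") {
      start <- c(p / 2, (1 - p) / 2 - eps)
      res <- cpp_mf_iterate(vcode, p, f, as.integer(q), start[1], start[2],
                            1 / n, -1, k_iter)
      abs(res$c_C - (1 - p) / 2) < eps
    } else {
      res <- cpp_mf_iterate(vcode, p, f, as.integer(q), 0.5 - eps, 0,
                            1 / n, -1, k_iter)
      abs(res$c_I - 0.5) < eps
    }
  }
  lo <- 0; hi <- 1 - 1e-6
  if (!symmetric_stable(hi)) stop("scan failed: symmetric state unstable at p ~ 1")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (symmetric_stable(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Bifurcation diagram of the mean-field recursion
#'
#' For every `p` in `p_grid` and every start `c0` in `c0_grid`, iterates
#' the recursion to its fixed point and labels the reached point
#' stable/unstable (numeric Jacobian, as in [mf_stationary()]).  Cells that
#' fail to converge within `max_iter` (a narrow window around the critical
#' point) are kept with `converged = FALSE` rather than dropped.
#'
#' @inheritParams mf_stationary
#' @param p_grid numeric vector of independence levels in \[0, 1\].
#' @param c0_grid starting concentrations (default `c(0, 0.5, 1)`).
#' @return a `data.frame` with columns `variant, q, f, p, c0, c_star,
#'   stable, iterations, converged` (`stable` is 1/0, `NA` when not
#'   converged).
#' @export
mf_bifurcation <- function(variant = c("person", "situation"), f, q = 4L,
                           p_grid, c0_grid = c(0, 0.5, 1), n = 1000L,
                           tol = 1e-8, max_iter = 5e6) {
  variant <- match.arg(variant)
  stopifnot(length(p_grid) >= 1, all(p_grid >= 0 & p_grid <= 1))
  grid <- expand.grid(c0 = c0_grid, p = p_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$p[i]; c0 <- grid$c0[i]
    res <- mf_iterate(variant, p, f, q, c0, n, tol, max_iter)
    data.frame(variant = variant, q = as.integer(q), f = f, p = p, c0 = c0,
               c_star = res$c_star,
               stable = if (res$converged)
                 as.integer(mf_is_stable(variant, p, f, q, res)) else NA_integer_,
               iterations = res$iterations, converged = res$converged)
  })
  do.call(rbind, rows)
}
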