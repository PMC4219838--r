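test_that("unanimity probability: exact product and c^q approximation", {
  # n_up = 4 of n_total = 5: the four non-target agents are exactly the
  # adopted ones, so a unanimous adopted group is certain
  expect_equal(group_unanimity_prob(4, 5, 4, "exact"), 1)
  expect_equal(group_unanimity_prob(4, 5, 4, "approx"), 0.8^4)
  expect_equal(group_unanimity_prob(0, 5, 4, "exact"), 0)
  expect_error(group_unanimity_prob(2, 4, 4), "invalid")
  expect_error(group_unanimity_prob(9, 5, 4), "invalid")

  # exact -> approx as n_total grows at fixed c; the relative error scales
  # like q(q-1)(1/c - 1)/(2 n), so at n = 1000 it is below 1% for c = 0.5
  # but NOT for c = 0.05 (where ~11% remains; it needs n ~ 1e5 to drop
  # below 1%)
  rel_err <- function(c, n) {
    ex <- group_unanimity_prob(round(c * n), n, 4, "exact")
    ap <- group_unanimity_prob(round(c * n), n, 4, "approx")
    abs(ap - ex) / ex
  }
  expect_lt(rel_err(0.5, 1000), 0.01)
  expect_gt(rel_err(0.05, 1000), 0.05)   # the coarse regime is real
  expect_lt(rel_err(0.05, 1e5), 0.01)
  expect_lt(rel_err(0.05, 1e5), rel_err(0.05, 1e4))
})

test_that("mean-field steps match direct substitution of the recursions", {
  # person, all-down start: only the independent gain term is active
  st <- mf_state_person(0, 0, p = 0.2, f = 0.5, n = 100)
  st1 <- mf_step_person(st)
  expect_equal(st1$c_I, 0.5 * 0.2 / 100)   # = 0.001
  expect_equal(st1$c_C, 0)

  # situation, all-down start
  st <- mf_state_situation(0, p = 0.1, f = 0.5, n = 100)
  expect_equal(mf_step_situation(st)$c, 0.1 * 0.5 / 100)  # = 5e-4

  # situation f = 0 from all-down is absorbing
  st <- mf_state_situation(0, p = 0.3, f = 0, n = 100)
  expect_equal(mf_step_situation(st)$c, 0)

  # constructed stationary point: both brackets vanish
  p <- 0.3; f <- 0.7
  cC <- stats::uniroot(function(x) {
    cc <- p / 2 + x
    (1 - p - x) * cc^4 - x * (1 - cc)^4
  }, c(0, (1 - p) / 2 - 1e-9), tol = 1e-14)$root
  st <- mf_state_person(p / 2, cC, p = p, f = f)
  d <- mf_drift(st)
  expect_lt(max(abs(d)), 1e-10)

  # c = 1/2 is a fixed point of the situation recursion by symmetry
  st <- mf_state_situation(0.5, p = 0.37, f = 0.61)
  expect_equal(mf_drift(st)[["c"]], 0)

  # states outside the invariant box are rejected
  expect_error(mf_state_person(0.4, 0.2, p = 0.3, f = 0.5), "domain error")
  expect_error(mf_state_situation(1.2, p = 0.3, f = 0.5), "domain error")
})

test_that("one mean-field step equals the one-step Monte Carlo average", {
  # brute-force oracle: average the concentration change over many single
  # elementary steps from a fixed all-down society on a complete graph
  n <- 100; reps <- 1e5

  cfg <- model_config("person", n, p = 0.2, f = 0.5)
  set.seed(21)
  soc <- init_society(cfg)
  hits <- 0L
  for (i in seq_len(reps)) {
    r <- elementary_step(soc)
    if (r$event$changed) hits <- hits + 1L  # all changes are c_I gains here
  }
  mc_delta <- hits / reps / n
  mf_delta <- mf_step_person(mf_state_person(0, 0, 0.2, 0.5, n = n))$c_I
  se <- sqrt(0.1 * 0.9 / reps) / n
  expect_lt(abs(mc_delta - mf_delta), 5 * se)

  cfg <- model_config("situation", n, p = 0.1, f = 0.5)
  set.seed(22)
  soc <- init_society(cfg)
  hits <- 0L
  for (i in seq_len(reps)) {
    r <- elementary_step(soc)
    if (r$event$changed) hits <- hits + 1L
  }
  mc_delta <- hits / reps / n
  mf_delta <- mf_step_situation(mf_state_situation(0, 0.1, 0.5, n = n))$c
  se <- sqrt(0.05 * 0.95 / reps) / n
  expect_lt(abs(mc_delta - mf_delta), 5 * se)
})

test_that("stationary states: closed-form anchors", {
  # no independence drive: the all-down state is absorbing
  for (v in c("person", "situation"))
    expect_equal(mf_stationary(v, p = 0, f = 0.5, c0 = 0)$c_star, 0)

  # person, p = 1: c_I* = p/2 = 1/2 and no conformists exist
  res <- mf_stationary("person", p = 1, f = 0.3, c0 = 0)
  expect_equal(res$c_star, 0.5, tolerance = 1e-7)
  expect_equal(res$c_C, 0)

  # situation above the critical point: status quo c* = 1/2
  res <- mf_stationary("situation", p = 0.5, f = 0.5, c0 = 0)
  expect_equal(res$c_star, 0.5, tolerance = 1e-6)
  expect_true(res$stable)

  # c_I* = p/2 for every f > 0 (exact algebraic identity)
  for (f in c(0.2, 0.5, 1)) for (p in c(0.3, 0.6)) {
    res <- mf_stationary("person", p = p, f = f, c0 = 0,
                         tol = 1e-13, max_iter = 2e6)
    expect_lt(abs(res$c_I - p / 2), 1e-12)
  }
})

test_that("near-critical non-convergence is reported, not hidden", {
  p_star <- critical_p("situation", f = 0.5)
  err <- tryCatch(
    mf_stationary("situation", p = p_star, f = 0.5, c0 = 0, max_iter = 1e4),
    error = function(e) e)
  expect_s3_class(err, "qv_nonconvergence")
  expect_true(is.list(err$data))
  expect_true(err$data$c_star > 0 && err$data$c_star < 0.5)
})

test_that("concentrations stay inside their invariant boxes under iteration", {
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(1); f <- runif(1)
    st <- mf_state_person(runif(1, 0, p), runif(1, 0, 1 - p), p, f, n = 200)
    for (i in 1:2000) st <- mf_step_person(st)
    expect_true(st$c_I >= 0 && st$c_I <= p && st$c_C >= 0 && st$c_C <= 1 - p)
    ss <- mf_state_situation(runif(1), p, f, n = 200)
    for (i in 1:2000) ss <- mf_step_situation(ss)
    expect_true(ss$c >= 0 && ss$c <= 1)
  }
})

test_that("the recursions have the up/down relabelling symmetry", {
  set.seed(32)
  for (rep in 1:50) {
    p <- runif(1); f <- runif(1); q <- sample(2:6, 1)
    cc <- runif(1)
    d <- mf_drift(mf_state_situation(cc, p, f, q))
    dm <- mf_drift(mf_state_situation(1 - cc, p, f, q))
    expect_equal(unname(dm), -unname(d), tolerance = 1e-12)

    cI <- runif(1, 0, p); cC <- runif(1, 0, 1 - p)
    d <- mf_drift(mf_state_person(cI, cC, p, f, q))
    dm <- mf_drift(mf_state_person(p - cI, (1 - p) - cC, p, f, q))
    expect_equal(unname(dm), -unname(d), tolerance = 1e-12)
  }
})

test_that("critical points match the closed forms and the scan oracle", {
  # person: p* = 1 - 1/q, free of f
  for (f in c(0.2, 0.5, 0.8))
    expect_equal(critical_p("person", f, q = 4), 0.75, tolerance = 1e-8)
  expect_equal(critical_p("person", 0.5, q = 3), 2 / 3, tolerance = 1e-8)

  # situation: p* = A / (2f + A), A = (q-1)/2^(q-1)
  A4 <- 3 / 8
  for (f in c(0.2, 0.5, 0.8))
    expect_equal(critical_p("situation", f, q = 4), A4 / (2 * f + A4),
                 tolerance = 1e-8)
  expect_equal(critical_p("situation", 0.5, q = 4), 3 / 11, tolerance = 1e-8)
  A3 <- 2 / 4
  expect_equal(critical_p("situation", 0.5, q = 3), A3 / (1 + A3),
               tolerance = 1e-8)

  # p*(f) strictly decreasing in f for the situation variant
  ps <- vapply(seq(0.1, 1, by = 0.1),
               function(f) critical_p("situation", f), numeric(1))
  expect_true(all(diff(ps) < 0))

  # frozen situation dynamics has no transition
  expect_error(critical_p("situation", f = 0), "undefined")
  expect_error(critical_p_scan("situation", f = 0), "undefined")

  # independent bifurcation-scan oracle agrees to its resolution
  expect_lt(abs(critical_p_scan("person", 0.5) - 0.75), 1e-3)
  expect_lt(abs(critical_p_scan("situation", 0.5) - 3 / 11), 1e-3)
  expect_lt(abs(critical_p_scan("situation", 0.2) - A4 / (0.4 + A4)), 1e-3)
})

test_that("bifurcation tables: f matters only in the situation variant", {
  p_grid <- c(0.05, 0.2, 0.4, 0.6, 0.85, 0.95)
  ba <- mf_bifurcation("person", f = 0.2, p_grid = p_grid)
  bb <- mf_bifurcation("person", f = 0.8, p_grid = p_grid)
  expect_true(all(ba$converged) && all(bb$converged))
  expect_lt(max(abs(ba$c_star - bb$c_star)), 1e-6)

  sa <- mf_bifurcation("situation", f = 0.2, p_grid = c(0.1, 0.15))
  sb <- mf_bifurcation("situation", f = 0.8, p_grid = c(0.1, 0.15))
  expect_gt(max(abs(sa$c_star - sb$c_star)), 0.05)

  # c = 1/2 (c0 = 0.5 start) is a fixed point at every p, stable only
  # above p*
  p_star <- critical_p("situation", 0.8)
  sym <- sb[sb$c0 == 0.5, ]
  expect_true(all(abs(sym$c_star - 0.5) < 1e-12))
  s_low <- mf_bifurcation("situation", f = 0.8, p_grid = 0.05,
                          c0_grid = 0.5)
  expect_identical(s_low$stable, 0L)
  s_high <- mf_bifurcation("situation", f = 0.8,
                           p_grid = min(0.9, p_star + 0.1), c0_grid = 0.5)
  expect_identical(s_high$stable, 1L)

  # lower branch rises monotonically towards the symmetric state
  low <- ba[ba$c0 == 0, ]
  expect_true(all(diff(low$c_star[order(low$p)]) >= -1e-9))
  expect_true(all(low$c_star <= 0.5 + 1e-9))
})
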