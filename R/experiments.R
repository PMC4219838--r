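#' Stationary concentration of one ensemble cell
#'
#' Runs `n_runs` independent simulations of one parameter cell.  Each run
#' builds a fresh network and all-down society, discards `burn_in_mcs`
#' Monte Carlo steps and averages the concentration over the following
#' `measure_mcs` MCS; the cell aggregates the per-run averages into their
#' mean and standard deviation.
#'
#' Each run uses two seeds drawn from a stream seeded with `seed`
#' (`sample.int(2^31 - 1, 2 * n_runs)`, consumed as a 2 x n_runs matrix):
#' one for the network build, one for the society initialization and the
#' dynamics.  Every run — and therefore the whole cell — is bit-for-bit
#' reproducible and individually replayable.  Decoupling the two streams
#' additionally means that cells sharing `seed` share their dynamics noise
#' even when the topology differs (common-random-number pairing for
#' equality comparisons across `f` or `M`).
#'
#' @param config a `qv_config`.
#' @param n_runs number of independent runs (>= 1).
#' @param burn_in_mcs,measure_mcs window lengths in MCS (>= 1 each).
#' @param seed master seed for the cell.
#' @param network optional fixed `qv_network` reused for every run
#'   (required for `topology = "custom"`).
#' @return a one-row `data.frame` with the fixed sweep header
#'   `variant, N, topology, M, q, p, f, n_runs, burn_in_mcs, measure_mcs,
#'   c_mean, c_std`.
#' @export
stationary_concentration <- function(config, n_runs, burn_in_mcs = 500L,
                                     measure_mcs = 500L, seed = 1L,
                                     network = NULL) {
  stopifnot(inherits(config, "qv_config"),
            n_runs >= 1, burn_in_mcs >= 1, measure_mcs >= 1)
  seeds <- with_seed(seed,
    matrix(sample.int(2147483647L, 2L * n_runs), nrow = 2L))
  c_bar <- vapply(seq_len(n_runs), function(r) {
    net <- if (!is.null(network)) network
           else with_seed(seeds[1L, r], build_network(config))
    with_seed(seeds[2L, r], {
      soc <- init_society(config, net)
      traj <- run_mcs(soc, burn_in_mcs + measure_mcs)
      mean(traj$c_series[(burn_in_mcs + 1):(burn_in_mcs + measure_mcs)])
    })
  }, numeric(1))
  data.frame(
    variant = config$variant, N = config$n_agents,
    topology = config$topology, M = config$m, q = config$q,
    p = config$p, f = config$f, n_runs = as.integer(n_runs),
    burn_in_mcs = as.integer(burn_in_mcs),
    measure_mcs = as.integer(measure_mcs),
    c_mean = mean(c_bar),
    c_std = if (n_runs > 1) stats::sd(c_bar) else 0
  )
}

#' Factorial phase-diagram sweep
#'
#' Full factorial grid over `p_grid` x `f_list` x `m_list`, one
#' [stationary_concentration()] cell per combination.  Per-cell master
#' seeds are drawn up front from a stream seeded with `seed` (one
#' `sample.int(2^31 - 1)` draw per cell, in row order of the expanded
#' grid), so cells are independent and individually replayable.
#'
#' @param config_template a `qv_config` supplying variant, N, q and
#'   topology; `p`, `f` (and `m`) are overridden cell by cell.
#' @param p_grid,f_list non-empty numeric grids.
#' @param m_list BA density values, or `NULL` to keep the template
#'   topology (use `NULL` for complete-graph sweeps).
#' @param n_runs,burn_in_mcs,measure_mcs per-cell protocol, see
#'   [stationary_concentration()].
#' @param seed master seed.
#' @return a `data.frame`, one row per cell, in the fixed sweep-header
#'   column order.
#' @export
phase_sweep <- function(config_template, p_grid, f_list, m_list = NULL,
                        n_runs = 100L, burn_in_mcs = 500L,
                        measure_mcs = 500L, seed = 1L) {
  stopifnot(length(p_grid) >= 1, length(f_list) >= 1)
  tpl <- config_template
  grid <- expand.grid(p = p_grid, f = f_list,
                      m = if (is.null(m_list)) NA else m_list)
  cell_seeds <- with_seed(seed, sample.int(2147483647L, nrow(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- model_config(
      tpl$variant, tpl$n_agents, grid$p[i], grid$f[i], tpl$q,
      topology = if (is.na(grid$m[i])) tpl$topology else "barabasi_albert",
      m = if (is.na(grid$m[i])) {
        if (tpl$topology == "barabasi_albert") tpl$m else NULL
      } else grid$m[i])
    stationary_concentration(cfg, n_runs, burn_in_mcs, measure_mcs,
                             seed = cell_seeds[i])
  })
  do.call(rbind, rows)
}

#' Monte Carlo vs. mean-field comparison on the complete graph
#'
#' For each `p` in `p_grid`, estimates the stationary Monte Carlo
#' concentration from the all-down start and iterates the matching
#' mean-field recursion from `c0 = 0`; tabulates both plus their absolute
#' difference.  Points closer than `crit_window` to the variant's critical
#' level `p*` are flagged `near_critical` — there relaxation times diverge
#' and finite simulations are not expected to agree with the fixed point —
#' and the standard usage is to exclude flagged rows from agreement
#' assertions.
#'
#' @param config a complete-graph `qv_config` (its `p` is ignored).
#' @param p_grid independence levels to compare at.
#' @param n_runs,burn_in_mcs,measure_mcs,seed Monte Carlo protocol per
#'   point, see [stationary_concentration()].
#' @param crit_window half-width of the near-critical flag window in `p`
#'   (default 0.02).
#' @return `data.frame` with columns `p, c_mc, c_mf, abs_diff,
#'   near_critical, p_star`.
#' @export
mc_vs_meanfield <- function(config, p_grid, n_runs = 30L,
                            burn_in_mcs = 500L, measure_mcs = 500L,
                            seed = 1L, crit_window = 0.02) {
  stopifnot(inherits(config, "qv_config"))
  if (config$topology != "complete")
    stop("mc_vs_meanfield is a complete-graph comparison; got topology ",
         config$topology)
  p_star <- if (config$variant == "situation" && config$f == 0)
    NA_real_ else critical_p(config$variant, config$f, config$q)
  point_seeds <- with_seed(seed, sample.int(2147483647L, length(p_grid)))
  rows <- lapply(seq_along(p_grid), function(i) {
    p <- p_grid[i]
    cfg <- model_config(config$variant, config$n_agents, p, config$f,
                        config$q, topology = "complete")
    mc <- stationary_concentration(cfg, n_runs, burn_in_mcs, measure_mcs,
                                   seed = point_seeds[i])
    mf <- mf_stationary(config$variant, p, config$f, config$q, c0 = 0,
                        n = config$n_agents)
    data.frame(p = p, c_mc = mc$c_mean, c_mf = mf$c_star,
               abs_diff = abs(mc$c_mean - mf$c_star),
               near_critical = !is.na(p_star) && abs(p - p_star) < crit_window,
               p_star = p_star)
  })
  do.call(rbind, rows)
}

#' Agent-by-time occupancy raster
#'
#' Runs `n_mcs` MCS recording the full agent state after every elementary
#' step (an N x (n_mcs * N) 0/1 matrix), plus the independent-agent ids in
#' the person variant.  Refuses N > 500 (memory contract).
#'
#' @param config a `qv_config` with `n_agents <= 500`.
#' @param n_mcs number of MCS.
#' @param seed run seed.
#' @return a `"qv_trajectory"` with a `raster` element.
#' @export
raster_run <- function(config, n_mcs, seed = 1L) {
  stopifnot(inherits(config, "qv_config"))
  if (config$n_agents > 500L)
    stop("raster runs are limited to N <= 500 (memory contract)")
  with_seed(seed, {
    soc <- init_society(config)
    run_mcs(soc, n_mcs, record = "full_raster")
  })
}

#' Summary statistics of a raster trajectory
#'
#' @param traj a `"qv_trajectory"` produced with raster recording.
#' @return list with `adopted_cells` (total adopted cell-steps),
#'   `independent_mass` (fraction of adopted cell-steps lying on
#'   independent agents' rows; `NA` for the situation variant) and
#'   `ever_adopted` (number of distinct agents adopted at any time).
#' @export
raster_summary <- function(traj) {
  if (is.null(traj$raster)) stop("trajectory has no raster; run with record = 'full_raster'")
  ras <- traj$raster
  total <- sum(ras)
  row_mass <- rowSums(ras)
  ind_mass <- if (traj$config$variant == "person") {
    if (total == 0) NA_real_ else sum(row_mass[traj$independents]) / total
  } else NA_real_
  list(adopted_cells = total,
       independent_mass = ind_mass,
       ever_adopted = sum(row_mass > 0))
}
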