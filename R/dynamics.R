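#' Model configuration
#'
#' Bundles every parameter of a single simulation: the variant of the
#' independence mechanism, system size, independence level `p`, flexibility
#' `f`, influence-group size `q`, and the interaction topology.
#'
#' * `variant = "person"`: a fixed set of `round(p * N)` agents (rounding
#'   half up) is independent for the whole run; everybody else always
#'   conforms.
#' * `variant = "situation"`: each update, the drawn agent acts
#'   independently with probability `p`.
#'
#' For Barabasi-Albert topologies `m >= q` is enforced here so that the
#' influence-group draw can never fail mid-run (the BA construction
#' guarantees minimum degree `m`).
#'
#' @param variant `"person"` or `"situation"`.
#' @param n_agents system size N (>= q + 1).
#' @param p independence level in \[0, 1\].
#' @param f flexibility in \[0, 1\]: the probability that an independently
#'   acting agent actually flips.
#' @param q influence-group size (default 4: a unanimous group of four is
#'   taken as the canonical persuasive unit).
#' @param topology `"complete"`, `"barabasi_albert"` or `"custom"`.
#' @param m BA density parameter (links per added node); required for
#'   `topology = "barabasi_albert"`.
#' @param seed optional integer stored with the config for provenance.
#' @return an object of class `"qv_config"`.
#' @export
#' @examples
#' model_config("person", n_agents = 1000, p = 0.1, f = 0.5)
model_config <- function(variant = c("person", "situation"), n_agents, p, f,
                         q = 4L, topology = c("complete", "barabasi_albert",
                                              "custom"),
                         m = NULL, seed = NULL) {
  variant <- match.arg(variant)
  topology <- match.arg(topology)
  n_agents <- as.integer(n_agents); q <- as.integer(q)
  if (is.na(n_agents) || is.na(q) || q < 1L)
    stop("configuration error: q must be a positive integer")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("configuration error: p must lie in [0, 1]")
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("configuration error: f must lie in [0, 1]")
  if (n_agents < q + 1L)
    stop("configuration error: n_agents must be at least q + 1")
  if (topology == "barabasi_albert") {
    if (is.null(m)) stop("configuration error: m is required for topology 'barabasi_albert'")
    m <- as.integer(m)
    if (is.na(m) || m < 1L || m >= n_agents)
      stop("configuration error: need n_agents > m >= 1")
    if (m < q)
      stop("configuration error: m must be >= q so every node can seed a ",
           "q-group (BA minimum degree equals m)")
  } else {
    m <- NA_integer_
  }
  structure(
    list(variant = variant, n_agents = n_agents, p = p, f = f, q = q,
         topology = topology, m = m,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "qv_config"
  )
}

#' @export
print.qv_config <- function(x, ...) {
  cat(sprintf("<qv_config> %s  N=%d  p=%g  f=%g  q=%d  topology=%s%s\n",
              x$variant, x$n_agents, x$p, x$f, x$q, x$topology,
              if (!is.na(x$m)) sprintf(" (M=%d)", x$m) else ""))
  invisible(x)
}

#' Build the network a configuration asks for
#'
#' @param config a `qv_config`. Consumes the global RNG stream for
#'   Barabasi-Albert topologies.
#' @return a `qv_network`.
#' @export
build_network <- function(config) {
  switch(config$topology,
    complete = make_complete_graph(config$n_agents),
    barabasi_albert = make_ba_network(config$n_agents, config$m),
    custom = stop("custom topology: pass the network explicitly to init_society()")
  )
}

#' Initialize a society in the all-unadopted state
#'
#' All agents start in state 0, the situation prior to introducing the
#' innovation.  In the person variant `round(p * N)` agents (half-up
#' rounding) are marked permanently independent, drawn uniformly at random
#' from the global RNG stream; the set is then constant for the whole run.
#'
#' @param config a `qv_config`.
#' @param network optional `qv_network`; built from the config when absent
#'   (required for `topology = "custom"`).
#' @return an object of class `"qv_society"` with fields `states`
#'   (integer 0/1 vector), `independents` (sorted ids; empty for the
#'   situation variant), `config` and `network`.
#' @export
init_society <- function(config, network = NULL) {
  stopifnot(inherits(config, "qv_config"))
  if (is.null(network)) network <- build_network(config)
  stopifnot(inherits(network, "qv_network"))
  if (network$n_nodes != config$n_agents)
    stop("configuration error: network has ", network$n_nodes,
         " nodes but config says n_agents = ", config$n_agents)
  n <- config$n_agents
  independents <- integer(0)
  if (config$variant == "person") {
    n_ind <- as.integer(floor(config$p * n + 0.5))  # round half up
    if (n_ind > 0L) independents <- sort.int(sample.int(n, n_ind))
  }
  structure(
    list(states = integer(n), independents = independents,
         config = config, network = network),
    class = "qv_society"
  )
}

#' @export
print.qv_society <- function(x, ...) {
  cat(sprintf("<qv_society> %s  N=%d  adopted=%d  independents=%d\n",
              x$config$variant, x$config$n_agents, sum(x$states),
              length(x$independents)))
  invisible(x)
}

#' Concentration of adopted agents
#'
#' The order parameter `c` = (number of adopted agents) / N.
#'
#' @param society a `qv_society`.
#' @return a single number in \[0, 1\].
#' @export
concentration <- function(society) sum(society$states) / society$config$n_agents

#' @describeIn concentration decomposition `c = c_I + c_C` into the adopted
#'   independent (`c_I`) and adopted conformist (`c_C`) components, both
#'   relative to the whole system size N.  `c_I`/`c_C` are `NA` for the
#'   situation variant, where no fixed independent set exists.
#' @export
concentration_components <- function(society) {
  n <- society$config$n_agents
  cc <- sum(society$states) / n
  if (society$config$variant != "person")
    return(c(c = cc, c_I = NA_real_, c_C = NA_real_))
  ci <- sum(society$states[society$independents]) / n
  c(c = cc, c_I = ci, c_C = cc - ci)
}

#' One elementary update (pure-R reference path)
#'
#' Draws one target uniformly and applies the update rule, consuming the
#' global RNG stream in the documented order (target, branch, flip, group).
#' The target-first sampling convention matches the mean-field derivation:
#' the influenced agent is drawn first, then `q` distinct members of its
#' neighbourhood; if and only if the group is unanimous the target takes
#' the group's state.  Independent behaviour flips the target's state with
#' probability `f`.
#'
#' This interpreted implementation is the normative reference; [run_steps()]
#' executes the identical rule (and identical RNG draws) in compiled code.
#'
#' @param society a `qv_society`.
#' @return list with `society` (at most one agent's state changed) and
#'   `event`, a list `(target, action, changed)` with `action` one of
#'   `"independent_flip"`, `"independent_stay"`,
#'   `"conform_adopt_group_state"`, `"no_unanimity"`.
#' @export
elementary_step <- function(society) {
  cfg <- society$config
  n <- cfg$n_agents
  target <- floor(runif(1) * n) + 1L
  if (target > n) target <- n
  independent <- if (cfg$variant == "person") {
    any(society$independents == target)
  } else {
    runif(1) < cfg$p
  }
  if (independent) {
    if (runif(1) < cfg$f) {
      society$states[target] <- 1L - society$states[target]
      event <- list(target = target, action = "independent_flip",
                    changed = TRUE)
    } else {
      event <- list(target = target, action = "independent_stay",
                    changed = FALSE)
    }
  } else {
    group <- sample_influence_group(society$network, target, cfg$q)
    gs <- society$states[group]
    if (all(gs == gs[1L])) {
      changed <- society$states[target] != gs[1L]
      society$states[target] <- gs[1L]
      event <- list(target = target, action = "conform_adopt_group_state",
                    changed = changed)
    } else {
      event <- list(target = target, action = "no_unanimity",
                    changed = FALSE)
    }
  }
  list(society = society, event = event)
}

flatten_adjacency <- function(net) {
  deg <- network_degrees(net)
  list(ptr = c(0L, cumsum(deg)),
       flat = as.integer(unlist(net$adj, use.names = FALSE) - 1L))
}

#' Run elementary steps (compiled loop)
#'
#' Low-level driver: executes `n_steps` elementary updates in compiled code
#' on the global RNG stream.  [run_mcs()] is the Monte Carlo-step wrapper
#' used by all experiments.
#'
#' @param society a `qv_society`.
#' @param n_steps number of elementary steps.
#' @param record_every record the concentration after every this many steps
#'   (0 = no series).
#' @param raster if `TRUE`, also store the full N x `n_steps` occupancy
#'   matrix (one column per elementary step).
#' @return a list of class `"qv_trajectory"`: `society` (final state),
#'   `c_series`, `counts` (named event-action totals), `n_changed`,
#'   `n_steps`, and optionally `raster`.
#' @export
run_steps <- function(society, n_steps, record_every = 0L, raster = FALSE) {
  stopifnot(inherits(society, "qv_society"), n_steps >= 1)
  cfg <- society$config
  ad <- flatten_adjacency(society$network)
  ind <- logical(cfg$n_agents)
  ind[society$independents] <- TRUE
  res <- cpp_run_steps(ad$ptr, ad$flat, society$states, ind,
                       if (cfg$variant == "person") 0L else 1L,
                       cfg$p, cfg$f, cfg$q,
                       as.double(n_steps), as.integer(record_every),
                       isTRUE(raster))
  society$states <- res$states
  out <- list(society = society, config = cfg,
              c_series = res$c_series, counts = res$counts,
              n_changed = res$n_changed, n_steps = n_steps,
              record_every = record_every,
              independents = society$independents)
  if (raster) out$raster <- res$raster
  class(out) <- "qv_trajectory"
  out
}

#' Run whole Monte Carlo steps
#'
#' One Monte Carlo step (MCS) is N elementary updates — the natural time
#' unit.  Runs `n_mcs` MCS from the society's current state and records the
#' concentration after every MCS (`record = "concentration"`) or the full
#' agent state after every elementary step (`record = "full_raster"`).
#' Deterministic given the RNG state (`set.seed()` before calling).
#'
#' @param society a `qv_society`.
#' @param n_mcs number of Monte Carlo steps (>= 1).
#' @param record `"concentration"` or `"full_raster"`.
#' @return a `"qv_trajectory"`; `times` holds the MCS indices `1:n_mcs` and
#'   `c_series` the concentration after each MCS.
#' @export
#' @examples
#' cfg <- model_config("situation", n_agents = 50, p = 0.3, f = 0.5)
#' set.seed(1)
#' soc <- init_society(cfg)
#' traj <- run_mcs(soc, 20)
#' tail(traj$c_series, 3)
run_mcs <- function(society, n_mcs,
                    record = c("concentration", "full_raster")) {
  record <- match.arg(record)
  n <- society$config$n_agents
  if (record == "full_raster" && n > 500L)
    stop("full_raster recording is limited to N <= 500 (memory contract)")
  traj <- run_steps(society, as.double(n_mcs) * n, record_every = n,
                    raster = record == "full_raster")
  traj$times <- seq_len(n_mcs)
  traj
}

#' @export
print.qv_trajectory <- function(x, ...) {
  cat(sprintf("<qv_trajectory> %s  N=%d  steps=%g  final c=%.4f\n",
              x$config$variant, x$config$n_agents, x$n_steps,
              concentration(x$society)))
  invisible(x)
}
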