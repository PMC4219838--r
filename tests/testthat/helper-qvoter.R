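# shared fixtures: everything is generated in code, no stored data

expect_network_invariants <- function(net) {
  expect_silent(validate_network(net))
  deg <- network_degrees(net)
  expect_identical(sum(deg) %% 2L, 0L)
  invisible(net)
}

# society with a prepared state vector (bypasses the all-down start for
# tests that need a specific configuration of opinions)
society_fixture <- function(variant, states, independents = integer(0),
                            net = NULL, p = 0, f = 0, q = 4L) {
  n <- length(states)
  if (is.null(net)) net <- make_complete_graph(n)
  cfg <- model_config(variant, n, p, f, q,
                      topology = "custom")
  soc <- structure(
    list(states = as.integer(states),
         independents = as.integer(sort(independents)),
         config = cfg, network = net),
    class = "qv_society")
  soc
}

# advance a society n steps through the pure-R reference path
r_reference_steps <- function(soc, n_steps) {
  for (i in seq_len(n_steps)) soc <- elementary_step(soc)$society
  soc
}

ba_test_grid <- expand.grid(n = c(6L, 15L, 40L), m = c(1L, 3L, 5L))
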