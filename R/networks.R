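#' Interaction topologies
#'
#' Networks are plain adjacency-list objects of class `"qv_network"`:
#' `n_nodes`, `adj` (a list of sorted integer neighbour vectors, 1-based
#' internally), `kind` (`"complete"`, `"barabasi_albert"` or `"custom"`) and
#' `m_param` (the BA density parameter `M`, `NA` otherwise).  All generated
#' networks are simple and undirected: `j %in% adj[[i]]` iff
#' `i %in% adj[[j]]`, no self-loops, no multi-edges.
#'
#' @name qv_network
NULL

new_network <- function(adj, kind, m_param = NA_integer_) {
  structure(
    list(n_nodes = length(adj), adj = adj, kind = kind,
         m_param = as.integer(m_param)),
    class = "qv_network"
  )
}

#' @export
print.qv_network <- function(x, ...) {
  cat(sprintf("<qv_network> kind=%s  n_nodes=%d  edges=%d%s\n",
              x$kind, x$n_nodes, network_edge_count(x),
              if (!is.na(x$m_param)) sprintf("  M=%d", x$m_param) else ""))
  invisible(x)
}

#' Complete graph on n nodes
#'
#' Every agent is connected to every other agent, the topology under which
#' the mean-field recursions are exact.
#'
#' @param n number of nodes (>= 2).
#' @return a `qv_network` with all `choose(n, 2)` edges.
#' @export
#' @examples
#' net <- make_complete_graph(5)
#' network_degrees(net)  # all equal 4
make_complete_graph <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("invalid size: a complete graph needs n >= 2 nodes")
  all_ids <- seq_len(n)
  adj <- lapply(all_ids, function(i) all_ids[-i])
  new_network(adj, "complete")
}

#' Barabasi-Albert preferential-attachment network
#'
#' Grows a network from a fully connected seed clique of `m` nodes; each
#' subsequently added node attaches to `m` distinct existing nodes chosen
#' with probability proportional to their current degree (for the first
#' added node all seed degrees are equal, so the choice is uniform).  The
#' construction guarantees minimum degree >= `m` and exactly
#' `m * (m - 1) / 2 + m * (n - m)` edges.
#'
#' Preferential choice uses the standard repeated-nodes pool: draws are made
#' with replacement from a multiset in which every node appears once per unit
#' of degree, and repeated until `m` distinct targets are collected.
#'
#' @param n final number of nodes (> m).
#' @param m seed-clique size and links per added node (>= 1).
#' @param seed optional integer; when given, the generator runs under a
#'   local RNG state so the edge set is a pure function of `(n, m, seed)`.
#' @return a `qv_network` of kind `"barabasi_albert"`.
#' @export
make_ba_network <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (length(n) != 1L || length(m) != 1L || is.na(n) || is.na(m) ||
      m < 1L || n <= m)
    stop("invalid size: Barabasi-Albert construction needs n > m >= 1")
  with_seed(seed, {
    # seed clique
    ei <- integer(0); ej <- integer(0)
    if (m > 1L) {
      pairs <- utils::combn(m, 2L)
      ei <- pairs[1L, ]; ej <- pairs[2L, ]
    }
    # degree-proportional pool: node id repeated once per incident edge
    pool <- c(ei, ej)
    for (v in seq.int(m + 1L, n)) {
      chosen <- integer(0)
      while (length(chosen) < m) {
        need <- m - length(chosen)
        cand <- if (length(pool) == 0L) {
          # degenerate m = 1 start: seed node has degree 0, choose uniformly
          seq_len(v - 1L)[sample.int(v - 1L, need, replace = TRUE)]
        } else {
          pool[sample.int(length(pool), need, replace = TRUE)]
        }
        chosen <- unique(c(chosen, cand))
      }
      ei <- c(ei, chosen); ej <- c(ej, rep.int(v, m))
      pool <- c(pool, chosen, rep.int(v, m))
    }
    net <- edges_to_network(ei, ej, n, "barabasi_albert")
    net$m_param <- m
    net
  })
}

#' Network from an explicit edge list
#'
#' @param edges two-column integer matrix of 1-based node ids, one
#'   undirected edge per row.
#' @param n_nodes total node count; defaults to the largest id seen.
#' @return a `qv_network` of kind `"custom"`.
#' @export
make_custom_network <- function(edges, n_nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must be a two-column matrix")
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L && any(edges < 1L)) stop("node ids must be >= 1")
  if (nrow(edges) > 0L && any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed")
  n <- if (is.null(n_nodes)) max(edges, 1L) else as.integer(n_nodes)
  if (nrow(edges) > 0L && max(edges) > n) stop("edge endpoint exceeds n_nodes")
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  edges_to_network(edges[, 1L], edges[, 2L], n, "custom")
}

edges_to_network <- function(ei, ej, n, kind) {
  inc_from <- split(c(ej, ei), factor(c(ei, ej), levels = seq_len(n)))
  adj <- lapply(inc_from, function(v) sort.int(as.integer(v)))
  names(adj) <- NULL
  new_network(adj, kind)
}

#' @rdname qv_network
#' @param net a `qv_network`.
#' @return `network_degrees()`: integer vector of node degrees;
#'   `network_edge_count()`: the number of undirected edges.
#' @export
network_degrees <- function(net) vapply(net$adj, length, integer(1))

#' @rdname qv_network
#' @export
network_edge_count <- function(net) sum(network_degrees(net)) %/% 2L

#' Check structural invariants of a network
#'
#' Asserts symmetry of the adjacency, absence of self-loops and of
#' multi-edges; errors on the first violation.
#'
#' @param net a `qv_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "qv_network"), length(net$adj) == net$n_nodes)
  for (i in seq_len(net$n_nodes)) {
    nb <- net$adj[[i]]
    if (anyDuplicated(nb)) stop("multi-edge at node ", i)
    if (any(nb == i)) stop("self-loop at node ", i)
    if (length(nb) && (any(nb < 1L) | any(nb > net$n_nodes)))
      stop("neighbor id out of range at node ", i)
    for (j in nb)
      if (!any(net$adj[[j]] == i))
        stop("asymmetric adjacency: ", i, " -> ", j)
  }
  invisible(net)
}

#' Draw an influence group
#'
#' Samples `q` distinct neighbours of `target` uniformly without
#' replacement, by a partial Fisher-Yates shuffle consuming exactly `q`
#' uniforms from the global RNG stream — the same draws, in the same order,
#' as the compiled simulation loop.
#'
#' @param net a `qv_network`.
#' @param target node id (1-based).
#' @param q group size; `degree(target)` must be >= `q`.
#' @return integer vector of `q` distinct neighbour ids.
#' @export
sample_influence_group <- function(net, target, q) {
  nb <- net$adj[[target]]
  deg <- length(nb)
  if (deg < q)
    stop("insufficient degree: node ", target, " has degree ", deg,
         " < q = ", q, " (network too sparse for the influence group)")
  for (k in seq_len(q)) {
    j <- (k - 1L) + floor(runif(1) * (deg - k + 1L)) + 1L
    if (j > deg) j <- deg
    tmp <- nb[k]; nb[k] <- nb[j]; nb[j] <- tmp
  }
  nb[seq_len(q)]
}

#' Edge-list import/export
#'
#' The interchange format is a tab-separated text file of 0-based node ids,
#' one undirected edge per line, written `i<TAB>j` with `i < j`, each edge
#' exactly once.
#'
#' @param net a `qv_network`.
#' @param path file path.
#' @param n_nodes node count for import (defaults to `max(id) + 1`); nodes
#'   with no incident edge at the tail of the id range need an explicit
#'   value.
#' @return `write_edgelist()`: `path` invisibly; `read_edgelist()`: a
#'   `qv_network` of kind `"custom"`.
#' @export
write_edgelist <- function(net, path) {
  deg <- network_degrees(net)
  ei <- rep.int(seq_len(net$n_nodes), deg)
  ej <- unlist(net$adj, use.names = FALSE)
  keep <- ei < ej
  df <- data.frame(i = ei[keep] - 1L, j = ej[keep] - 1L)
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  raw <- read.table(path, sep = "\t", col.names = c("i", "j"),
                    colClasses = "integer")
  if (is.null(n_nodes)) n_nodes <- max(raw$i, raw$j) + 1L
  make_custom_network(cbind(raw$i + 1L, raw$j + 1L), n_nodes = n_nodes)
}
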