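#' Random interaction graphs for the agent-based process
#'
#' `er_graph()` draws an Erdős–Rényi graph G(N, p) and `ws_graph()` a
#' Watts–Strogatz small-world graph (ring lattice with `K/2` neighbours on
#' each side, edges rewired with probability `rewire_p`). Both rejection
#' sample whole graphs until the result is connected and every node has at
#' least `min_degree` neighbours — the consensus mechanisms need each agent
#' to have enough neighbours to fill its sample sets.
#'
#' @param N Number of nodes (agents).
#' @param p Edge probability in (0, 1].
#' @param min_degree Minimum degree required of every node.
#' @param seed Optional integer seed; when given, generation is
#'   reproducible and the ambient RNG state is untouched.
#' @param max_attempts Rejection-sampling budget; exceeded -> error.
#' @return An object of class `ci_graph`.
#' @examples
#' g <- er_graph(50, 0.2, seed = 1)
#' g
#' @export
er_graph <- function(N, p, min_degree = 1L, seed = NULL, max_attempts = 1000L) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) abort("N must be an integer >= 2")
  if (!is.numeric(p) || p <= 0 || p > 1) abort("p must lie in (0, 1]")
  if (max_attempts < 1L) abort("max_attempts must be >= 1")
  with_seed_if(seed, {
    for (attempt in seq_len(max_attempts)) {
      g <- igraph::sample_gnp(N, p)
      if (igraph::is_connected(g) && min(igraph::degree(g)) >= min_degree) {
        return(new_ci_graph(g, "erdos_renyi",
                            list(N = N, p = p, min_degree = min_degree),
                            seed = seed, attempts = attempt))
      }
    }
    abort(sprintf(
      "failed to generate a connected G(%d, %g) with min degree %d in %d attempts",
      N, p, min_degree, max_attempts
    ))
  })
}

#' @rdname er_graph
#' @param K Even number of lattice neighbours per node (K/2 on each side).
#' @param rewire_p Edge rewiring probability in [0, 1].
#' @export
ws_graph <- function(N, K, rewire_p, min_degree = 1L, seed = NULL,
                     max_attempts = 1000L) {
  N <- as.integer(N)
  K <- as.integer(K)
  if (is.na(N) || N < 3L) abort("N must be an integer >= 3")
  if (is.na(K) || K %% 2L != 0L) abort("K must be an even integer")
  if (K < 2L || K > N - 1L) abort("K must satisfy 0 < K <= N - 1")
  if (rewire_p < 0 || rewire_p > 1) abort("rewire_p must lie in [0, 1]")
  with_seed_if(seed, {
    for (attempt in seq_len(max_attempts)) {
      g <- igraph::sample_smallworld(1, N, K %/% 2L, rewire_p,
                                     loops = FALSE, multiple = FALSE)
      g <- igraph::simplify(g)
      if (igraph::is_connected(g) && min(igraph::degree(g)) >= min_degree) {
        return(new_ci_graph(g, "watts_strogatz",
                            list(N = N, K = K, rewire_p = rewire_p,
                                 min_degree = min_degree),
                            seed = seed, attempts = attempt))
      }
    }
    abort(sprintf(
      "failed to generate a connected Watts-Strogatz graph in %d attempts",
      max_attempts
    ))
  })
}

#' Build a simulation graph from an igraph object
#'
#' Wraps an undirected simple connected igraph graph in the flat adjacency
#' (CSR-style) representation the simulator uses.
#'
#' @param g An igraph object.
#' @param generator Free-text generator name recorded in the descriptor.
#' @param gen_params Named list of generator parameters for the descriptor.
#' @param seed,attempts Provenance fields recorded in the descriptor.
#' @return An object of class `ci_graph`: list with `n`, `deg`, `ptr`
#'   (0-based offsets), `nbr` (concatenated neighbour ids), and
#'   `descriptor`.
#' @export
new_ci_graph <- function(g, generator = "custom", gen_params = list(),
                         seed = NULL, attempts = NA_integer_) {
  if (igraph::is_directed(g)) abort("the interaction graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    abort("the interaction graph must be simple (no loops or multi-edges)")
  }
  adj <- igraph::as_adj_list(g)
  deg <- lengths(adj)
  nbr <- as.integer(unlist(adj, use.names = FALSE))
  structure(
    list(
      n = igraph::vcount(g),
      deg = as.integer(deg),
      ptr = c(0L, cumsum(as.integer(deg))),
      nbr = nbr,
      igraph = g,
      descriptor = list(
        N = igraph::vcount(g), generator = generator,
        parameters = gen_params, seed = seed, attempts = attempts
      )
    ),
    class = "ci_graph"
  )
}

#' @export
print.ci_graph <- function(x, ...) {
  cat(sprintf(
    "<ci_graph> %s: %d nodes, %d edges, degree range [%d, %d]\n",
    x$descriptor$generator, x$n, length(x$nbr) %/% 2L,
    min(x$deg), max(x$deg)
  ))
  invisible(x)
}

#' Write and read a graph as a plain-text edge list
#'
#' The edge list uses 0-based node ids, one `u v` pair per line. A JSON
#' descriptor (node count, generator, parameters, seed) is written next to
#' it as `<path>.json`.
#'
#' @param graph A `ci_graph`.
#' @param path Edge-list file path.
#' @return `write_graph_edgelist()` the path invisibly;
#'   `read_graph_edgelist()` a `ci_graph`.
#' @export
write_graph_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph$igraph, names = FALSE) - 1L
  writeLines(paste(el[, 1], el[, 2]), path)
  jsonlite::write_json(graph$descriptor, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_graph_edgelist
#' @export
read_graph_edgelist <- function(path) {
  el <- utils::read.table(path, col.names = c("u", "v"))
  desc_path <- paste0(path, ".json")
  desc <- if (file.exists(desc_path)) jsonlite::read_json(desc_path) else list()
  n <- if (!is.null(desc$N)) as.integer(desc$N) else max(el) + 1L
  g <- igraph::graph_from_edgelist(as.matrix(el) + 1L, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  new_ci_graph(g, generator = desc$generator %||% "file",
               gen_params = desc$parameters %||% list(),
               seed = desc$seed)
}
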