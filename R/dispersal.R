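# Dispersal scenarios on the river network: connectivity with optional dam
# barriers, scenario presence sets, and range-change accounting.

#' Build the connectivity graph
#'
#' The traversable graph is the river-adjacency network, minus the dammed
#' edges when barriers are active. Dams block traversal in both directions.
#'
#' @param network a `catchment_network`.
#' @param dams data.frame (from, to) of dammed edges, each an existing
#'   network edge.
#' @param barriers_active remove dam edges (`TRUE`) or keep the full network.
#' @return an igraph undirected graph over all catchment ids.
#' @export
build_connectivity <- function(network, dams = NULL, barriers_active = FALSE) {
  ed <- network$edges
  if (!is.null(dams) && nrow(dams)) {
    bad <- !(edge_key(dams$from, dams$to) %in% edge_key(ed$from, ed$to))
    if (any(bad))
      stop("dam edge not in network: ",
           paste(paste(dams$from[bad], dams$to[bad], sep = "-"),
                 collapse = ", "), call. = FALSE)
    if (barriers_active)
      ed <- ed[!(edge_key(ed$from, ed$to) %in%
                   edge_key(dams$from, dams$to)), , drop = FALSE]
  }
  igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = network$catchments$catchment_id))
}

#' Apply a dispersal scenario
#'
#' * `no_dispersal`: the future range is the baseline range unchanged.
#' * `free_dispersal`: predicted-present catchments that are connected
#'   through the network to a baseline-present catchment (a catchment that
#'   is itself baseline-present counts via the zero-length path).
#' * `restricted_dispersal`: as free, on the graph with dam edges removed.
#'
#' Paths may traverse catchments that are not themselves suitable; only the
#' endpoints' status matters.
#'
#' @param predicted character vector of predicted-present catchment ids
#'   (future consensus range).
#' @param baseline character vector of baseline-present catchment ids.
#' @param graph connectivity graph from [build_connectivity()] (with
#'   barriers active for the restricted scenario).
#' @param scenario one of `"no_dispersal"`, `"free_dispersal"`,
#'   `"restricted_dispersal"`.
#' @return an object of class `scenario_range`: list (scenario, presence,
#'   n_presences).
#' @export
apply_scenario <- function(predicted, baseline, graph,
                           scenario = c("no_dispersal", "free_dispersal",
                                        "restricted_dispersal")) {
  scenario <- match.arg(scenario)
  ids <- igraph::V(graph)$name
  unknown <- setdiff(c(predicted, baseline), ids)
  if (length(unknown))
    stop("ids not in graph: ", paste(utils::head(unknown, 5),
                                     collapse = ", "), call. = FALSE)
  presence <- if (scenario == "no_dispersal") {
    sort(unique(baseline))
  } else {
    comp <- igraph::components(graph)$membership
    reachable <- comp[predicted] %in% comp[baseline]
    sort(unique(predicted[reachable]))
  }
  structure(list(scenario = scenario, presence = presence,
                 n_presences = length(presence)),
            class = "scenario_range")
}

#' All three dispersal scenarios at once
#'
#' @param predicted,baseline presence id vectors (see [apply_scenario()]).
#' @param network a `catchment_network`.
#' @param dams data.frame of dammed edges.
#' @return named list of `scenario_range` objects
#'   (no_dispersal, free_dispersal, restricted_dispersal).
#' @export
dispersal_scenarios <- function(predicted, baseline, network, dams) {
  free_graph <- build_connectivity(network, dams, barriers_active = FALSE)
  cut_graph <- build_connectivity(network, dams, barriers_active = TRUE)
  list(
    no_dispersal = apply_scenario(predicted, baseline, free_graph,
                                  "no_dispersal"),
    free_dispersal = apply_scenario(predicted, baseline, free_graph,
                                    "free_dispersal"),
    restricted_dispersal = apply_scenario(predicted, baseline, cut_graph,
                                          "restricted_dispersal"))
}

#' Signed percent range change
#'
#' `round(100 * (n_scenario - n_baseline) / n_baseline)` to the nearest
#' integer, half away from zero.
#'
#' @param n_baseline baseline presence count (> 0).
#' @param n_scenario scenario presence count.
#' @return integer signed percent.
#' @export
range_change <- function(n_baseline, n_scenario) {
  if (!is.numeric(n_baseline) || n_baseline <= 0)
    stop("n_baseline must be positive", call. = FALSE)
  pct <- 100 * (n_scenario - n_baseline) / n_baseline
  as.integer(sign(pct) * floor(abs(pct) + 0.5))
}

#' @export
print.scenario_range <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d presences\n", x$scenario, x$n_presences))
  invisible(x)
}
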