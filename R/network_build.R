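#' Select the events entering one behavioural network
#'
#' Returns the events of one behaviour in one phase. For aggression, only
#' dyadic events met with a clear submissive response are retained (those
#' are the decided conflicts the aggression network is built from); every
#' other behaviour passes unfiltered.
#'
#' @param events validated `interaction_events`.
#' @param behaviour one of [behaviours()].
#' @param phase `"baseline"` or `"experimental"`.
#' @return The matching subset, still an `interaction_events` data.frame.
#' @export
filter_events <- function(events, behaviour, phase) {
  .check_behaviour(behaviour)
  .check_phase(phase)
  keep <- events$behaviour == behaviour & events$phase == phase
  if (behaviour == "aggression")
    keep <- keep & !is.na(events$submissive_response) &
      events$submissive_response
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build one weighted behavioural network
#'
#' Aggregates pre-filtered events into a weighted (di)graph for one
#' behaviour and phase. Edge weights are raw dyadic event counts
#' (observation effort is equal across phases, so counts are comparable).
#' All eligible individuals appear as nodes, including isolates, so a
#' centrality of zero is distinguishable from exclusion. Events with an
#' endpoint outside `eligible_ids` are dropped and counted in the
#' `"dropped"` attribute.
#'
#' @param events events for this behaviour and phase, from
#'   [filter_events()].
#' @param behaviour,phase the layer being built (checked against the
#'   events).
#' @param eligible_ids node set, typically [phase_presence_filter()] output.
#' @return An object of class `"behaviour_network"`: a list with fields
#'   `behaviour`, `phase`, `directed`, `nodes` (sorted ids) and `edges`
#'   (data.frame `from`, `to`, `weight`; for undirected networks the pair
#'   is stored with `from < to`).
#' @examples
#' ev <- interaction_events(data.frame(
#'   date = "2019-03-04", phase = "baseline", behaviour = "grooming",
#'   actor = c("a", "a", "b"), recipient = c("b", "b", "a"),
#'   severity = NA, submissive_response = NA))
#' net <- build_network(ev, "grooming", "baseline", c("a", "b", "c"))
#' net$edges  # a->b weight 2, b->a weight 1; "c" is an isolate
#' @export
build_network <- function(events, behaviour, phase, eligible_ids) {
  .check_behaviour(behaviour)
  .check_phase(phase)
  if (length(eligible_ids) == 0L) stop("eligible_ids must be non-empty")
  eligible_ids <- sort(unique(as.character(eligible_ids)))
  ev <- events[events$behaviour == behaviour & events$phase == phase, ,
               drop = FALSE]
  ok <- ev$actor %in% eligible_ids & ev$recipient %in% eligible_ids
  dropped <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]
  directed <- behaviour %in% .DIRECTED
  from <- ev$actor; to <- ev$recipient
  if (!directed) {
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  if (length(from)) {
    key <- paste(from, to, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        to = vapply(parts, `[`, "", 2L),
                        weight = as.integer(tab),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer())
  }
  structure(list(behaviour = behaviour, phase = phase, directed = directed,
                 nodes = eligible_ids, edges = edges),
            class = "behaviour_network",
            dropped = dropped)
}

#' @export
print.behaviour_network <- function(x, ...) {
  cat(sprintf("<behaviour_network> %s / %s: %d nodes, %d edges, %d events%s\n",
              x$behaviour, x$phase, length(x$nodes), nrow(x$edges),
              sum(x$edges$weight),
              if (x$directed) " (directed)" else " (undirected)"))
  invisible(x)
}

#' Convert a behavioural network to igraph
#'
#' @param network a `"behaviour_network"`.
#' @return An [igraph::graph] with a `weight` edge attribute; isolates are
#'   kept.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "behaviour_network"))
  igraph::graph_from_data_frame(network$edges,
                                directed = network$directed,
                                vertices = data.frame(name = network$nodes))
}

#' Export a network as a weighted edge list or GraphML
#'
#' `write_edgelist()` writes a CSV with columns `actor, recipient, weight`;
#' `write_graphml()` writes GraphML via igraph (node set preserved,
#' including isolates).
#'
#' @param network a `"behaviour_network"`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "behaviour_network"))
  df <- network$edges
  names(df) <- c("actor", "recipient", "weight")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Build all six behavioural networks for one phase
#'
#' Applies [filter_events()] and [build_network()] for every behaviour.
#'
#' @param events validated `interaction_events`.
#' @param phase phase label.
#' @param eligible_ids node set shared by all layers.
#' @return Named list of `"behaviour_network"` objects, one per behaviour.
#' @export
build_phase_networks <- function(events, phase, eligible_ids) {
  stats::setNames(lapply(.BEHAVIOURS, function(beh)
    build_network(filter_events(events, beh, phase), beh, phase,
                  eligible_ids)),
    .BEHAVIOURS)
}
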