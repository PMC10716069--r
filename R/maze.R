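#' Build a metric maze graph
#'
#' Constructs and validates a `maze_graph`: a connected, undirected metric
#' graph with planar node coordinates (meters), named landmark placements and
#' a learned route (the guided-tour path participants follow during the
#' learning phase). The maze is the source of the shortest-path denominators
#' used by the travel-efficiency measure.
#'
#' @param spec A maze specification: either a path to a JSON file or a list
#'   with elements
#'   \describe{
#'     \item{nodes}{named list/matrix, node id -> `c(x, y)` in meters}
#'     \item{edges}{list of `c(id, id)` or `c(id, id, length)`; when the
#'       length is omitted it defaults to the Euclidean distance between the
#'       endpoint coordinates}
#'     \item{landmarks}{named character vector/list, landmark name -> node id}
#'     \item{learned_route}{character vector of node ids; consecutive pairs
#'       must be edges}
#'   }
#' @return An object of class `maze_graph` with fields `nodes` (2-column
#'   matrix of coordinates, rownames are node ids), `edges` (data.frame
#'   `from`, `to`, `length`), `landmarks` (named character vector),
#'   `learned_route` (character vector) and `graph` (the underlying weighted
#'   \pkg{igraph} object).
#' @examples
#' m <- build_maze(list(
#'   nodes = list(A = c(0, 0), B = c(1, 0), C = c(1, 1), D = c(0, 1)),
#'   edges = list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")),
#'   landmarks = c(start = "A", goal = "C"),
#'   learned_route = c("A", "B", "C")
#' ))
#' shortest_path_length(m, "A", "C")
#' @export
build_maze <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    spec <- jsonlite::read_json(spec, simplifyVector = FALSE)
  }
  stopifnot(is.list(spec))
  for (field in c("nodes", "edges", "landmarks", "learned_route")) {
    if (is.null(spec[[field]])) {
      stop("maze specification is missing field '", field, "'", call. = FALSE)
    }
  }

  node_ids <- names(spec$nodes)
  if (is.null(node_ids) || anyDuplicated(node_ids) || any(!nzchar(node_ids))) {
    stop("nodes must be uniquely named", call. = FALSE)
  }
  coords <- t(vapply(spec$nodes, function(p) as.numeric(unlist(p)[1:2]),
                     numeric(2)))
  rownames(coords) <- node_ids
  colnames(coords) <- c("x", "y")
  if (anyNA(coords)) stop("node coordinates must be numeric [x, y]", call. = FALSE)

  edges <- lapply(spec$edges, function(e) unlist(e, use.names = FALSE))
  from <- vapply(edges, function(e) as.character(e[[1]]), character(1))
  to   <- vapply(edges, function(e) as.character(e[[2]]), character(1))
  len  <- vapply(edges, function(e) {
    if (length(e) >= 3) as.numeric(e[[3]]) else NA_real_
  }, numeric(1))
  for (id in unique(c(from, to))) {
    if (!id %in% node_ids) {
      stop("edge references unknown node '", id, "'", call. = FALSE)
    }
  }
  need <- is.na(len)
  if (any(need)) {
    len[need] <- sqrt(rowSums((coords[from[need], , drop = FALSE] -
                               coords[to[need], , drop = FALSE])^2))
  }
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("edge lengths must be strictly positive", call. = FALSE)
  }
  edge_df <- data.frame(from = from, to = to, length = len,
                        stringsAsFactors = FALSE)

  landmarks <- unlist(spec$landmarks)
  landmarks <- stats::setNames(as.character(landmarks), names(landmarks))
  if (length(landmarks) && (is.null(names(landmarks)) || any(!nzchar(names(landmarks))))) {
    stop("landmarks must be named", call. = FALSE)
  }
  for (i in seq_along(landmarks)) {
    if (!landmarks[[i]] %in% node_ids) {
      stop("landmark '", names(landmarks)[i], "' references unknown node '",
           landmarks[[i]], "'", call. = FALSE)
    }
  }

  route <- as.character(unlist(spec$learned_route))
  bad <- setdiff(route, node_ids)
  if (length(bad)) {
    stop("learned route references unknown node '", bad[1], "'", call. = FALSE)
  }

  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = data.frame(name = node_ids))
  if (!igraph::is_connected(g)) stop("maze graph is disconnected", call. = FALSE)

  maze <- structure(
    list(nodes = coords, edges = edge_df, landmarks = landmarks,
         learned_route = route, graph = g),
    class = "maze_graph"
  )
  # learned route must be walkable
  if (length(route) > 1) {
    route_length(maze, route)
  }
  maze
}

#' @export
print.maze_graph <- function(x, ...) {
  cat(sprintf("maze_graph: %d nodes, %d edges, %d landmarks, learned route of %d nodes\n",
              nrow(x$nodes), nrow(x$edges), length(x$landmarks),
              length(x$learned_route)))
  invisible(x)
}

#' Write a maze graph to its JSON interchange form
#'
#' Inverse of [build_maze()] over the JSON maze-specification format; a
#' written maze re-parses and revalidates identically.
#'
#' @param maze A `maze_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maze <- function(maze, path) {
  stopifnot(inherits(maze, "maze_graph"))
  spec <- list(
    nodes = stats::setNames(
      lapply(seq_len(nrow(maze$nodes)), function(i) unname(maze$nodes[i, ])),
      rownames(maze$nodes)),
    edges = lapply(seq_len(nrow(maze$edges)), function(i) {
      list(maze$edges$from[i], maze$edges$to[i], maze$edges$length[i])
    }),
    landmarks = as.list(maze$landmarks),
    learned_route = maze$learned_route
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

check_node <- function(maze, id) {
  if (!id %in% rownames(maze$nodes)) {
    stop("unknown node '", id, "'", call. = FALSE)
  }
  id
}

#' Shortest traversable path length between two nodes
#'
#' Length in meters of the minimal-total-length path through the maze's
#' corridor network (Dijkstra on the weighted graph). This is the denominator
#' of the travel-efficiency ratio.
#'
#' @param maze A `maze_graph`.
#' @param a,b Node ids.
#' @return Length in meters; `0` when `a == b`.
#' @export
shortest_path_length <- function(maze, a, b) {
  stopifnot(inherits(maze, "maze_graph"))
  check_node(maze, a); check_node(maze, b)
  as.numeric(igraph::distances(maze$graph, v = a, to = b,
                               weights = igraph::E(maze$graph)$length))
}

#' Total length of a walked route
#'
#' Sums traversed edge lengths along an ordered node sequence; revisited
#' edges are counted every time they are walked.
#'
#' @param maze A `maze_graph`.
#' @param route Character vector of node ids; each consecutive pair must be
#'   an edge of the maze.
#' @return Length in meters; `0` for a single node.
#' @export
route_length <- function(maze, route) {
  stopifnot(inherits(maze, "maze_graph"))
  route <- as.character(route)
  for (id in unique(route)) check_node(maze, id)
  if (length(route) < 2) return(0)
  key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  lens <- stats::setNames(maze$edges$length, key(maze$edges$from, maze$edges$to))
  steps <- key(route[-length(route)], route[-1])
  miss <- which(!(steps %in% names(lens)))
  if (length(miss)) {
    stop("route step (", route[miss[1]], ", ", route[miss[1] + 1],
         ") is not an edge of the maze", call. = FALSE)
  }
  sum(lens[steps])
}

# Distance walked along the learned route from the start landmark's node to
# the first subsequent occurrence of the target's node. The route is treated
# as a tour: if the target does not occur after the start, the walk wraps
# from the route's end back to its beginning (the final and first route nodes
# are joined by construction or by an existing edge).
along_route_length <- function(maze, start_landmark, target_landmark) {
  route <- maze$learned_route
  for (nm in c(start_landmark, target_landmark)) {
    if (!nm %in% names(maze$landmarks)) {
      stop("unknown landmark '", nm, "'", call. = FALSE)
    }
  }
  a <- maze$landmarks[[start_landmark]]
  b <- maze$landmarks[[target_landmark]]
  if (!a %in% route) stop("landmark '", start_landmark, "' is not on the learned route", call. = FALSE)
  if (!b %in% route) stop("landmark '", target_landmark, "' is not on the learned route", call. = FALSE)
  i <- match(a, route)
  # unroll the tour once past its own length so a wrap is a plain walk
  closed <- route[length(route)] == route[1]
  loop <- if (closed) route[-1] else route
  walk <- c(route[i:length(route)], loop)
  j <- match(b, walk)
  seg <- walk[1:j]
  # wrapping across the route's two ends requires them to be joined
  if (!closed && j > (length(route) - i + 1)) {
    route_length(maze, c(route[length(route)], route[1]))  # errors if not an edge
  }
  route_length(maze, seg)
}

#' Average learned-route efficiency over a set of trials
#'
#' For each (start, target) landmark pair, the ratio of the distance walked
#' along the learned route (forward from the start landmark, wrapping around
#' the tour if needed) to the shortest traversable path length. The mean over
#' trial pairs is the efficiency score a participant would obtain by always
#' following the learned route; it is also the value imputed for failed
#' shortcutting trials. Published reference values for the original two
#' mazes, usable as overrides when no maze geometry is available, are `2.54`
#' (desktop) and `2.19` (immersive).
#'
#' @param maze A `maze_graph`.
#' @param trial_pairs A two-column data.frame or matrix (start landmark,
#'   target landmark), or a list of length-2 character vectors.
#' @return The mean ratio (unitless, >= 1).
#' @export
learned_route_efficiency <- function(maze, trial_pairs) {
  stopifnot(inherits(maze, "maze_graph"))
  if (is.list(trial_pairs) && !is.data.frame(trial_pairs)) {
    trial_pairs <- do.call(rbind, lapply(trial_pairs, as.character))
  }
  trial_pairs <- as.data.frame(trial_pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(trial_pairs) >= 2, nrow(trial_pairs) >= 1)
  ratios <- vapply(seq_len(nrow(trial_pairs)), function(i) {
    s <- as.character(trial_pairs[i, 1]); t <- as.character(trial_pairs[i, 2])
    along <- along_route_length(maze, s, t)
    short <- shortest_path_length(maze, maze$landmarks[[s]], maze$landmarks[[t]])
    along / short
  }, numeric(1))
  mean(ratios)
}
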