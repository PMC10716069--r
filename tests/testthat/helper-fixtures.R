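# Shared fixtures and independent oracles, built in code.

# 2x2 unit grid with a closed perimeter learned route.
unit_square_maze <- function() {
  build_maze(list(
    nodes = list(A = c(0, 0), B = c(1, 0), C = c(1, 1), D = c(0, 1)),
    edges = list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")),
    landmarks = c(LA = "A", LB = "B", LC = "C", LD = "D"),
    learned_route = c("A", "B", "C", "D", "A")
  ))
}

# Random connected graph: random spanning tree plus extra random edges,
# random planar coordinates, Euclidean edge lengths.
random_connected_maze <- function(n_nodes, extra_edges = 2) {
  ids <- sprintf("v%d", seq_len(n_nodes))
  coords <- matrix(runif(2 * n_nodes, 0, 10), ncol = 2)
  nodes <- setNames(lapply(seq_len(n_nodes), function(i) coords[i, ]), ids)
  edges <- list()
  perm <- sample(ids)
  for (i in 2:n_nodes) {
    edges[[length(edges) + 1]] <- c(perm[i], perm[sample.int(i - 1, 1)])
  }
  for (e in seq_len(extra_edges)) {
    pair <- sample(ids, 2)
    edges[[length(edges) + 1]] <- pair
  }
  # drop duplicate/parallel edges
  keys <- vapply(edges, function(e) paste(sort(e), collapse = "|"), "")
  edges <- edges[!duplicated(keys)]
  build_maze(list(nodes = nodes, edges = edges,
                  landmarks = c(start = ids[1]), learned_route = ids[1]))
}

# Exhaustive-enumeration shortest path: minimum total length over all
# simple paths, by depth-first search. Only viable for small graphs.
enumerate_shortest <- function(maze, a, b) {
  adj <- list()
  for (i in seq_len(nrow(maze$edges))) {
    f <- maze$edges$from[i]; t <- maze$edges$to[i]; l <- maze$edges$length[i]
    adj[[f]] <- rbind(adj[[f]], data.frame(to = t, len = l))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = f, len = l))
  }
  best <- Inf
  visit <- function(node, dist, seen) {
    if (dist >= best) return(invisible())
    if (node == b) { best <<- dist; return(invisible()) }
    nb <- adj[[node]]
    for (i in seq_len(NROW(nb))) {
      if (!nb$to[i] %in% seen) {
        visit(nb$to[i], dist + nb$len[i], c(seen, nb$to[i]))
      }
    }
  }
  visit(a, 0, a)
  best
}

# Independent scripted split-half computation: explicit loops, no reuse of
# package internals.
manual_split_half <- function(m, half1, half2) {
  h1 <- numeric(nrow(m)); h2 <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    h1[i] <- mean(m[i, half1], na.rm = TRUE)
    h2[i] <- mean(m[i, half2], na.rm = TRUE)
  }
  keep <- is.finite(h1) & is.finite(h2)
  r <- cor(h1[keep], h2[keep])
  2 * r / (1 + r)
}

# Rotation-matrix bearing oracle: rotate the frame so the facing direction
# is north (+y), then read the clockwise azimuth of the rotated target ray.
rotation_bearing <- function(observer, facing_point, target) {
  u <- facing_point - observer
  v <- target - observer
  phi <- atan2(u[1], u[2])          # clockwise azimuth of facing from +y
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  w <- as.numeric(rot %*% v)
  (atan2(w[1], w[2]) * 180 / pi) %% 360
}

# Minimal valid pointing / shortcut tables for plumbing tests.
tiny_pointing <- function(ids = c("p1", "p2"), k = 4, phase = "I") {
  expand <- expand.grid(participant_id = ids, trial = seq_len(k),
                        stringsAsFactors = FALSE)
  data.frame(
    participant_id = expand$participant_id, phase = phase,
    trial_id = sprintf("PT%02d", expand$trial),
    start_landmark = "L01", target_landmark = "L02",
    response_bearing_deg = (expand$trial * 37) %% 360,
    true_bearing_deg = (expand$trial * 91) %% 360,
    stringsAsFactors = FALSE
  )
}

tiny_shortcut <- function(ids = c("p1", "p2"), k = 4, success = TRUE) {
  expand <- expand.grid(participant_id = ids, trial = seq_len(k),
                        stringsAsFactors = FALSE)
  data.frame(
    participant_id = expand$participant_id,
    trial_id = sprintf("ST%02d", expand$trial),
    start_landmark = "L01", target_landmark = "L02",
    success = rep_len(success, nrow(expand)),
    traveled_length_m = 10 + expand$trial,
    shortest_length_m = 8,
    stringsAsFactors = FALSE
  )
}
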