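# Shared fixtures: small trees and environments built in code.

default_tree <- function(seed = 1L, side = "right") {
  generate_tree(tree_params(side = side), seed = seed)
}

# environment on a default Y-tree with a mid-branch target
default_env <- function(seed = 1L, target_seed = 2L, cfg = env_config()) {
  tree <- default_tree(seed)
  nav_env(tree, sample_target(tree, seed = target_seed), cfg)
}

# independent Dijkstra oracle over the resampled node graph (used to check
# the package's tree-traversal distance)
dijkstra_to_target <- function(tree, from_node, target_node) {
  n <- nrow(tree$nodes)
  adj <- vector("list", n)
  for (i in which(tree$parent > 0L)) {
    w <- sqrt(sum((tree$nodes[i, ] - tree$nodes[tree$parent[i], ])^2))
    adj[[i]] <- rbind(adj[[i]], c(tree$parent[i], w))
    adj[[tree$parent[i]]] <- rbind(adj[[tree$parent[i]]], c(i, w))
  }
  dist <- rep(Inf, n)
  dist[from_node] <- 0
  visited <- rep(FALSE, n)
  repeat {
    u <- which.min(ifelse(visited, Inf, dist))
    if (visited[u] || is.infinite(dist[u])) break
    visited[u] <- TRUE
    if (u == target_node) break
    for (k in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][k, 1]
      w <- adj[[u]][k, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist[target_node]
}
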