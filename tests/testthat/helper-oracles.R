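# Independent oracles, kept deliberately naive and separate from the
# package implementation paths they check.

# all permutations of a vector, one per row
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub, deparse.level = 0))
  }
  out
}

# brute-force Euclidean distance matrix (double loop, no dist())
brute_distances <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(ncol(m))) s <- s + (m[i, k] - m[j, k])^2
      d[i, j] <- sqrt(s)
    }
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# exhaustive permutation null for one pair of rows: population mean and sd
# of the Euclidean distance over all joint row permutations
exhaustive_pair_null <- function(row_a, row_b) {
  pa <- all_perms(row_a)
  pb <- all_perms(row_b)
  ds <- numeric(nrow(pa) * nrow(pb))
  idx <- 1L
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      ds[idx] <- sqrt(sum((pa[i, ] - pb[j, ])^2))
      idx <- idx + 1L
    }
  }
  list(mean = mean(ds), sd = sqrt(mean((ds - mean(ds))^2)), distances = ds)
}

# geodesic tree-path oracle via igraph shortest paths on the node graph
igraph_path_length <- function(skel) {
  nd <- skel$nodes
  e <- nd[!is.na(nd$parent_id), c("node_id", "parent_id")]
  w <- vapply(seq_len(nrow(e)), function(i) {
    a <- nd[nd$node_id == e$node_id[i], c("x", "y", "z")]
    b <- nd[nd$node_id == e$parent_id[i], c("x", "y", "z")]
    sqrt(sum((as.numeric(a) - as.numeric(b))^2))
  }, numeric(1))
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = nd$node_id)
  igraph::distances(g, v = skel$soma_node, to = skel$entry_node,
                    weights = w)[1, 1]
}

# random rooted tree skeleton with n nodes and random 3-D coordinates
random_tree_skeleton <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
    nd <- data.frame(node_id = as.character(seq_len(n)),
                     x = stats::runif(n, 0, 100),
                     y = stats::runif(n, 0, 100),
                     z = stats::runif(n, 0, 100),
                     parent_id = as.character(parent),
                     stringsAsFactors = FALSE)
    pair <- sample.int(n, 2)
    skeleton(nd, soma_node = as.character(pair[1]),
             entry_node = as.character(pair[2]), unit = "um")
  })
}
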