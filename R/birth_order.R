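# Birth-order proxy from skeleton morphology: geodesic cortex neurite
# length (soma to neuropil entry, measured along the skeleton) and its
# Pearson correlation with birth rank.

#' Cortex neurite length of a skeleton
#'
#' Along-skeleton (geodesic) distance between the soma node and the
#' neuropil-entry node: the sum of Euclidean segment lengths along the
#' unique tree path connecting them. This is the standard reconstruction
#' measurement "distance between two nodes"; it is invariant under rigid
#' motion of the coordinates and scales linearly with the unit.
#'
#' @param skel a [skeleton()].
#' @param unit report in the skeleton's native unit (`"native"`) or
#'   convert to micrometres (`"um"`, assuming nm coordinates when the
#'   skeleton unit is nm).
#' @return Non-negative length (0 when soma and entry coincide).
#' @export
cortex_neurite_length <- function(skel, unit = c("native", "um")) {
  unit <- match.arg(unit)
  stopifnot(inherits(skel, "skeleton"))
  nd <- skel$nodes
  pidx <- match(nd$parent_id, nd$node_id)
  coord <- as.matrix(nd[, c("x", "y", "z")])

  # path from a node up to the root: indices and cumulative edge lengths
  climb <- function(start) {
    path <- integer(0)
    len <- numeric(0)
    i <- match(start, nd$node_id)
    acc <- 0
    path <- i
    len <- 0
    while (!is.na(pidx[i])) {
      j <- pidx[i]
      acc <- acc + sqrt(sum((coord[i, ] - coord[j, ])^2))
      i <- j
      path <- c(path, i)
      len <- c(len, acc)
    }
    list(path = path, len = len)
  }
  a <- climb(skel$soma_node)
  b <- climb(skel$entry_node)
  # lowest common ancestor: first node of a's root path present in b's
  common <- a$path %in% b$path
  lca_pos_a <- which(common)[1]
  lca <- a$path[lca_pos_a]
  lca_pos_b <- which(b$path == lca)
  total <- a$len[lca_pos_a] + b$len[lca_pos_b]
  if (unit == "um" && skel$unit == "nm") total <- total / 1000
  total
}

#' Assemble a birth-order table
#'
#' One row per neuron with its birth rank and its cortex neurite length on
#' each available side; `length_avg` is the mean over non-missing sides
#' (falling back to the single available side, flagged via `one_sided`).
#'
#' @param neuron_id character vector.
#' @param birth_rank positive integer ranks (1 = first-born).
#' @param length_L,length_R per-side lengths (NA allowed).
#' @return A `birth_order_table` data.frame with `length_avg` and
#'   `one_sided` columns added.
#' @export
birth_order_table <- function(neuron_id, birth_rank, length_L = NA,
                              length_R = NA) {
  df <- data.frame(neuron_id = as.character(neuron_id),
                   birth_rank = as.integer(birth_rank),
                   length_L = as.numeric(length_L),
                   length_R = as.numeric(length_R),
                   stringsAsFactors = FALSE)
  if (any(!is.na(df$birth_rank) & df$birth_rank < 1)) {
    stop("birth_rank must be >= 1")
  }
  for (col in c("length_L", "length_R")) {
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) stop(col, " must be >= 0")
  }
  df$length_avg <- rowMeans(df[, c("length_L", "length_R")], na.rm = TRUE)
  df$length_avg[is.nan(df$length_avg)] <- NA_real_
  df$one_sided <- xor(is.na(df$length_L), is.na(df$length_R))
  class(df) <- c("birth_order_table", "data.frame")
  df
}

#' Pearson correlation between birth rank and cortex neurite length
#'
#' Standard product-moment correlation of (birth rank, length) with a
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#' Unit-invariant (nm vs um give identical r).
#'
#' @param t a [birth_order_table()].
#' @param which side to correlate: `"avg"`, `"L"`, or `"R"`.
#' @return List with `r`, `p`, `n` (complete pairs), `df` (n - 2).
#' @export
birth_order_correlation <- function(t, which = c("avg", "L", "R")) {
  which <- match.arg(which)
  col <- switch(which, avg = "length_avg", L = "length_L", R = "length_R")
  ok <- !is.na(t$birth_rank) & !is.na(t[[col]])
  x <- t$birth_rank[ok]
  y <- t[[col]][ok]
  if (length(x) < 3) stop("need at least 3 neurons with both rank and length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in rank or length; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = length(x) - 2L)
}
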