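# Pairwise Euclidean distance between neurons' synaptic input vectors,
# with an identity-shuffling permutation null, z-score normalisation, and
# similarity/difference significance calls. Binary and input-dropout
# variants, plus left-right / following-pair summaries.

#' Build the input matrix for a set of analysed neurons
#'
#' One row per analysed (postsynaptic) neuron; one column per presynaptic
#' neuron in the shared universe, which is the union of presynaptic ids
#' observed over the analysed set after dropout filtering (sorted ids, so
#' the input order is identical for every neuron and deterministic).
#' Columns that would be all-zero cannot occur by construction. Values are
#' synapse counts (`mode = "count"`) or presence bits (`mode = "binary"`).
#' Dropout restricts the presynaptic universe to sensory neurons only or
#' interneurons only (per catalog `source_type`), so similarity can be
#' assessed on each input category separately.
#'
#' @param sub a [synapse_table()] (typically from [inputs_onto()]).
#' @param analyzed character vector of analysed neuron ids (row order).
#' @param mode `"count"` or `"binary"`.
#' @param dropout `"none"`, `"sensory_only"`, or `"interneuron_only"`.
#' @param catalog a [neuron_catalog()]; required for dropout, and used to
#'   check that analysed neurons are known.
#' @return An `input_matrix`: integer matrix with `analyzed` rownames and
#'   universe colnames; attributes `mode`, `dropout`, and `flagged`
#'   (analysed neurons with an all-zero row).
#' @export
build_input_matrix <- function(sub, analyzed,
                               mode = c("count", "binary"),
                               dropout = c("none", "sensory_only",
                                           "interneuron_only"),
                               catalog = NULL) {
  mode <- match.arg(mode)
  dropout <- match.arg(dropout)
  analyzed <- as.character(analyzed)
  if (anyDuplicated(analyzed)) stop("duplicate analysed neuron ids")
  if (!is.null(catalog)) {
    missing_ids <- setdiff(analyzed, catalog$neuron_id)
    if (length(missing_ids) > 0) {
      stop("analysed neuron(s) absent from catalog: ",
           paste(missing_ids, collapse = ", "))
    }
  }
  rows <- sub[sub$post_id %in% analyzed, , drop = FALSE]
  if (dropout != "none") {
    if (is.null(catalog)) stop("dropout filtering requires a catalog")
    st <- .source_type_of(rows$pre_id, catalog)
    want <- if (dropout == "sensory_only") "sensory" else "interneuron"
    rows <- rows[st == want, , drop = FALSE]
  }
  universe <- sort(unique(rows$pre_id))
  m <- matrix(0L, nrow = length(analyzed), ncol = length(universe),
              dimnames = list(analyzed, universe))
  if (nrow(rows) > 0) {
    m[cbind(match(rows$post_id, analyzed), match(rows$pre_id, universe))] <-
      rows$count
  }
  if (mode == "binary") m[] <- as.integer(m > 0)
  flagged <- analyzed[rowSums(m) == 0]
  if (length(universe) == 0) {
    message("input matrix has an empty presynaptic universe after dropout")
  }
  structure(m, mode = mode, dropout = dropout, flagged = flagged,
            class = c("input_matrix", class(m)))
}

#' Pairwise Euclidean distances between input vectors
#'
#' `d(i, j) = sqrt(sum_k (m[i,k] - m[j,k])^2)` over the shared presynaptic
#' universe; symmetric with a zero diagonal.
#'
#' @param m numeric matrix (rows = analysed neurons).
#' @return Symmetric numeric matrix with the row labels of `m`.
#' @export
euclidean_distances <- function(m) {
  if (nrow(m) < 2) stop("need at least two analysed neurons")
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Permutation null for input-vector distances
#'
#' In each of `n_perm` permutations, every row of the input matrix is
#' independently shuffled across the universe columns (a uniform random
#' permutation of that row's entries). This preserves each neuron's
#' in-degree and per-partner synapse counts while randomising partner
#' identity. Pairwise Euclidean distances are computed on each shuffled
#' matrix; the per-pair sample mean and sample standard deviation
#' (n - 1 denominator) over permutations form the null.
#'
#' @param m input matrix (from [build_input_matrix()] or compatible).
#' @param n_perm number of permutations (default 100; must be >= 2, since
#'   the standard deviation is undefined below that).
#' @param seed integer seed; the global RNG state is left untouched.
#' @param keep_perms if TRUE, also return the `n_perm` per-pair distances.
#' @return List with `null_mean`, `null_sd` (symmetric matrices), `n_perm`,
#'   `seed`, and optionally `perm_distances` (array pair x pair x perm).
#' @export
shuffle_null <- function(m, n_perm = 100L, seed, keep_perms = FALSE) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 2) stop("n_perm must be at least 2 (sd undefined otherwise)")
  if (missing(seed)) stop("a seed is required for reproducibility")
  n <- nrow(m)
  labels <- rownames(m)
  s <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  perms <- if (keep_perms) array(NA_real_, dim = c(n, n, n_perm)) else NULL
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(n_perm)) {
      shuffled <- m
      for (i in seq_len(n)) {
        shuffled[i, ] <- m[i, sample.int(ncol(m))]
      }
      dm <- as.matrix(stats::dist(shuffled, method = "euclidean"))
      s <- s + dm
      s2 <- s2 + dm * dm
      if (keep_perms) perms[, , p] <- dm
    }
  })
  null_mean <- s / n_perm
  var_hat <- (s2 - n_perm * null_mean^2) / (n_perm - 1)
  var_hat[var_hat < 0] <- 0  # guard against tiny negative rounding
  null_sd <- sqrt(var_hat)
  dimnames(null_mean) <- dimnames(null_sd) <- list(labels, labels)
  out <- list(null_mean = null_mean, null_sd = null_sd, n_perm = n_perm,
              seed = as.integer(seed))
  if (keep_perms) out$perm_distances <- perms
  out
}

#' Normalise distances against the permutation null and call significance
#'
#' `z = (d - null_mean) / null_sd` elementwise. A pair whose real distance
#' is smaller than expected by chance (negative z) has more similar inputs
#' than chance; larger (positive z), more different. Two-tailed calls at
#' level `alpha`: `similar` when `z < -q`, `different` when `z > +q`, with
#' `q = qnorm(1 - alpha/2)` (1.96 at alpha = 0.05). Pairs with zero null
#' standard deviation get an undefined (NA) z, are flagged, and are never
#' called significant. The diagonal is excluded from all calls.
#'
#' @param d real distance matrix from [euclidean_distances()].
#' @param null_mean,null_sd matrices from [shuffle_null()].
#' @param alpha two-tailed significance level (default 0.05).
#' @return A `distance_result`: list with `d`, `null_mean`, `null_sd`, `z`,
#'   `similar`, `different`, `undefined` (logical matrices), `alpha`,
#'   `z_threshold`.
#' @export
zscore_and_call <- function(d, null_mean, null_sd, alpha = 0.05) {
  if (!all(dim(d) == dim(null_mean)) || !all(dim(d) == dim(null_sd))) {
    stop("distance and null matrices must have identical shapes")
  }
  q <- stats::qnorm(1 - alpha / 2)
  z <- (d - null_mean) / null_sd
  undefined <- null_sd == 0
  z[undefined] <- NA_real_
  off <- !diag(nrow = nrow(d))
  similar <- !is.na(z) & z < -q & off
  different <- !is.na(z) & z > q & off
  structure(list(d = d, null_mean = null_mean, null_sd = null_sd, z = z,
                 similar = similar, different = different,
                 undefined = undefined & off, alpha = alpha,
                 z_threshold = q),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  n <- nrow(x$d)
  npair <- n * (n - 1) / 2
  ut <- upper.tri(x$d)
  cat(sprintf("<distance_result> %d neurons, %d pairs: %d similar, %d different, %d undefined (alpha=%g, |z|>%.3f)\n",
              n, npair, sum(x$similar[ut]), sum(x$different[ut]),
              sum(x$undefined[ut]), x$alpha, x$z_threshold))
  invisible(x)
}

#' Full distance analysis on an edge table
#'
#' Convenience wrapper: builds the input matrix, computes real distances,
#' runs the permutation null, and makes significance calls. Identical
#' seed and inputs give a bit-identical result.
#'
#' @inheritParams build_input_matrix
#' @inheritParams shuffle_null
#' @inheritParams zscore_and_call
#' @return A `distance_result` with added `meta` (mode, dropout, universe
#'   size, n_perm, seed, alpha) and the `input_matrix`.
#' @export
distance_analysis <- function(sub, analyzed, catalog = NULL,
                              mode = c("count", "binary"),
                              dropout = c("none", "sensory_only",
                                          "interneuron_only"),
                              n_perm = 100L, seed, alpha = 0.05) {
  mode <- match.arg(mode)
  dropout <- match.arg(dropout)
  m <- build_input_matrix(sub, analyzed, mode = mode, dropout = dropout,
                          catalog = catalog)
  d <- euclidean_distances(m)
  null <- shuffle_null(m, n_perm = n_perm, seed = seed)
  res <- zscore_and_call(d, null$null_mean, null$null_sd, alpha = alpha)
  res$input_matrix <- m
  res$meta <- list(mode = mode, dropout = dropout,
                   n_analyzed = nrow(m), universe_size = ncol(m),
                   n_perm = null$n_perm, seed = null$seed, alpha = alpha,
                   flagged_zero_input = attr(m, "flagged"))
  res
}

#' Left-right and following-pair z-score summaries
#'
#' Extracts, regardless of significance, the z-score of every left-right
#' homolog pair (the same neuron in the left and right hemisegment) and
#' every following pair (neurons with consecutive birth orders in the same
#' lineage, hemilineage, and hemisegment) among the analysed neurons,
#' grouped by cohort. Intended for binary-mode results, where partner
#' identity rather than synapse weight drives the score. Midline neurons
#' (homolog = self) are excluded from left-right pairs; neurons without a
#' birth order are skipped from following pairs.
#'
#' @param result a `distance_result` whose matrices are labeled by neuron id.
#' @param catalog a [neuron_catalog()] supplying homolog_id, birth_order,
#'   lineage, hemilineage, side, segment, and cohort.
#' @return data.frame: `pair_type` (`left_right` / `following`), `id_a`,
#'   `id_b`, `cohort`, `z`, `significant_similar`; attribute
#'   `z_threshold` carries the reference line.
#' @export
pair_summaries <- function(result, catalog) {
  ids <- rownames(result$z)
  idx <- match(ids, catalog$neuron_id)
  if (anyNA(idx)) {
    stop("analysed neuron(s) absent from catalog: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  info <- catalog[idx, ]
  rows <- list()
  emit <- function(type, a, b) {
    ca <- info$cohort[info$neuron_id == a]
    cb <- info$cohort[info$neuron_id == b]
    cohort <- if (!is.na(ca) && !is.na(cb) && ca == cb) ca else "mixed"
    rows[[length(rows) + 1L]] <<- data.frame(
      pair_type = type, id_a = a, id_b = b, cohort = cohort,
      z = result$z[a, b],
      significant_similar = isTRUE(result$similar[a, b]),
      stringsAsFactors = FALSE)
  }
  # left-right pairs
  for (i in seq_along(ids)) {
    a <- ids[i]
    h <- info$homolog_id[i]
    if (is.na(h) || h == a || !h %in% ids) next
    if (a < h) emit("left_right", a, h)
  }
  # following pairs: consecutive birth order within lineage/hemilineage/side
  has_bo <- !is.na(info$birth_order)
  grp <- paste(info$lineage, info$hemilineage, info$side, info$segment,
               sep = "|")
  for (g in unique(grp[has_bo])) {
    sel <- which(grp == g & has_bo)
    sel <- sel[order(info$birth_order[sel])]
    if (length(sel) < 2) next
    for (k in seq_len(length(sel) - 1)) {
      i <- sel[k]; j <- sel[k + 1]
      if (info$birth_order[j] == info$birth_order[i] + 1L) {
        emit("following", ids[i], ids[j])
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pair_type = character(0), id_a = character(0),
               id_b = character(0), cohort = character(0), z = numeric(0),
               significant_similar = logical(0), stringsAsFactors = FALSE)
  attr(out, "z_threshold") <- -result$z_threshold
  out
}
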