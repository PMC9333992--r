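# Core domain containers: neuron catalog, synapse table, skeleton.
# All are plain data.frames / lists with a light S3 class for printing and
# validation; no computation here beyond consistency checks.

CATALOG_COLUMNS <- c(
  "neuron_id", "name", "side", "segment", "source_type", "sensory_class",
  "morph_class", "lineage", "hemilineage", "birth_order", "cohort",
  "homolog_id"
)

SOURCE_TYPES <- c("interneuron", "sensory", "brain_or_SEZ", "unknown_fragment")
SENSORY_CLASSES <- c("chordotonal", "proprioceptive", "other")

#' Ordered segment labels of the larval nerve cord
#'
#' Fixed anterior-to-posterior ordering (three thoracic, ten abdominal
#' segments) used wherever "anterior/posterior" logic is needed.
#'
#' @return Character vector `c("T1","T2","T3","A1",...,"A10")`.
#' @export
segment_levels <- function() {
  c("T1", "T2", "T3", paste0("A", 1:10))
}

#' Build a neuron annotation catalog
#'
#' Normalises a data.frame of per-neuron annotations into the canonical
#' catalog layout. Missing optional columns are added as NA; empty strings
#' are converted to NA. `birth_order` is coerced to integer.
#'
#' @param df data.frame with at least a `neuron_id` column; recognised
#'   columns are `r paste(CATALOG_COLUMNS, collapse = ", ")`.
#' @return A `neuron_catalog` (data.frame with the canonical columns).
#' @export
neuron_catalog <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"neuron_id" %in% names(df)) {
    stop("catalog must have a 'neuron_id' column")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in setdiff(CATALOG_COLUMNS, names(df))) {
    df[[col]] <- rep(NA_character_, nrow(df))
  }
  df <- df[, CATALOG_COLUMNS]
  chr_cols <- setdiff(CATALOG_COLUMNS, "birth_order")
  for (col in chr_cols) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[col]] <- v
  }
  bo <- df$birth_order
  bo[!is.na(bo) & bo == ""] <- NA
  df$birth_order <- as.integer(bo)
  rownames(df) <- NULL
  class(df) <- c("neuron_catalog", "data.frame")
  df
}

#' Build a synapse (edge) table
#'
#' Directed weighted edge list: one row per (presynaptic, postsynaptic)
#' neuron pair with a positive integer synapse count. Duplicate
#' (pre, post) rows are summed into one row with a warning, matching how
#' per-synapse reconstruction exports are aggregated.
#'
#' @param df data.frame with columns `pre_id`, `post_id`, `count`.
#' @param aggregate sum duplicate (pre, post) rows (default TRUE); with
#'   FALSE duplicates raise an error.
#' @return A `synapse_table` (data.frame with `pre_id`, `post_id`, `count`).
#' @export
synapse_table <- function(df, aggregate = TRUE) {
  stopifnot(is.data.frame(df))
  need <- c("pre_id", "post_id", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("edge table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    pre_id = as.character(df$pre_id),
    post_id = as.character(df$post_id),
    count = df$count,
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) {
    cnt <- df$count
    if (any(is.na(cnt)) || any(cnt != as.integer(cnt)) || any(cnt < 1)) {
      bad <- which(is.na(cnt) | cnt != round(cnt) | cnt < 1)[1]
      stop(sprintf("synapse count must be a positive integer (row %d: %s)",
                   bad, as.character(df$count[bad])))
    }
    df$count <- as.integer(cnt)
    key <- paste(df$pre_id, df$post_id, sep = "\r")
    if (anyDuplicated(key)) {
      if (!aggregate) {
        stop("duplicate (pre_id, post_id) rows present and aggregate = FALSE")
      }
      warning("duplicate (pre_id, post_id) rows summed during aggregation")
      agg <- rowsum(df$count, key, reorder = FALSE)
      first <- !duplicated(key)
      df <- df[first, ]
      df$count <- as.integer(agg[match(paste(df$pre_id, df$post_id, sep = "\r"),
                                       rownames(agg)), 1])
    }
  } else {
    df$count <- integer(0)
  }
  rownames(df) <- NULL
  class(df) <- c("synapse_table", "data.frame")
  df
}

#' Build a skeleton object
#'
#' Rooted tree of 3-D nodes (coordinates in the stated length unit) with a
#' marked soma node and neuropil-entry node. Enforces the single-tree
#' invariants: exactly one root, all parents resolvable, no cycles.
#'
#' @param nodes data.frame with columns `node_id`, `x`, `y`, `z`,
#'   `parent_id` (NA for the root).
#' @param soma_node,entry_node node ids; must be members of `nodes`.
#' @param unit length unit of the coordinates, `"nm"` or `"um"`.
#' @return A `skeleton` object (list with `nodes`, `soma_node`,
#'   `entry_node`, `unit`).
#' @export
skeleton <- function(nodes, soma_node, entry_node, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(nodes))
  need <- c("node_id", "x", "y", "z", "parent_id")
  if (!all(need %in% names(nodes))) {
    stop("skeleton nodes need columns: ", paste(need, collapse = ", "))
  }
  nodes <- data.frame(
    node_id = as.character(nodes$node_id),
    x = as.numeric(nodes$x), y = as.numeric(nodes$y), z = as.numeric(nodes$z),
    parent_id = as.character(nodes$parent_id),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node ids in skeleton")
  }
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1) {
    stop(sprintf("skeleton must have exactly one root, found %d", length(roots)))
  }
  known <- nodes$node_id
  parents <- nodes$parent_id[!is.na(nodes$parent_id)]
  orphan <- setdiff(parents, known)
  if (length(orphan) > 0) {
    stop("node(s) reference absent parent: ", paste(orphan, collapse = ", "))
  }
  # cycle / connectivity check: walk every node to the root
  pidx <- match(nodes$parent_id, nodes$node_id)
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    steps <- 0L
    j <- i
    while (!is.na(pidx[j])) {
      j <- pidx[j]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in skeleton node graph")
    }
  }
  soma_node <- as.character(soma_node)
  entry_node <- as.character(entry_node)
  if (!soma_node %in% known) stop("soma_node not in node set: ", soma_node)
  if (!entry_node %in% known) stop("entry_node not in node set: ", entry_node)
  structure(
    list(nodes = nodes, soma_node = soma_node, entry_node = entry_node,
         unit = unit),
    class = "skeleton"
  )
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes (%s), soma=%s entry=%s\n",
              nrow(x$nodes), x$unit, x$soma_node, x$entry_node))
  invisible(x)
}

#' Validate a catalog against a synapse table
#'
#' Consistency report covering: duplicate neuron ids, asymmetric or
#' dangling homolog links, midline (side M) neurons whose homolog is not
#' themselves, duplicate birth orders within a (lineage, hemilineage,
#' side) group, non-positive synapse counts, duplicate (pre, post) edge
#' rows, and edge endpoints that resolve neither to the catalog nor to an
#' `unknown_fragment` record.
#'
#' The report is independent of row order in either input.
#'
#' @param catalog a [neuron_catalog()].
#' @param table a [synapse_table()].
#' @return A `validation_report`: list with `pass` (logical) and `issues`
#'   (data.frame with columns `issue`, `detail`).
#' @export
validate_catalog <- function(catalog, table) {
  catalog <- neuron_catalog(catalog)
  issues <- list()
  add <- function(issue, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      issue = issue, detail = detail, stringsAsFactors = FALSE)
  }

  dup <- sort(unique(catalog$neuron_id[duplicated(catalog$neuron_id)]))
  for (id in dup) add("duplicate_neuron_id", id)

  ids <- catalog$neuron_id
  hom <- catalog$homolog_id
  midline <- !is.na(catalog$side) & catalog$side == "M"
  bad_mid <- midline & (is.na(hom) | hom != ids)
  for (id in sort(ids[bad_mid])) add("midline_homolog_not_self", id)

  has_hom <- !is.na(hom)
  back <- hom[match(hom, ids)]  # homolog of each neuron's homolog
  dangling <- has_hom & !(hom %in% ids)
  for (id in sort(ids[dangling])) add("dangling_homolog_id", id)
  asym <- has_hom & (hom %in% ids) & (is.na(back) | back != ids)
  for (id in sort(ids[asym])) add("asymmetric_homolog", id)

  bo <- catalog$birth_order
  has_bo <- !is.na(bo)
  if (any(has_bo & bo < 1)) {
    for (id in sort(ids[has_bo & bo < 1])) add("birth_order_below_one", id)
  }
  grp <- paste(catalog$lineage, catalog$hemilineage, catalog$side, sep = "|")
  key <- paste(grp, bo, sep = "#")[has_bo]
  dup_bo <- unique(key[duplicated(key)])
  for (k in sort(dup_bo)) add("duplicate_birth_order", k)

  if (nrow(table) > 0) {
    if (any(table$count < 1)) {
      bad <- which(table$count < 1)
      for (i in bad) add("non_positive_count",
                         paste(table$pre_id[i], table$post_id[i], sep = "->"))
    }
    ekey <- paste(table$pre_id, table$post_id, sep = "->")
    for (k in sort(unique(ekey[duplicated(ekey)]))) add("duplicate_edge", k)
    endpoints <- sort(unique(c(table$pre_id, table$post_id)))
    unresolved <- setdiff(endpoints, ids)
    for (id in unresolved) add("dangling_edge_endpoint", id)
  }

  issues_df <- if (length(issues) > 0) {
    do.call(rbind, issues)
  } else {
    data.frame(issue = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  }
  issues_df <- issues_df[order(issues_df$issue, issues_df$detail), ,
                         drop = FALSE]
  rownames(issues_df) <- NULL
  structure(list(pass = nrow(issues_df) == 0, issues = issues_df),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s, %d issue(s)\n",
              if (x$pass) "PASS" else "FAIL", nrow(x$issues)))
  if (nrow(x$issues) > 0) print(x$issues)
  invisible(x)
}
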