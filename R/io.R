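# Readers and writers for the plain-text formats the pipeline touches:
# annotation catalog CSV, edge-table CSV, SWC skeletons (+ companion
# entry-node map), and labeled square matrices. CSV dialect is comma
# separated, UTF-8, "." decimal, ids unquoted; empty string means missing.

#' Read a neuron annotation catalog CSV
#'
#' Expected header: `neuron_id,name,side,segment,source_type,sensory_class,
#' morph_class,lineage,hemilineage,birth_order,cohort,homolog_id`.
#' Empty fields become NA.
#'
#' @param path path to the CSV file.
#' @return A [neuron_catalog()].
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"neuron_id" %in% names(df)) {
    stop("catalog file lacks a 'neuron_id' column: ", path)
  }
  neuron_catalog(df)
}

#' Write a neuron annotation catalog CSV
#'
#' @param catalog a [neuron_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a synaptic edge table CSV
#'
#' Expected header: `pre_id,post_id,count`. Duplicate (pre, post) rows are
#' summed into one row (with a warning). Counts must be positive integers;
#' offending lines are reported by file line number (header = line 1).
#'
#' @param path path to the CSV file.
#' @return A [synapse_table()].
#' @export
read_edge_table <- function(path) {
  if (!file.exists(path)) stop("edge table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pre_id", "post_id", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("edge table %s missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) > 0) {
    cnt <- suppressWarnings(as.numeric(df$count))
    bad <- which(is.na(cnt) | cnt != round(cnt) | cnt < 1)
    if (length(bad) > 0) {
      stop(sprintf("invalid synapse count '%s' at line %d of %s (must be a positive integer)",
                   as.character(df$count[bad[1]]), bad[1] + 1L, path))
    }
    df$count <- as.integer(cnt)
  }
  tab <- synapse_table(df, aggregate = TRUE)
  message(sprintf("read %d edge row(s), %d total synapses from %s",
                  nrow(tab), sum(tab$count), path))
  tab
}

#' Write a synaptic edge table CSV
#'
#' @param table a [synapse_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a neuron skeleton from an SWC file
#'
#' SWC: whitespace-separated columns `id type x y z radius parent`, with
#' `parent = -1` marking the single root. Comment lines start with `#`.
#' The soma is the first node carrying `soma_marker` as its structure
#' type; the neuropil-entry node is supplied explicitly (typically from a
#' companion map, see [read_entry_map()]). The radius column is parsed
#' and ignored. Coordinates are taken to be in `unit` (reconstruction
#' exports conventionally use nanometres).
#'
#' @param path SWC file path.
#' @param entry_node node id of the neuropil-entry node.
#' @param soma_marker SWC structure-type code treated as soma (default 1).
#' @param unit coordinate unit, `"nm"` (default) or `"um"`.
#' @return A [skeleton()].
#' @export
read_skeleton <- function(path, entry_node, soma_marker = 1L,
                          unit = c("nm", "um")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("SWC file has no node records: ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    stop(sprintf("malformed SWC record (expected 7 fields) at node line %d of %s",
                 which(nf != 7)[1], path))
  }
  m <- do.call(rbind, fields)
  nodes <- data.frame(
    node_id = m[, 1],
    x = as.numeric(m[, 3]), y = as.numeric(m[, 4]), z = as.numeric(m[, 5]),
    parent_id = ifelse(m[, 7] == "-1", NA_character_, m[, 7]),
    stringsAsFactors = FALSE
  )
  type <- as.integer(m[, 2])
  soma_idx <- which(type == soma_marker)
  if (length(soma_idx) == 0) {
    stop(sprintf("no node with soma structure type %d in %s", soma_marker, path))
  }
  skeleton(nodes, soma_node = nodes$node_id[soma_idx[1]],
           entry_node = entry_node, unit = unit)
}

#' Read a neuropil-entry-node companion map
#'
#' CSV with header `neuron_id,entry_node` mapping each skeleton to the
#' node id (chosen during reconstruction) where it enters the neuropil.
#'
#' @param path CSV path.
#' @return Named character vector: entry node id per neuron id.
#' @export
read_entry_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("neuron_id", "entry_node")
  if (!all(need %in% names(df))) {
    stop("entry map needs columns neuron_id, entry_node: ", path)
  }
  stats::setNames(df$entry_node, df$neuron_id)
}

#' Write a skeleton to an SWC file
#'
#' The soma node is written with structure type 1, all others with type 0.
#'
#' @param skel a [skeleton()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  stopifnot(inherits(skel, "skeleton"))
  nd <- skel$nodes
  type <- ifelse(nd$node_id == skel$soma_node, 1L, 0L)
  parent <- ifelse(is.na(nd$parent_id), "-1", nd$parent_id)
  rec <- sprintf("%s %d %.6g %.6g %.6g 1 %s",
                 nd$node_id, type, nd$x, nd$y, nd$z, parent)
  writeLines(c("# SWC id type x y z radius parent", rec), path)
  invisible(path)
}

#' Write a labeled square matrix as CSV
#'
#' Row and column labels are preserved; values round-trip through
#' [read_labeled_matrix()] to at least 12 significant digits.
#'
#' @param m square numeric matrix with identical, unique row/col names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  labels <- rownames(m)
  if (nrow(m) > 0) {
    if (is.null(labels) || is.null(colnames(m))) {
      stop("matrix must carry row and column labels")
    }
    if (anyDuplicated(labels) || anyDuplicated(colnames(m))) {
      stop("matrix labels must be unique")
    }
    if (!identical(labels, colnames(m))) {
      stop("row and column labels must match for a square labeled matrix")
    }
  }
  header <- paste(c("", colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(labels[i], formatC(m[i, ], format = "g", digits = 15)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a labeled square matrix written by [write_labeled_matrix()]
#'
#' @param path CSV path.
#' @return Numeric matrix with row/column labels.
#' @export
read_labeled_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  labels <- header[-1]
  n <- length(lines) - 1L
  m <- matrix(NA_real_, nrow = n, ncol = length(labels),
              dimnames = list(character(n), labels))
  rn <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    rn[i] <- f[1]
    v <- trimws(f[-1])
    v[v == "NA"] <- NA_character_
    m[i, ] <- as.numeric(v)
  }
  rownames(m) <- rn
  m
}
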