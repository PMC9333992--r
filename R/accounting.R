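# Input accounting on a chosen target neuron set: source-type composition,
# per-target sensory breakdown, synapse-count histograms with a
# Kolmogorov-Smirnov comparison, the left-right pairing filter, the
# highly-connected filter, and morphological class composition.

#' Define a target neuron set
#'
#' The targets are the postsynaptic neurons whose inputs are analysed,
#' e.g. every neuron of one lineage in the left and right hemisegments.
#' `homolog_map` pairs each left-side target with its right-side
#' (hemisegmentally homologous) copy; it is required by the pairing and
#' highly-connected filters.
#'
#' @param name label for the set.
#' @param members character vector of target neuron ids (ordered).
#' @param homolog_map optional data.frame with columns `left`, `right`
#'   pairing homologous targets; every id must be a member.
#' @return A `target_set` object.
#' @export
target_set <- function(name, members, homolog_map = NULL) {
  members <- as.character(members)
  if (length(members) == 0) stop("target set must have at least one member")
  if (anyDuplicated(members)) stop("duplicate target ids")
  if (!is.null(homolog_map)) {
    stopifnot(is.data.frame(homolog_map),
              all(c("left", "right") %in% names(homolog_map)))
    homolog_map <- data.frame(left = as.character(homolog_map$left),
                              right = as.character(homolog_map$right),
                              stringsAsFactors = FALSE)
    unknown <- setdiff(c(homolog_map$left, homolog_map$right), members)
    if (length(unknown) > 0) {
      stop("homolog_map references non-member id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(name = name, members = members, homolog_map = homolog_map),
            class = "target_set")
}

#' Restrict a synapse table to inputs onto a target set
#'
#' @param table a [synapse_table()].
#' @param targets a [target_set()], or a character vector of target ids.
#' @return The sub-table of rows with `post_id` in the target set, with
#'   attributes `total_synapses` and `n_sources` (distinct presynaptic
#'   ids); also retrievable via [input_summary()].
#' @export
inputs_onto <- function(table, targets) {
  members <- if (inherits(targets, "target_set")) targets$members
             else as.character(targets)
  sub <- table[table$post_id %in% members, , drop = FALSE]
  rownames(sub) <- NULL
  class(sub) <- c("synapse_table", "data.frame")
  attr(sub, "total_synapses") <- sum(sub$count)
  attr(sub, "n_sources") <- length(unique(sub$pre_id))
  sub
}

#' Summary counts of an input sub-table
#'
#' @param sub a sub-table from [inputs_onto()].
#' @return List with `total_synapses` and `n_sources`.
#' @export
input_summary <- function(sub) {
  list(total_synapses = sum(sub$count),
       n_sources = length(unique(sub$pre_id)))
}

.source_type_of <- function(ids, catalog) {
  st <- catalog$source_type[match(ids, catalog$neuron_id)]
  st[is.na(st)] <- "unknown_fragment"
  st
}

#' Composition of inputs by source type
#'
#' Tallies synapses by presynaptic source type (interneuron, sensory,
#' brain/SEZ, unknown fragment). Presynaptic ids absent from the catalog
#' are counted as `unknown_fragment`. Percentages are over total synapses
#' and sum to exactly 100 before rounding.
#'
#' @param sub input sub-table from [inputs_onto()].
#' @param catalog a [neuron_catalog()].
#' @return data.frame: `source_type`, `n_neurons`, `n_synapses`,
#'   `percent` (raw), `percent_rounded` (nearest integer).
#' @export
compose_by_source_type <- function(sub, catalog) {
  st <- .source_type_of(sub$pre_id, catalog)
  types <- unique(c(SOURCE_TYPES, st))
  n_syn <- vapply(types, function(t) sum(sub$count[st == t]), numeric(1))
  n_neu <- vapply(types, function(t) length(unique(sub$pre_id[st == t])),
                  numeric(1))
  total <- sum(sub$count)
  pct <- if (total > 0) 100 * n_syn / total else rep(0, length(types))
  data.frame(source_type = types, n_neurons = as.integer(n_neu),
             n_synapses = as.integer(n_syn), percent = pct,
             percent_rounded = round(pct), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-target sensory input fractions by sensory class
#'
#' For each target neuron, the fraction of its total synaptic input that
#' comes from each sensory class (chordotonal, proprioceptive, other).
#' Fractions per neuron sum to at most 1; the remainder is non-sensory
#' input. Targets with zero input are reported with zero fractions and
#' `no_input = TRUE`.
#'
#' @param sub input sub-table from [inputs_onto()].
#' @param catalog a [neuron_catalog()].
#' @param targets a [target_set()].
#' @return data.frame: one row per (target, sensory class) with `fraction`,
#'   plus `total_input` and `no_input` per target.
#' @export
sensory_breakdown <- function(sub, catalog, targets) {
  members <- targets$members
  st <- .source_type_of(sub$pre_id, catalog)
  sclass <- catalog$sensory_class[match(sub$pre_id, catalog$neuron_id)]
  out <- list()
  for (t in members) {
    rows <- sub$post_id == t
    total <- sum(sub$count[rows])
    for (cl in SENSORY_CLASSES) {
      syn <- sum(sub$count[rows & st == "sensory" & !is.na(sclass) &
                           sclass == cl])
      out[[length(out) + 1L]] <- data.frame(
        target = t, sensory_class = cl,
        fraction = if (total > 0) syn / total else 0,
        total_input = total, no_input = total == 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Define a synapse-count histogram binning
#'
#' Bins are labeled integer intervals that are disjoint and exhaustive
#' above `starts[1]`; the last bin is open-ended (`"k+"`). Values below
#' `starts[1]` fall into an explicit underflow bucket.
#'
#' @param starts strictly increasing integer left edges; bin i covers
#'   `[starts[i], starts[i+1] - 1]`, the last bin `[starts[n], Inf)`.
#' @return A `histogram_spec` object.
#' @examples
#' histogram_spec(1:10)            # bins 1,2,...,9,10+
#' histogram_spec(seq(0, 45, 5))   # bins 0-4, 5-9, ..., 45+
#' @export
histogram_spec <- function(starts) {
  starts <- as.integer(starts)
  if (length(starts) < 1 || any(diff(starts) <= 0)) {
    stop("bin starts must be strictly increasing")
  }
  labels <- character(length(starts))
  n <- length(starts)
  for (i in seq_len(n - 1)) {
    hi <- starts[i + 1] - 1L
    labels[i] <- if (hi == starts[i]) as.character(starts[i])
                 else paste0(starts[i], "-", hi)
  }
  labels[n] <- paste0(starts[n], "+")
  structure(list(starts = starts, labels = labels), class = "histogram_spec")
}

#' Histogram of synapse counts
#'
#' With `per = "edge"` each (presynaptic neuron, target) contact count is
#' one item; with `per = "source_pooled"` each presynaptic neuron's summed
#' synapses over the whole target set is one item. Values below the lowest
#' bin start are counted in an explicit `underflow` bucket (with a
#' message).
#'
#' @param sub input sub-table from [inputs_onto()].
#' @param spec a [histogram_spec()].
#' @param per binning unit, `"edge"` or `"source_pooled"`.
#' @return data.frame with `bin`, `n` (and an `underflow` attribute);
#'   bin counts plus underflow sum to the number of binned items.
#' @export
synapse_histogram <- function(sub, spec,
                              per = c("edge", "source_pooled")) {
  per <- match.arg(per)
  stopifnot(inherits(spec, "histogram_spec"))
  values <- if (per == "edge") {
    sub$count
  } else if (nrow(sub) > 0) {
    as.integer(rowsum(sub$count, sub$pre_id)[, 1])
  } else {
    integer(0)
  }
  under <- sum(values < spec$starts[1])
  if (under > 0) {
    message(sprintf("%d value(s) below lowest bin start counted as underflow",
                    under))
  }
  idx <- findInterval(values, spec$starts)
  n <- vapply(seq_along(spec$starts), function(i) sum(idx == i), integer(1))
  out <- data.frame(bin = spec$labels, n = n, stringsAsFactors = FALSE)
  attr(out, "underflow") <- under
  attr(out, "values") <- values
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of synapse-count samples
#'
#' Two-sided test on the raw per-neuron synapse totals (not the binned
#' histogram). The exact p-value is used when both samples have at most
#' 25 observations and no ties across samples; otherwise the asymptotic
#' formula is used (ties are common in synapse counts, and the exact
#' computation is undefined with ties).
#'
#' @param a,b non-empty integer vectors of synapse counts.
#' @return List with `D` (statistic in `[0, 1]`) and `p`.
#' @export
ks_compare <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty")
  }
  exact <- length(a) <= 25 && length(b) <= 25 &&
    !anyDuplicated(c(a, b))
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = res$p.value)
}

.homolog_of <- function(ids, catalog) {
  catalog$homolog_id[match(ids, catalog$neuron_id)]
}

# synapse count from one presynaptic id onto one target id (0 if absent)
.count_lookup <- function(sub) {
  key <- paste(sub$pre_id, sub$post_id, sep = "\r")
  cnt <- stats::setNames(sub$count, key)
  function(pre, post) {
    v <- cnt[paste(pre, post, sep = "\r")]
    ifelse(is.na(v), 0L, v)
  }
}

#' Left-right paired interneuron filter
#'
#' Retains candidate presynaptic interneurons organised as left-right
#' homolog pairs (or unpaired midline neurons) that clear a two-sided
#' synapse-count threshold onto a homologous target pair: one member must
#' form at least `thr_high` synapses onto a target and the other member at
#' least `thr_low` synapses onto the hemisegmentally homologous target.
#' Either member may carry the high count. Midline neurons (side M) are
#' evaluated with themselves in both roles against the two homologous
#' targets. Candidates with missing side/homolog annotation are excluded
#' and listed in the `skipped` component.
#'
#' @param sub input sub-table from [inputs_onto()].
#' @param catalog a [neuron_catalog()].
#' @param targets a [target_set()] with a `homolog_map`.
#' @param thr_high,thr_low synapse thresholds (defaults 4 and 2).
#' @return A `paired_input_set`: list with `pairs` (data.frame of retained
#'   pairs and qualifying evidence), `neuron_ids` (all retained
#'   interneuron ids), `total_neurons`, `total_synapses` (their summed
#'   synapses onto the target set), and `skipped`.
#' @export
lr_pair_filter <- function(sub, catalog, targets, thr_high = 4L,
                           thr_low = 2L) {
  if (is.null(targets$homolog_map)) {
    stop("target set lacks a homolog_map; pairing filter needs homologous targets")
  }
  st <- .source_type_of(sub$pre_id, catalog)
  cand <- unique(sub$pre_id[st == "interneuron"])
  side <- catalog$side[match(cand, catalog$neuron_id)]
  hom <- .homolog_of(cand, catalog)
  skipped <- cand[is.na(side) | (side != "M" & is.na(hom))]
  cand <- setdiff(cand, skipped)
  side <- catalog$side[match(cand, catalog$neuron_id)]
  hom <- .homolog_of(cand, catalog)

  cnt <- .count_lookup(sub)
  hmap <- targets$homolog_map
  # evaluate each unordered candidate pair once
  pair_key <- ifelse(side == "M", cand,
                     paste(pmin(cand, hom), pmax(cand, hom), sep = "\r"))
  seen <- !duplicated(pair_key)
  rows <- list()
  for (i in which(seen)) {
    p1 <- cand[i]
    p2 <- if (side[i] == "M") p1 else hom[i]
    best <- NULL
    for (j in seq_len(nrow(hmap))) {
      tl <- hmap$left[j]; tr <- hmap$right[j]
      combos <- rbind(
        c(cnt(p1, tl), cnt(p2, tr)),
        c(cnt(p1, tr), cnt(p2, tl)),
        c(cnt(p2, tl), cnt(p1, tr)),
        c(cnt(p2, tr), cnt(p1, tl))
      )
      ok <- combos[, 1] >= thr_high & combos[, 2] >= thr_low
      if (any(ok)) {
        k <- which(ok)[1]
        ev <- combos[k, ]
        if (is.null(best) || max(ev) > max(best)) best <- ev
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        member_1 = p1, member_2 = p2, midline = side[i] == "M",
        count_high = max(best), count_low = min(best),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(member_1 = character(0), member_2 = character(0),
               midline = logical(0), count_high = integer(0),
               count_low = integer(0), stringsAsFactors = FALSE)
  ids <- unique(c(pairs$member_1, pairs$member_2))
  structure(list(
    pairs = pairs,
    neuron_ids = sort(ids),
    total_neurons = length(ids),
    total_synapses = sum(sub$count[sub$pre_id %in% ids]),
    skipped = sort(skipped),
    thr_high = thr_high, thr_low = thr_low
  ), class = "paired_input_set")
}

#' @export
print.paired_input_set <- function(x, ...) {
  cat(sprintf("<paired_input_set> %d retained interneuron(s), %d synapse(s) (thr %d/%d), %d skipped\n",
              x$total_neurons, x$total_synapses, x$thr_high, x$thr_low,
              length(x$skipped)))
  invisible(x)
}

#' Highly connected presynaptic neurons
#'
#' A sensory neuron or interneuron is highly connected when at least one
#' member of its left-right pair (or the midline neuron itself) makes
#' `min_syn` or more summed synapses onto the target set. Returns both the
#' individually qualifying ids and the pair-expanded member set, plus the
#' class/lineage composition of the retained neurons.
#'
#' @param sub input sub-table from [inputs_onto()].
#' @param catalog a [neuron_catalog()].
#' @param targets a [target_set()] (used only for reporting).
#' @param min_syn threshold on summed synapses (default 10).
#' @return List with `qualifying` (ids with >= min_syn synapses),
#'   `members` (qualifying plus their homologs that also synapse onto the
#'   targets), and `composition` (data.frame by morph_class and lineage).
#' @export
highly_connected <- function(sub, catalog, targets, min_syn = 10L) {
  st <- .source_type_of(sub$pre_id, catalog)
  keep <- st %in% c("interneuron", "sensory")
  sub2 <- sub[keep, , drop = FALSE]
  if (nrow(sub2) == 0) {
    return(list(qualifying = character(0), members = character(0),
                composition = data.frame(morph_class = character(0),
                                         lineage = character(0),
                                         n_neurons = integer(0),
                                         n_synapses = integer(0),
                                         stringsAsFactors = FALSE)))
  }
  totals <- rowsum(sub2$count, sub2$pre_id)
  per_src <- stats::setNames(as.integer(totals[, 1]), rownames(totals))
  qualifying <- names(per_src)[per_src >= min_syn]
  hom <- .homolog_of(qualifying, catalog)
  members <- sort(unique(c(qualifying,
                           hom[!is.na(hom) & hom %in% names(per_src)])))
  cls <- catalog$morph_class[match(members, catalog$neuron_id)]
  cls[is.na(cls)] <- "other"
  lin <- catalog$lineage[match(members, catalog$neuron_id)]
  lin[is.na(lin)] <- "unknown"
  grp <- paste(cls, lin, sep = "\r")
  comp <- do.call(rbind, lapply(unique(grp), function(g) {
    idx <- grp == g
    data.frame(morph_class = cls[idx][1], lineage = lin[idx][1],
               n_neurons = sum(idx),
               n_synapses = sum(per_src[members[idx]]),
               stringsAsFactors = FALSE)
  }))
  rownames(comp) <- NULL
  list(qualifying = sort(qualifying), members = members, composition = comp,
       per_source_totals = per_src, min_syn = min_syn)
}

#' Composition of inputs by morphological class
#'
#' Percentage of total synapses (and distinct presynaptic neuron count)
#' contributed by each morphological class; presynaptic neurons without a
#' class annotation, or with a class outside `classes`, fall into
#' `"other"`.
#'
#' @param sub input sub-table from [inputs_onto()].
#' @param catalog a [neuron_catalog()].
#' @param classes optional character vector of classes to report
#'   individually (default: all classes present).
#' @return data.frame: `morph_class`, `n_neurons`, `n_synapses`,
#'   `percent`, `percent_rounded`.
#' @export
class_composition <- function(sub, catalog, classes = NULL) {
  cls <- catalog$morph_class[match(sub$pre_id, catalog$neuron_id)]
  cls[is.na(cls)] <- "other"
  if (!is.null(classes)) {
    cls[!cls %in% classes] <- "other"
    levels <- unique(c(classes, "other"))
  } else {
    levels <- unique(cls)
  }
  total <- sum(sub$count)
  out <- do.call(rbind, lapply(levels, function(cl) {
    idx <- cls == cl
    syn <- sum(sub$count[idx])
    data.frame(morph_class = cl,
               n_neurons = length(unique(sub$pre_id[idx])),
               n_synapses = syn,
               percent = if (total > 0) 100 * syn / total else 0,
               stringsAsFactors = FALSE)
  }))
  out$percent_rounded <- round(out$percent)
  rownames(out) <- NULL
  out
}
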