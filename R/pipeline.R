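# Config-driven end-to-end orchestration: validate -> input accounting ->
# distance analysis (count + binary, optional dropouts) -> pair summaries
# -> birth order, with per-stage CSV outputs and a consolidated
# report.json carrying every headline number and full provenance.

#' Run the full analysis pipeline
#'
#' Executes, in order: catalog/edge validation, input accounting onto the
#' target set (totals, source-type composition, synapse histogram,
#' left-right pairing filter, highly-connected filter, class composition),
#' distance analysis in count and binary modes (plus sensory-only and
#' interneuron-only dropouts when enabled), left-right / following pair
#' summaries, and the birth-order correlation when skeleton lengths and
#' ranks are available. Writes per-stage CSVs and a `report.json` under
#' `out_dir`. All numbers in the report are stored unrounded; rerunning
#' with an identical config and seed reproduces the report byte-for-byte
#' except its `timestamp` field.
#'
#' @param config list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{edges, catalog}{paths to the edge-table and catalog CSVs, or
#'       in-memory objects under `edges_table` / `catalog_table`.}
#'     \item{targets}{list with `name`, `members`, and optional
#'       `homolog_pairs` (list of two-id pairs).}
#'     \item{analyzed}{neuron ids for the distance analysis (default: the
#'       target members).}
#'     \item{n_perm, alpha, seed}{distance-analysis parameters (defaults
#'       100, 0.05; seed required).}
#'     \item{thr_high, thr_low, min_syn}{accounting thresholds (4, 2, 10).}
#'     \item{hist_starts}{histogram bin starts (default 1..10).}
#'     \item{dropouts}{logical, also run sensory-only / interneuron-only
#'       distance variants (default FALSE).}
#'     \item{birth_order}{optional list with `ranks` (named integer
#'       vector) and `skeletons` (named list of [skeleton()]s) or
#'       `lengths` (data.frame neuron_id, birth_rank, length_L,
#'       length_R).}
#'   }
#' @param out_dir output directory (created if needed).
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must supply a seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[stage %s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  # --- load ------------------------------------------------------------
  inputs <- stage("load", {
    catalog <- if (!is.null(config$catalog_table)) {
      neuron_catalog(config$catalog_table)
    } else {
      if (is.null(config$catalog) || !file.exists(config$catalog)) {
        stop("catalog path missing or not found: ",
             if (is.null(config$catalog)) "<unset>" else config$catalog)
      }
      read_catalog(config$catalog)
    }
    edges <- if (!is.null(config$edges_table)) {
      synapse_table(config$edges_table)
    } else {
      if (is.null(config$edges) || !file.exists(config$edges)) {
        stop("edges path missing or not found: ",
             if (is.null(config$edges)) "<unset>" else config$edges)
      }
      read_edge_table(config$edges)
    }
    list(catalog = catalog, edges = edges)
  })
  catalog <- inputs$catalog
  edges <- inputs$edges

  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("cohortwiring")),
      seed = config$seed,
      config = config[setdiff(names(config),
                              c("catalog_table", "edges_table",
                                "birth_order"))]
    ),
    warnings = character(0)
  )

  # --- validate --------------------------------------------------------
  vr <- stage("validate", validate_catalog(catalog, edges))
  utils::write.csv(vr$issues, file.path(out_dir, "validation_issues.csv"),
                   row.names = FALSE)
  report$validation <- list(pass = vr$pass, n_issues = nrow(vr$issues))

  # --- accounting ------------------------------------------------------
  tg <- config$targets
  hmap <- if (!is.null(tg$homolog_pairs)) {
    do.call(rbind, lapply(tg$homolog_pairs, function(p) {
      data.frame(left = p[[1]], right = p[[2]], stringsAsFactors = FALSE)
    }))
  } else NULL
  targets <- target_set(tg$name, tg$members, hmap)

  acct <- stage("account", {
    sub <- inputs_onto(edges, targets)
    comp <- compose_by_source_type(sub, catalog)
    spec <- histogram_spec(config$hist_starts %||% 1:10)
    hist <- synapse_histogram(sub, spec, per = "edge")
    cls <- class_composition(sub, catalog)
    pairs <- if (!is.null(targets$homolog_map)) {
      lr_pair_filter(sub, catalog, targets,
                     thr_high = config$thr_high %||% 4L,
                     thr_low = config$thr_low %||% 2L)
    } else NULL
    hc <- highly_connected(sub, catalog, targets,
                           min_syn = config$min_syn %||% 10L)
    list(sub = sub, comp = comp, hist = hist, cls = cls, pairs = pairs,
         hc = hc)
  })
  utils::write.csv(acct$comp, file.path(out_dir, "source_type_composition.csv"),
                   row.names = FALSE)
  utils::write.csv(acct$hist, file.path(out_dir, "synapse_histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(acct$cls, file.path(out_dir, "class_composition.csv"),
                   row.names = FALSE)
  s <- input_summary(acct$sub)
  report$accounting <- list(
    total_synapses = s$total_synapses,
    distinct_sources = s$n_sources,
    source_type_percent = stats::setNames(as.list(acct$comp$percent),
                                          acct$comp$source_type),
    highly_connected_n = length(acct$hc$qualifying)
  )
  if (!is.null(acct$pairs)) {
    report$accounting$lr_paired_neurons <- acct$pairs$total_neurons
    report$accounting$lr_paired_synapses <- acct$pairs$total_synapses
    utils::write.csv(acct$pairs$pairs, file.path(out_dir, "lr_pairs.csv"),
                     row.names = FALSE)
  }

  # --- distance --------------------------------------------------------
  analyzed <- config$analyzed %||% targets$members
  n_perm <- config$n_perm %||% 100L
  alpha <- config$alpha %||% 0.05
  variants <- list(count = c("count", "none"), binary = c("binary", "none"))
  if (isTRUE(config$dropouts)) {
    variants$count_sensory <- c("count", "sensory_only")
    variants$count_interneuron <- c("count", "interneuron_only")
  }
  dist_res <- stage("distance", {
    lapply(variants, function(v) {
      distance_analysis(acct$sub, analyzed, catalog = catalog, mode = v[1],
                        dropout = v[2], n_perm = n_perm, seed = config$seed,
                        alpha = alpha)
    })
  })
  report$distance <- lapply(dist_res, function(r) {
    ut <- upper.tri(r$z)
    list(n_pairs = sum(ut), n_similar = sum(r$similar[ut]),
         n_different = sum(r$different[ut]),
         n_undefined = sum(r$undefined[ut]),
         similar_rate = mean(r$similar[ut]),
         universe_size = r$meta$universe_size)
  })
  for (nm in names(dist_res)) {
    r <- dist_res[[nm]]
    write_labeled_matrix(r$d, file.path(out_dir, paste0(nm, ".d.csv")))
    write_labeled_matrix(r$z, file.path(out_dir, paste0(nm, ".z.csv")))
    calls <- ifelse(r$similar, "similar",
                    ifelse(r$different, "different", ""))
    dimnames(calls) <- dimnames(r$z)
    utils::write.csv(calls, file.path(out_dir, paste0(nm, ".calls.csv")))
    if (length(r$meta$flagged_zero_input) > 0) {
      report$warnings <- c(report$warnings,
        sprintf("%s: zero-input analysed neuron(s): %s", nm,
                paste(r$meta$flagged_zero_input, collapse = ",")))
    }
  }

  # --- pair summaries (on the binary result) ---------------------------
  psum <- stage("pairs", pair_summaries(dist_res$binary, catalog))
  utils::write.csv(psum, file.path(out_dir, "pair_summaries.csv"),
                   row.names = FALSE)
  report$pair_summaries <- lapply(split(psum, psum$pair_type), function(g) {
    lapply(split(g, g$cohort), function(h) {
      list(n = nrow(h), mean_z = mean(h$z, na.rm = TRUE),
           n_similar = sum(h$significant_similar))
    })
  })

  # --- birth order -----------------------------------------------------
  if (!is.null(config$birth_order)) {
    bo <- stage("birthorder", {
      b <- config$birth_order
      tab <- if (!is.null(b$lengths)) {
        birth_order_table(b$lengths$neuron_id, b$lengths$birth_rank,
                          b$lengths$length_L, b$lengths$length_R)
      } else {
        lens <- vapply(b$skeletons, cortex_neurite_length, numeric(1))
        birth_order_table(names(b$ranks), b$ranks,
                          length_L = lens[names(b$ranks)])
      }
      list(table = tab, corr = birth_order_correlation(tab, which = "avg"))
    })
    utils::write.csv(as.data.frame(bo$table),
                     file.path(out_dir, "birth_order.csv"), row.names = FALSE)
    report$birth_order <- list(r = bo$corr$r, p = bo$corr$p, n = bo$corr$n,
                               df = bo$corr$df)
  }

  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
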