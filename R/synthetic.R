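# Seeded generator of synthetic nervous systems with the statistical
# structure the analysis assumes: lineages partitioned into temporal
# cohorts, left-right mirrored hemisegments, a shared presynaptic partner
# universe wired under a sharp (block-structured), graded (drifting), or
# null (uniform) model, skewed per-edge synapse counts, and chain
# skeletons whose cortex neurite length grows with birth rank.

#' Configuration for the synthetic connectome generator
#'
#' Defaults emulate a 13-neuron lineage (two early non-cohort neurons,
#' a five-neuron early cohort, a six-neuron late cohort) instantiated in
#' both hemisegments, wired over a universe of 200 candidate presynaptic
#' partners. Under the sharp model each cohort draws a dedicated
#' (disjoint) partner pool and members connect to pool partners with
#' `p_within` and to all others with `p_across`; under the graded model
#' each neuron inherits its rank-predecessor's partner set with
#' per-partner replacement probability `drift_rate`; under the null model
#' every (partner, neuron) edge is independent with a uniform probability
#' matched to the sharp model's expected density. Per-edge synapse counts
#' follow a geometric law with `P(count = 1) = count_geom_p` (default 0.8,
#' so most edges carry a single synapse) truncated at `count_max`; an
#' optional strong-edge mixture component (`count_strong_frac`, default 0)
#' replaces that fraction of draws with uniform counts in
#' `[10, count_max]`. The strong component makes individual multi-synapse
#' contacts common but, because it is attached to edges independently of
#' partner identity, it acts as heavy-tailed noise that dilutes the
#' identity signal the distance statistic measures; it is therefore off by
#' default.
#' Partner identities are shared input channels (side M) by default;
#' `paired_partner_frac` emits that fraction of channels as explicit
#' left-right partner pairs instead, to exercise pairing rules.
#'
#' @param n_lineages number of lineages.
#' @param n_neurons neurons per lineage (10-30 is typical).
#' @param cohort_breaks strictly increasing rank cut-points; ranks up to
#'   `cohort_breaks[k]` belong to cohort k.
#' @param cohort_labels one label per cohort (length = breaks + 1).
#' @param hemisegments sides to instantiate (`"L"`, `"R"`).
#' @param mirror_noise probability that a right-side edge is resampled
#'   rather than copied from its left homolog (0 = perfect mirror).
#' @param universe_size number of candidate presynaptic partner channels.
#' @param wiring_model `"sharp"`, `"graded"`, or `"null"`.
#' @param p_within,p_across connection probabilities to pool / non-pool
#'   partners (sharp model).
#' @param pool_size partners per cohort pool (sharp model).
#' @param pool_overlap fraction of each pool shared with the previous
#'   cohort's pool (0 = disjoint).
#' @param drift_rate per-rank partner turnover (graded model).
#' @param count_geom_p probability an edge carries exactly one synapse.
#' @param count_strong_frac fraction of edges drawn from the strong
#'   (10 to `count_max` synapses) component of the count law (default 0:
#'   pure truncated geometric).
#' @param count_max truncation of the synapse-count law.
#' @param sensory_frac,interneuron_frac fractions of the universe labeled
#'   sensory / interneuron (remainder brain_or_SEZ or unknown_fragment).
#' @param paired_partner_frac fraction of partner channels emitted as
#'   explicit L/R id pairs rather than shared (side M) identities.
#' @param skeleton_base,skeleton_slope,skeleton_noise_sd cortex neurite
#'   length law, `length = base + slope * rank + N(0, sd)`, in
#'   micrometres.
#' @param segment segment label for generated neurons.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_lineages = 1L,
                         n_neurons = 13L,
                         cohort_breaks = c(2L, 7L),
                         cohort_labels = c("other", "early", "late"),
                         hemisegments = c("L", "R"),
                         mirror_noise = 0.1,
                         universe_size = 200L,
                         wiring_model = c("sharp", "graded", "null"),
                         p_within = 0.8,
                         p_across = 0.05,
                         pool_size = 30L,
                         pool_overlap = 0,
                         drift_rate = 0.2,
                         count_geom_p = 0.8,
                         count_strong_frac = 0,
                         count_max = 30L,
                         sensory_frac = 0.19,
                         interneuron_frac = 0.61,
                         paired_partner_frac = 0,
                         skeleton_base = 10,
                         skeleton_slope = 5,
                         skeleton_noise_sd = 2,
                         segment = "A1",
                         seed = 1L) {
  wiring_model <- match.arg(wiring_model)
  probs <- c(mirror_noise = mirror_noise, p_within = p_within,
             p_across = p_across, pool_overlap = pool_overlap,
             drift_rate = drift_rate, count_geom_p = count_geom_p,
             count_strong_frac = count_strong_frac,
             sensory_frac = sensory_frac,
             interneuron_frac = interneuron_frac,
             paired_partner_frac = paired_partner_frac)
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1][1]
    stop(bad, " must be in [0, 1]")
  }
  if (sensory_frac + interneuron_frac > 1) {
    stop("sensory_frac + interneuron_frac must be <= 1")
  }
  if (length(cohort_breaks) > 0) {
    if (any(diff(c(0L, as.integer(cohort_breaks), n_neurons)) <= 0)) {
      stop("cohort_breaks must be strictly increasing within 1..n_neurons-1")
    }
  }
  if (length(cohort_labels) != length(cohort_breaks) + 1) {
    stop("need one cohort label per cohort (breaks + 1)")
  }
  if (count_max < 1) stop("count_max must be >= 1")
  n_cohorts <- length(cohort_labels)
  if (wiring_model == "sharp") {
    span <- pool_size + (n_cohorts - 1) * round(pool_size * (1 - pool_overlap))
    if (span > universe_size) {
      stop(sprintf("infeasible config: %d cohort pools of %d (overlap %.2f) exceed universe %d",
                   n_cohorts, pool_size, pool_overlap, universe_size))
    }
  }
  structure(list(
    n_lineages = as.integer(n_lineages), n_neurons = as.integer(n_neurons),
    cohort_breaks = as.integer(cohort_breaks), cohort_labels = cohort_labels,
    hemisegments = hemisegments, mirror_noise = mirror_noise,
    universe_size = as.integer(universe_size), wiring_model = wiring_model,
    p_within = p_within, p_across = p_across,
    pool_size = as.integer(pool_size), pool_overlap = pool_overlap,
    drift_rate = drift_rate, count_geom_p = count_geom_p,
    count_strong_frac = count_strong_frac,
    count_max = as.integer(count_max), sensory_frac = sensory_frac,
    interneuron_frac = interneuron_frac,
    paired_partner_frac = paired_partner_frac,
    skeleton_base = skeleton_base, skeleton_slope = skeleton_slope,
    skeleton_noise_sd = skeleton_noise_sd, segment = segment,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Synapse counts: a truncated geometric body, optionally mixed with a
# "strong edge" component drawn uniformly from [10, count_max]; the body's
# parameter is inflated so that P(count = 1) = p overall.
.draw_counts <- function(n, p, count_max, strong_frac = 0) {
  if (n == 0) return(integer(0))
  if (count_max < 10) strong_frac <- 0
  q <- min(1, p / (1 - strong_frac))
  out <- pmin(1L + stats::rgeom(n, q), count_max)
  if (strong_frac > 0) {
    strong <- stats::runif(n) < strong_frac
    if (any(strong)) {
      out[strong] <- sample(10:count_max, sum(strong), replace = TRUE)
    }
  }
  out
}

#' Mirror a hemisegment's wiring matrix
#'
#' Produces the opposite-side copy of a (neuron x partner-channel) wiring
#' matrix: each cell is copied from the left side with probability
#' `1 - mirror_noise` and independently resampled otherwise. Resampling
#' draws edge presence with the row's realised connection density (so the
#' expected in-degree is preserved) and a fresh synapse count from the
#' count law. `mirror_noise = 0` returns an identical matrix;
#' `mirror_noise = 1` gives wiring independent of the left side.
#'
#' Uses the current RNG state (call inside a seeded context for
#' reproducibility).
#'
#' @param w_left integer matrix, rows = neurons, cols = partner channels.
#' @param mirror_noise per-cell resampling probability.
#' @param count_geom_p,count_max,count_strong_frac synapse-count law
#'   parameters (see [synth_config()]).
#' @return Integer matrix of the same shape.
#' @export
mirror_wiring <- function(w_left, mirror_noise, count_geom_p = 0.8,
                          count_max = 30L, count_strong_frac = 0) {
  w <- w_left
  u <- ncol(w)
  if (u == 0 || mirror_noise == 0) return(w)
  for (i in seq_len(nrow(w))) {
    resample <- stats::runif(u) < mirror_noise
    if (!any(resample)) next
    dens <- mean(w_left[i, ] > 0)
    k <- sum(resample)
    present <- stats::runif(k) < dens
    vals <- integer(k)
    vals[present] <- .draw_counts(sum(present), count_geom_p, count_max,
                                  count_strong_frac)
    w[i, resample] <- vals
  }
  w
}

# left-side wiring matrix (neurons x channels) for one lineage
.wire_left <- function(cfg, cohort_of, pools) {
  n <- cfg$n_neurons
  u <- cfg$universe_size
  w <- matrix(0L, n, u)
  if (cfg$wiring_model == "sharp") {
    for (i in seq_len(n)) {
      pool <- pools[[cohort_of[i]]]
      p <- rep(cfg$p_across, u)
      p[pool] <- cfg$p_within
      edge <- stats::runif(u) < p
      w[i, edge] <- .draw_counts(sum(edge), cfg$count_geom_p, cfg$count_max,
                                 cfg$count_strong_frac)
    }
  } else if (cfg$wiring_model == "null") {
    p_null <- (cfg$pool_size * cfg$p_within +
               (u - cfg$pool_size) * cfg$p_across) / u
    for (i in seq_len(n)) {
      edge <- stats::runif(u) < p_null
      w[i, edge] <- .draw_counts(sum(edge), cfg$count_geom_p, cfg$count_max,
                                 cfg$count_strong_frac)
    }
  } else { # graded: inherit predecessor's partner set with drift
    k0 <- max(1L, round(cfg$pool_size * cfg$p_within +
                        (u - cfg$pool_size) * cfg$p_across))
    partners <- sample.int(u, min(k0, u))
    for (i in seq_len(n)) {
      if (i > 1) {
        turnover <- stats::runif(length(partners)) < cfg$drift_rate
        if (any(turnover)) {
          avail <- setdiff(seq_len(u), partners)
          repl <- sample(avail, min(sum(turnover), length(avail)))
          partners <- c(partners[!turnover], repl)
        }
      }
      w[i, partners] <- .draw_counts(length(partners), cfg$count_geom_p,
                                     cfg$count_max, cfg$count_strong_frac)
    }
  }
  w
}

#' Generate a synthetic nervous system
#'
#' Produces a neuron annotation catalog, a synaptic edge table, chain
#' skeletons for every generated lineage neuron, and a ground-truth record
#' (cohort partition, cohort partner pools, wiring model), all
#' deterministically from `cfg$seed`. See [synth_config()] for the wiring
#' models and defaults.
#'
#' @param cfg a [synth_config()].
#' @return List with `catalog` ([neuron_catalog()]), `edges`
#'   ([synapse_table()]), `skeletons` (named list of [skeleton()]s, one
#'   per lineage neuron, micrometre units), and `truth` (list: `model`,
#'   `cohort` named by neuron id, `pools`, `analyzed` ids per side).
#' @export
generate_connectome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, .generate_impl(cfg))
}

.generate_impl <- function(cfg) {
  u <- cfg$universe_size
  n_cohorts <- length(cfg$cohort_labels)

  # --- partner universe -----------------------------------------------
  n_paired <- round(cfg$paired_partner_frac * u)
  chan_paired <- seq_len(u) <= n_paired
  chan_id <- sprintf("P%03d", seq_len(u))
  n_sens <- round(cfg$sensory_frac * u)
  n_int <- round(cfg$interneuron_frac * u)
  stype <- rep("brain_or_SEZ", u)
  stype[sample.int(u)[seq_len(n_sens + n_int)]] <-
    c(rep("sensory", n_sens), rep("interneuron", n_int))
  sclass <- rep(NA_character_, u)
  sens_idx <- which(stype == "sensory")
  sclass[sens_idx] <- sample(SENSORY_CLASSES, length(sens_idx),
                             replace = TRUE, prob = c(0.5, 0.3, 0.2))
  mclass <- rep("other", u)
  mclass[stype == "sensory" & !is.na(sclass) & sclass == "chordotonal"] <- "CHO"
  int_idx <- which(stype == "interneuron")
  if (length(int_idx) > 0) {
    mclass[int_idx] <- sample(c("Basin", "Ladder", "other"), length(int_idx),
                              replace = TRUE, prob = c(0.15, 0.15, 0.7))
  }

  partner_rows <- list()
  pre_id_of_channel <- function(side) {
    ifelse(chan_paired, paste0(chan_id, side), chan_id)
  }
  for (k in seq_len(u)) {
    if (chan_paired[k]) {
      for (s in c("L", "R")) {
        partner_rows[[length(partner_rows) + 1L]] <- data.frame(
          neuron_id = paste0(chan_id[k], s), name = paste0(chan_id[k], s),
          side = s, segment = cfg$segment, source_type = stype[k],
          sensory_class = sclass[k], morph_class = mclass[k],
          lineage = NA_character_, hemilineage = NA_character_,
          birth_order = NA_integer_, cohort = NA_character_,
          homolog_id = paste0(chan_id[k], if (s == "L") "R" else "L"),
          stringsAsFactors = FALSE)
      }
    } else {
      partner_rows[[length(partner_rows) + 1L]] <- data.frame(
        neuron_id = chan_id[k], name = chan_id[k], side = "M",
        segment = cfg$segment, source_type = stype[k],
        sensory_class = sclass[k], morph_class = mclass[k],
        lineage = NA_character_, hemilineage = NA_character_,
        birth_order = NA_integer_, cohort = NA_character_,
        homolog_id = chan_id[k], stringsAsFactors = FALSE)
    }
  }

  # --- lineage neurons --------------------------------------------------
  cohort_of <- findInterval(seq_len(cfg$n_neurons) - 1L, cfg$cohort_breaks) + 1L
  edge_rows <- list()
  neuron_rows <- list()
  skeletons <- list()
  truth_cohort <- character(0)
  analyzed <- stats::setNames(vector("list", length(cfg$hemisegments)),
                              cfg$hemisegments)
  pools <- NULL

  for (l in seq_len(cfg$n_lineages)) {
    lin <- sprintf("LIN%d", l)
    # cohort partner pools (sharp): contiguous slices of a random channel order
    perm <- sample.int(u)
    step <- round(cfg$pool_size * (1 - cfg$pool_overlap))
    pools_l <- lapply(seq_len(n_cohorts), function(c) {
      start <- (c - 1L) * step
      sort(perm[start + seq_len(cfg$pool_size)])
    })
    names(pools_l) <- cfg$cohort_labels
    if (l == 1) pools <- pools_l

    w_left <- .wire_left(cfg, cohort_of, pools_l)
    w_side <- list()
    for (s in cfg$hemisegments) {
      w_side[[s]] <- if (s == cfg$hemisegments[1]) w_left else
        mirror_wiring(w_left, cfg$mirror_noise, cfg$count_geom_p,
                      cfg$count_max, cfg$count_strong_frac)
    }

    both_sides <- length(cfg$hemisegments) > 1
    for (s in cfg$hemisegments) {
      ids <- sprintf("%s_%s%s_n%02d", lin, cfg$segment, s,
                     seq_len(cfg$n_neurons))
      other <- if (both_sides) setdiff(cfg$hemisegments, s)[1] else NA
      hom <- if (both_sides) {
        sprintf("%s_%s%s_n%02d", lin, cfg$segment, other,
                seq_len(cfg$n_neurons))
      } else rep(NA_character_, cfg$n_neurons)
      neuron_rows[[length(neuron_rows) + 1L]] <- data.frame(
        neuron_id = ids, name = ids, side = s, segment = cfg$segment,
        source_type = "interneuron", sensory_class = NA_character_,
        morph_class = "EL", lineage = lin, hemilineage = "NotchOFF",
        birth_order = seq_len(cfg$n_neurons),
        cohort = cfg$cohort_labels[cohort_of], homolog_id = hom,
        stringsAsFactors = FALSE)
      truth_cohort <- c(truth_cohort,
                        stats::setNames(cfg$cohort_labels[cohort_of], ids))
      if (l == 1) analyzed[[s]] <- ids

      w <- w_side[[s]]
      pre_ids <- pre_id_of_channel(s)
      for (i in seq_len(cfg$n_neurons)) {
        nz <- which(w[i, ] > 0)
        if (length(nz) > 0) {
          edge_rows[[length(edge_rows) + 1L]] <- data.frame(
            pre_id = pre_ids[nz], post_id = ids[i], count = w[i, nz],
            stringsAsFactors = FALSE)
        }
      }

      # chain skeleton: soma -> 5 segments -> entry -> short distal arbor
      for (i in seq_len(cfg$n_neurons)) {
        len <- max(0.5, cfg$skeleton_base + cfg$skeleton_slope * i +
                         stats::rnorm(1, 0, cfg$skeleton_noise_sd))
        xs <- seq(0, len, length.out = 6)
        nd <- data.frame(
          node_id = as.character(1:8),
          x = c(xs, len + 1, len + 2),
          y = 0, z = 0,
          parent_id = c(NA, as.character(1:7)),
          stringsAsFactors = FALSE)
        skeletons[[ids[i]]] <- skeleton(nd, soma_node = "1",
                                        entry_node = "6", unit = "um")
      }
    }
  }

  catalog <- neuron_catalog(rbind(do.call(rbind, neuron_rows),
                                  do.call(rbind, partner_rows)))
  edges <- synapse_table(if (length(edge_rows) > 0) {
    do.call(rbind, edge_rows)
  } else {
    data.frame(pre_id = character(0), post_id = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  })
  truth <- list(
    model = cfg$wiring_model,
    has_cohort_structure = cfg$wiring_model != "null",
    cohort = truth_cohort,
    pools = if (cfg$wiring_model == "sharp") pools else NULL,
    analyzed = analyzed,
    seed = cfg$seed
  )
  list(catalog = catalog, edges = edges, skeletons = skeletons,
       truth = truth, config = cfg)
}
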