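test_that("inputs_onto restricts to the target set and reports totals", {
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  s <- input_summary(sub)
  expect_equal(s$total_synapses, 45L)   # hand-counted from the fixture
  expect_equal(s$n_sources, 12L)

  empty <- synapse_table(data.frame(pre_id = character(0),
                                    post_id = character(0),
                                    count = integer(0)))
  s0 <- input_summary(inputs_onto(empty, fixture_targets()))
  expect_equal(s0$total_synapses, 0L)
  expect_equal(s0$n_sources, 0L)

  one <- synapse_table(data.frame(pre_id = "a", post_id = "t", count = 7L))
  s1 <- input_summary(inputs_onto(one, "t"))
  expect_equal(s1$total_synapses, 7L)
  expect_equal(s1$n_sources, 1L)
})

test_that("source-type composition percentages are exact and sum to 100", {
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  comp <- compose_by_source_type(sub, fixture_catalog())
  get <- function(t, col) comp[[col]][comp$source_type == t]
  # hand counts: interneuron 29, sensory 13, brain 2, unknown fragment 1
  expect_equal(get("interneuron", "n_synapses"), 29L)
  expect_equal(get("sensory", "n_synapses"), 13L)
  expect_equal(get("brain_or_SEZ", "n_synapses"), 2L)
  expect_equal(get("unknown_fragment", "n_synapses"), 1L)
  expect_equal(get("interneuron", "percent"), 100 * 29 / 45)
  expect_equal(sum(comp$percent), 100)
  expect_equal(sum(comp$n_synapses), 45L)

  # two types with counts 3 and 1 -> 75% / 25%
  cat2 <- neuron_catalog(data.frame(
    neuron_id = c("a", "b", "t"),
    source_type = c("interneuron", "sensory", "interneuron"),
    stringsAsFactors = FALSE))
  sub2 <- synapse_table(data.frame(pre_id = c("a", "b"), post_id = "t",
                                   count = c(3L, 1L)))
  comp2 <- compose_by_source_type(sub2, cat2)
  expect_equal(comp2$percent[comp2$source_type == "interneuron"], 75)
  expect_equal(comp2$percent[comp2$source_type == "sensory"], 25)
})

test_that("per-target sensory fractions are synapse-weighted and bounded", {
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  br <- sensory_breakdown(sub, fixture_catalog(), fixture_targets())
  frac <- function(t, cl) br$fraction[br$target == t & br$sensory_class == cl]
  # tL2 receives 7 synapses total, 4 chordotonal (from s1)
  expect_equal(frac("tL2", "chordotonal"), 4 / 7)
  # tL3 receives 13 total, 3 proprioceptive (from s2)
  expect_equal(frac("tL3", "proprioceptive"), 3 / 13)
  # tL1 gets no sensory input at all
  expect_equal(sum(br$fraction[br$target == "tL1"]), 0)
  # fractions per target never exceed 1
  per_target <- tapply(br$fraction, br$target, sum)
  expect_true(all(per_target <= 1 + 1e-12))
})

test_that("synapse histograms bin per edge and per pooled source, with underflow", {
  spec <- histogram_spec(1:10)
  expect_equal(spec$labels, c(as.character(1:9), "10+"))
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  h <- synapse_histogram(sub, spec, per = "edge")
  # hand-binned edge counts: 4,2,4,2,3,2,5,2,5,4,6,3,2,1
  expect_equal(h$n, c(1L, 5L, 2L, 3L, 2L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(sum(h$n) + attr(h, "underflow"), nrow(sub))

  # counts {1,1,10} -> bins 1:2, 10+:1
  sub2 <- synapse_table(data.frame(pre_id = c("a", "b", "c"), post_id = "t",
                                   count = c(1L, 1L, 10L)))
  h2 <- synapse_histogram(sub2, spec, per = "edge")
  expect_equal(h2$n[h2$bin == "1"], 2L)
  expect_equal(h2$n[h2$bin == "10+"], 1L)

  # pooled per source: s1 contributes 10 in total in the fixture
  hp <- synapse_histogram(sub, spec, per = "source_pooled")
  expect_equal(sum(hp$n), 12L)  # 12 distinct sources
  expect_equal(hp$n[hp$bin == "10+"], 1L)

  # empty sub-table -> all zero
  empty <- synapse_table(data.frame(pre_id = character(0),
                                    post_id = character(0),
                                    count = integer(0)))
  expect_true(all(synapse_histogram(empty, spec)$n == 0))

  # value below the lowest bin start goes to the underflow bucket
  spec5 <- histogram_spec(seq(5, 20, 5))
  expect_message(h5 <- synapse_histogram(sub2, spec5, per = "edge"),
                 "underflow")
  expect_equal(attr(h5, "underflow"), 2L)
  expect_equal(sum(h5$n) + attr(h5, "underflow"), 3L)
})

test_that("KS comparison matches hand-enumerated CDFs and handles edge cases", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disjoint <- ks_compare(c(1, 1, 1), c(100, 100, 100))
  expect_equal(disjoint$D, 1)
  # ECDFs of {1,2,3,4} vs {2,3,4,5} differ by at most 0.25
  shifted <- ks_compare(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(shifted$D, 0.25)
  expect_error(ks_compare(numeric(0), 1), "non-empty")
})

test_that("left-right pairing filter enforces the high/low thresholds on homologous targets", {
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  ps <- lr_pair_filter(sub, fixture_catalog(), fixture_targets())
  # hand evaluation: i1/i2 qualify (4 onto tL1, 2 onto tR1); the midline
  # neuron m1 qualifies (5 onto tL3, 2 onto tR3); i3/i4 fail (counts on
  # non-homologous targets); i5/i6 fail (3 < 4); m2 fails (one side only)
  expect_setequal(ps$neuron_ids, c("i1", "i2", "m1"))
  expect_equal(ps$total_neurons, 3L)
  expect_equal(ps$total_synapses, 13L)  # 4 + 2 + 7, hand-summed

  # empty input -> empty set
  empty <- synapse_table(data.frame(pre_id = character(0),
                                    post_id = character(0),
                                    count = integer(0)))
  ps0 <- lr_pair_filter(empty, fixture_catalog(), fixture_targets())
  expect_equal(ps0$total_neurons, 0L)
})

test_that("pairing filter boundary: (4,2) retained, (4,1) and (3,2) rejected", {
  cat <- fixture_catalog()
  tg <- fixture_targets()
  mk <- function(hi, lo) {
    synapse_table(data.frame(pre_id = c("i1", "i2"),
                             post_id = c("tL1", "tR1"),
                             count = c(hi, lo)))
  }
  expect_equal(lr_pair_filter(mk(4L, 2L), cat, tg)$total_neurons, 2L)
  expect_equal(lr_pair_filter(mk(4L, 1L), cat, tg)$total_neurons, 0L)
  expect_equal(lr_pair_filter(mk(3L, 2L), cat, tg)$total_neurons, 0L)
  # either member may carry the high count
  expect_equal(lr_pair_filter(mk(2L, 4L), cat, tg)$total_neurons, 2L)
})

test_that("pairing filter is monotone in thresholds and invariant to row order and global L/R swap", {
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  cat <- fixture_catalog()
  tg <- fixture_targets()
  base <- lr_pair_filter(sub, cat, tg)
  stricter <- lr_pair_filter(sub, cat, tg, thr_high = 6L, thr_low = 3L)
  expect_true(all(stricter$neuron_ids %in% base$neuron_ids))

  withr::with_seed(9, sub2 <- sub[sample(nrow(sub)), ])
  shuf <- lr_pair_filter(synapse_table(sub2), cat, tg)
  expect_setequal(shuf$neuron_ids, base$neuron_ids)
  expect_equal(shuf$total_synapses, base$total_synapses)

  # swap every L and R label (and the target homolog map orientation)
  cat_sw <- as.data.frame(cat)
  cat_sw$side <- chartr("LR", "RL", cat_sw$side)
  tg_sw <- target_set(tg$name, tg$members,
                      data.frame(left = tg$homolog_map$right,
                                 right = tg$homolog_map$left,
                                 stringsAsFactors = FALSE))
  swapped <- lr_pair_filter(sub, neuron_catalog(cat_sw), tg_sw)
  expect_setequal(swapped$neuron_ids, base$neuron_ids)
})

test_that("candidates without side or homolog annotation are skipped, not retained", {
  cat <- as.data.frame(fixture_catalog())
  cat$homolog_id[cat$neuron_id == "i1"] <- NA
  cat$homolog_id[cat$neuron_id == "i2"] <- NA
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  ps <- lr_pair_filter(sub, neuron_catalog(cat), fixture_targets())
  expect_true(all(c("i1", "i2") %in% ps$skipped))
  expect_false("i1" %in% ps$neuron_ids)
})

test_that("highly connected filter applies the summed-synapse threshold with pair expansion", {
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  hc <- highly_connected(sub, fixture_catalog(), fixture_targets())
  expect_equal(hc$qualifying, "s1")   # s1 sums to exactly 10
  expect_equal(hc$members, "s1")

  one <- function(n) synapse_table(data.frame(pre_id = "s1", post_id = "tL1",
                                              count = n))
  expect_equal(highly_connected(one(9L), fixture_catalog(),
                                fixture_targets())$qualifying, character(0))
  expect_equal(highly_connected(one(10L), fixture_catalog(),
                                fixture_targets())$qualifying, "s1")

  # monotone in min_syn
  hc15 <- highly_connected(sub, fixture_catalog(), fixture_targets(),
                           min_syn = 15L)
  expect_true(all(hc15$qualifying %in% hc$qualifying))

  # one member of an L/R pair qualifying pulls in the other member
  sub_pair <- synapse_table(data.frame(pre_id = c("i1", "i2"),
                                       post_id = c("tL1", "tR1"),
                                       count = c(12L, 2L)))
  hcp <- highly_connected(sub_pair, fixture_catalog(), fixture_targets())
  expect_equal(hcp$qualifying, "i1")
  expect_setequal(hcp$members, c("i1", "i2"))
})

test_that("class composition percentages are over total synapses with distinct neuron counts", {
  sub <- inputs_onto(fixture_edges(), fixture_targets())
  cc <- class_composition(sub, fixture_catalog(),
                          classes = c("CHO", "Ladder"))
  cho <- cc[cc$morph_class == "CHO", ]
  lad <- cc[cc$morph_class == "Ladder", ]
  expect_equal(cho$n_neurons, 1L)       # s1 only
  expect_equal(cho$n_synapses, 10L)
  expect_equal(cho$percent, 100 * 10 / 45)
  expect_equal(lad$n_neurons, 2L)       # m1, m2
  expect_equal(lad$n_synapses, 12L)
  expect_equal(sum(cc$percent), 100)

  # one class holding all rows -> 100%
  solo <- synapse_table(data.frame(pre_id = "m1", post_id = "tL3", count = 5L))
  cc1 <- class_composition(solo, fixture_catalog())
  expect_equal(cc1$percent[cc1$morph_class == "Ladder"], 100)
})
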