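# Hand-built miniature connectome fixture with independently hand-counted
# expected values (frozen in the tests that use it). Three left-right
# target pairs; presynaptic interneuron pairs, midline neurons, sensory
# and brain sources designed to exercise every accounting rule.

fixture_catalog <- function() {
  neuron_catalog(data.frame(
    neuron_id = c("tL1", "tR1", "tL2", "tR2", "tL3", "tR3",
                  "i1", "i2", "i3", "i4", "i5", "i6",
                  "m1", "m2", "s1", "s2", "b1"),
    side = c("L", "R", "L", "R", "L", "R",
             "L", "R", "L", "R", "L", "R",
             "M", "M", "M", "M", "L"),
    segment = "A1",
    source_type = c(rep("interneuron", 6),
                    rep("interneuron", 6),
                    "interneuron", "interneuron",
                    "sensory", "sensory", "brain_or_SEZ"),
    sensory_class = c(rep(NA, 14), "chordotonal", "proprioceptive", NA),
    morph_class = c(rep("EL", 6), rep(NA, 6), "Ladder", "Ladder",
                    "CHO", NA, NA),
    lineage = c(rep("LINT", 6), rep(NA, 11)),
    hemilineage = c(rep("NotchOFF", 6), rep(NA, 11)),
    birth_order = c(1L, 1L, 2L, 2L, 3L, 3L, rep(NA, 11)),
    cohort = c("other", "other", "early", "early", "late", "late",
               rep(NA, 11)),
    homolog_id = c("tR1", "tL1", "tR2", "tL2", "tR3", "tL3",
                   "i2", "i1", "i4", "i3", "i6", "i5",
                   "m1", "m2", "s1", "s2", NA),
    stringsAsFactors = FALSE
  ))
}

fixture_edges <- function() {
  synapse_table(data.frame(
    pre_id  = c("i1", "i2", "i3", "i4", "i5", "i6",
                "m1", "m1", "m2", "s1", "s1", "s2", "b1", "u1"),
    post_id = c("tL1", "tR1", "tL1", "tR2", "tL2", "tR2",
                "tL3", "tR3", "tL3", "tL2", "tR2", "tL3", "tL1", "tR1"),
    count   = c(4L, 2L, 4L, 2L, 3L, 2L,
                5L, 2L, 5L, 4L, 6L, 3L, 2L, 1L),
    stringsAsFactors = FALSE
  ))
}

fixture_targets <- function() {
  target_set("LINT_A1LR",
             members = c("tL1", "tR1", "tL2", "tR2", "tL3", "tR3"),
             homolog_map = data.frame(left = c("tL1", "tL2", "tL3"),
                                      right = c("tR1", "tR2", "tR3"),
                                      stringsAsFactors = FALSE))
}
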