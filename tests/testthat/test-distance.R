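test_that("input matrix tabulates counts over a shared sorted universe", {
  sub <- synapse_table(data.frame(pre_id = c("a", "b", "a"),
                                  post_id = c("x", "x", "y"),
                                  count = c(2L, 1L, 3L)))
  m <- build_input_matrix(sub, c("x", "y"), mode = "count")
  expect_equal(colnames(m), c("a", "b"))
  expect_equal(m["x", ], c(a = 2L, b = 1L))
  expect_equal(m["y", ], c(a = 3L, b = 0L))
  mb <- build_input_matrix(sub, c("x", "y"), mode = "binary")
  expect_equal(sort(unique(as.vector(mb))), c(0L, 1L))
  expect_equal(mb["y", ], c(a = 1L, b = 0L))
  # binarising is idempotent
  expect_equal(as.integer(mb > 0), as.vector(mb))
})

test_that("dropout restricts the universe by source type and flags empty rows", {
  cat <- neuron_catalog(data.frame(
    neuron_id = c("a", "b", "x", "y"),
    source_type = c("sensory", "interneuron", "interneuron", "interneuron"),
    stringsAsFactors = FALSE))
  sub <- synapse_table(data.frame(pre_id = c("a", "b", "a"),
                                  post_id = c("x", "x", "y"),
                                  count = c(2L, 1L, 3L)))
  ms <- build_input_matrix(sub, c("x", "y"), dropout = "sensory_only",
                           catalog = cat)
  expect_equal(colnames(ms), "a")
  mi <- build_input_matrix(sub, c("x", "y"), dropout = "interneuron_only",
                           catalog = cat)
  expect_equal(colnames(mi), "b")
  expect_equal(attr(mi, "flagged"), "y")  # y has no interneuron input
  # no sensory sources at all -> zero-column matrix, message
  sub2 <- synapse_table(data.frame(pre_id = "b", post_id = "x", count = 1L))
  expect_message(m0 <- build_input_matrix(sub2, c("x", "y"),
                                          dropout = "sensory_only",
                                          catalog = cat), "empty")
  expect_equal(ncol(m0), 0)
  expect_error(build_input_matrix(sub, c("x", "zz"), catalog = cat),
               "absent from catalog")
})

test_that("Euclidean distances match the brute-force double-loop oracle", {
  expect_equal(euclidean_distances(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)
  expect_equal(euclidean_distances(rbind(a = c(3, 0), b = c(0, 4)))["a", "b"], 5)
  withr::with_seed(13, {
    m <- matrix(sample.int(9, 24, replace = TRUE), nrow = 4,
                dimnames = list(paste0("n", 1:4), paste0("p", 1:6)))
  })
  d <- euclidean_distances(m)
  expect_equal(d, brute_distances(m))
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("shuffle null preserves each row's value multiset in every permutation", {
  withr::with_seed(3, {
    m <- matrix(rpois(5 * 12, 2), nrow = 5,
                dimnames = list(paste0("n", 1:5), paste0("p", 1:12)))
  })
  # re-run the shuffling by hand with the same seed and check conservation
  withr::with_seed(21, {
    for (p in 1:20) {
      for (i in seq_len(nrow(m))) {
        shuffled_row <- m[i, sample.int(ncol(m))]
        expect_equal(sort(shuffled_row), sort(m[i, ]), ignore_attr = TRUE)
        expect_equal(sum(shuffled_row), sum(m[i, ]))
      }
    }
  })
  # and through the public API: row sums of the null mean relate sanely
  null <- shuffle_null(m, n_perm = 50, seed = 21)
  expect_true(all(null$null_sd >= 0))
  expect_true(isSymmetric(null$null_mean))
})

test_that("a single-column universe leaves no permutation freedom", {
  m <- matrix(c(2L, 5L), 2, 1, dimnames = list(c("a", "b"), "p"))
  null <- shuffle_null(m, n_perm = 10, seed = 1)
  expect_equal(null$null_sd["a", "b"], 0)
  expect_equal(null$null_mean["a", "b"], 3)  # |2-5| every time
  expect_error(shuffle_null(m, n_perm = 1, seed = 1), "at least 2")
})

test_that("Monte-Carlo null converges to the exhaustive joint-permutation oracle", {
  # two rows with a single 1 in different columns: distances {0,0,sqrt2,sqrt2}
  m <- rbind(a = c(1L, 0L), b = c(0L, 1L))
  ex <- exhaustive_pair_null(m["a", ], m["b", ])
  expect_equal(sort(unique(round(ex$distances, 12))),
               round(c(0, sqrt(2)), 12))
  expect_equal(ex$mean, sqrt(2) / 2)

  null <- shuffle_null(m, n_perm = 10000, seed = 4)
  se_mean <- ex$sd / sqrt(10000)
  expect_lt(abs(null$null_mean["a", "b"] - ex$mean), 3 * se_mean)
  se_sd <- ex$sd * sqrt(1 / (2 * (10000 - 1)))
  expect_lt(abs(null$null_sd["a", "b"] - ex$sd), 3 * se_sd)
})

test_that("z-scores and significance calls follow the two-tailed convention", {
  d <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  nm <- d; nsd <- matrix(1, 2, 2, dimnames = dimnames(d))
  res <- zscore_and_call(d, nm, nsd)
  expect_equal(res$z["a", "b"], 0)
  expect_false(any(res$similar) || any(res$different))

  nm2 <- d + 3  # real distance 3 sd below chance -> similar
  res2 <- zscore_and_call(d, nm2, nsd)
  expect_equal(res2$z["a", "b"], -3)
  expect_true(res2$similar["a", "b"])
  expect_false(res2$different["a", "b"])

  nm3 <- d - 3  # real distance 3 sd above chance -> different
  res3 <- zscore_and_call(d, nm3, nsd)
  expect_true(res3$different["a", "b"])

  # zero null sd -> undefined, never significant
  nsd0 <- nsd; nsd0[] <- 0
  res4 <- zscore_and_call(d, nm2, nsd0)
  expect_true(is.na(res4$z["a", "b"]))
  expect_true(res4$undefined["a", "b"])
  expect_false(res4$similar["a", "b"])

  # threshold is derived from alpha
  res5 <- zscore_and_call(d, nm, nsd, alpha = 0.01)
  expect_equal(res5$z_threshold, qnorm(0.995))
  expect_error(zscore_and_call(d, nm[1, 1, drop = FALSE], nsd), "shape")
})

test_that("distance analysis is deterministic given seed and inputs", {
  g <- generate_connectome(synth_config(seed = 31, hemisegments = "L",
                                        universe_size = 60L, pool_size = 15L))
  ids <- g$truth$analyzed$L
  sub <- inputs_onto(g$edges, target_set("t", ids))
  r1 <- distance_analysis(sub, ids, catalog = g$catalog, n_perm = 50,
                          seed = 77)
  r2 <- distance_analysis(sub, ids, catalog = g$catalog, n_perm = 50,
                          seed = 77)
  expect_identical(r1$z, r2$z)
  expect_identical(r1$similar, r2$similar)
  r3 <- distance_analysis(sub, ids, catalog = g$catalog, n_perm = 50,
                          seed = 78)
  expect_false(identical(r1$z, r3$z))
})

test_that("binarising removes weight-driven difference calls", {
  # Difference calls arise when a pair's observed distance exceeds the
  # identity-shuffling null, i.e. when the structure in the vectors is
  # anti-aligned beyond chance. Construct data where that structure lives
  # purely in the synapse weights: two cohorts share (almost) the same
  # partner set, but each concentrates its strong contacts on a different
  # partner block. Count mode must flag across-cohort pairs as different;
  # binary mode, which discards the weights, must not add any calls.
  partners <- sprintf("P%02d", 1:30)
  ids <- sprintf("n%02d", 1:10)
  strong_block <- list(1:10, 21:30)  # cohort 1 vs cohort 2
  rows <- list()
  withr::with_seed(90, {
    for (i in seq_along(ids)) {
      present <- sort(sample.int(30, 28))  # near-identical binary vectors
      counts <- rep(1L, length(present))
      blk <- strong_block[[if (i <= 5) 1 else 2]]
      counts[present %in% blk] <- 8L
      rows[[i]] <- data.frame(pre_id = partners[present], post_id = ids[i],
                              count = counts, stringsAsFactors = FALSE)
    }
  })
  sub <- synapse_table(do.call(rbind, rows))
  rc <- distance_analysis(sub, ids, mode = "count", n_perm = 200, seed = 91)
  rb <- distance_analysis(sub, ids, mode = "binary", n_perm = 200, seed = 91)
  ut <- upper.tri(rc$z)
  diff_count <- sum(rc$different[ut])
  diff_binary <- sum(rb$different[ut])
  expect_gt(diff_count, 0)             # count mode has power here
  expect_lte(diff_binary, diff_count)  # removing weights adds no calls
  # the across-cohort anti-alignment is exactly what count mode flags
  across <- outer(1:10, 1:10, function(a, b) (a <= 5) != (b <= 5)) & ut
  expect_true(all(rc$different[ut & !across] == FALSE))
})

test_that("pair summaries extract left-right and consecutive-birth-order pairs", {
  cat <- neuron_catalog(data.frame(
    neuron_id = c("aL", "aR", "bL", "bR", "cL", "m"),
    side = c("L", "R", "L", "R", "L", "M"),
    segment = "A1",
    lineage = "X", hemilineage = "A",
    birth_order = c(1L, 1L, 2L, 2L, 3L, NA),
    cohort = c("early", "early", "early", "early", "late", NA),
    homolog_id = c("aR", "aL", "bR", "bL", NA, "m"),
    stringsAsFactors = FALSE))
  ids <- c("aL", "aR", "bL", "bR", "cL", "m")
  z <- matrix(seq(-3, 3, length.out = 36), 6, 6,
              dimnames = list(ids, ids))
  z <- (z + t(z)) / 2
  diag(z) <- 0
  res <- structure(list(z = z, similar = z < -1.96, different = z > 1.96,
                        z_threshold = 1.96), class = "distance_result")
  ps <- pair_summaries(res, cat)
  lr <- ps[ps$pair_type == "left_right", ]
  expect_setequal(paste(lr$id_a, lr$id_b), c("aL aR", "bL bR"))
  # midline neuron (homolog self) excluded from left-right pairs
  expect_false("m" %in% c(lr$id_a, lr$id_b))
  fo <- ps[ps$pair_type == "following", ]
  # consecutive orders on side L: (1,2) and (2,3); nothing on side R beyond
  # (1,2); no pair (1,3); m skipped (no birth order)
  expect_setequal(paste(fo$id_a, fo$id_b), c("aL bL", "bL cL", "aR bR"))
  expect_equal(fo$cohort[fo$id_a == "bL" & fo$id_b == "cL"], "mixed")
  expect_equal(attr(ps, "z_threshold"), -1.96)
})
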