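test_that("call_domains applies length and probability thresholds as stated", {
  L <- 60
  p <- matrix(0, L, 2, dimnames = list(NULL, c("A", "B")))
  p[11:35, 1] <- 0.9                       # 25 residues above threshold
  calls <- call_domains(p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$family, "A")
  expect_equal(c(calls$start, calls$end), c(10L, 35L))
  expect_equal(calls$mean_probability, 0.9)

  p19 <- matrix(0, L, 1, dimnames = list(NULL, "A"))
  p19[1:19, 1] <- 0.9                      # 19 < min_length
  expect_equal(nrow(call_domains(p19)), 0L)

  # exactly the threshold is not above it: run is broken at that position
  p[23, 1] <- 0.025
  broken <- call_domains(p)
  expect_equal(nrow(broken), 0L)           # 12- and 12-residue fragments

  expect_error(call_domains(matrix(-0.1, 30, 1)),
               class = "famsim_error_probability_range")
})

test_that("overlapping calls of different classes are allowed", {
  p <- matrix(0, 100, 2, dimnames = list(NULL, c("A", "B")))
  p[1:100, 1] <- 0.5
  p[31:60, 2] <- 0.5
  calls <- call_domains(p)
  expect_equal(calls$family, c("A", "B"))
  expect_equal(calls$start, c(0L, 30L))
  expect_equal(calls$end, c(100L, 60L))
})

test_that("call_domains matches the run-length oracle on random matrices", {
  set.seed(99)
  for (trial in 1:60) {
    L <- sample(5:200, 1)
    C <- sample(1:10, 1)
    cfg <- calling_config(min_length = sample(c(5L, 20L), 1),
                          prob_threshold = sample(c(0.025, 0.3), 1))
    probs <- matrix(runif(L * C)^2, L, C,
                    dimnames = list(NULL, sprintf("F%02d", 1:C)))
    got <- call_domains(probs, config = cfg)
    want <- oracle_call_domains(probs, cfg$min_length, cfg$prob_threshold)
    expect_equal(got$family, want$family)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$mean_probability, want$mean_probability)
    # structural invariants: in bounds, per class disjoint and sorted
    expect_true(all(got$start >= 0 & got$end <= L))
    for (f in unique(got$family)) {
      g <- got[got$family == f, ]
      expect_true(all(diff(g$start) > 0))
      expect_true(all(utils::head(g$end, -1) < utils::tail(g$start, -1) + 1))
    }
    expect_true(all(got$mean_probability > cfg$prob_threshold))
  }
})

test_that("midpoint_overlap implements the either-direction >50% rule", {
  expect_true(midpoint_overlap(0, 30, 10, 30))    # 20/30 = 66.7%
  expect_false(midpoint_overlap(10, 60, 40, 140)) # 40% and 20%
  expect_true(midpoint_overlap(5, 25, 5, 25))     # identical spans
  # asymmetric by construction: tiny prediction inside a huge reference
  expect_true(midpoint_overlap(0, 10, 0, 100))    # 100% of prediction
  expect_false(midpoint_overlap(0, 10, 9, 100))   # 10% and ~1%
  expect_error(midpoint_overlap(5, 5, 0, 10), class = "famsim_error_invalid_span")
})

test_that("filter_calls modes behave per contract", {
  calls <- domain_calls(c("s1", "s1", "s2"), c("PF1", "PF2", "PF1"),
                        c(0L, 50L, 0L), c(30L, 90L, 30L), c(0.9, 0.8, 0.7))
  ref <- data.frame(sequence_id = "s1", family = "PF1",
                    start = 10L, end = 30L, source = "SEED",
                    stringsAsFactors = FALSE)
  expect_identical(filter_calls(calls, mode = "all"), calls)
  kept <- filter_calls(calls, ref, "seed_overlap")
  expect_equal(nrow(kept), 1L)             # only s1/PF1 has a SEED match
  expect_equal(kept$sequence_id, "s1")
  expect_equal(kept$family, "PF1")
  expect_equal(nrow(filter_calls(calls, ref, "full_overlap")), 0L)
  expect_error(filter_calls(calls, mode = "seed_overlap"),
               class = "famsim_error_missing_reference")
})

test_that("cooccurrence_stats counts overlap and adjacency", {
  calls <- domain_calls(
    sequence_id = c("s1", "s1", "s2", "s2", "s3"),
    family = c("A", "B", "A", "B", "C"),
    start = c(0L, 30L, 0L, 55L, 0L),
    end = c(100L, 60L, 50L, 100L, 40L),
    mean_probability = rep(0.9, 5))
  st <- cooccurrence_stats(calls, gap = 10L)
  ab <- st[st$family_i == "A" & st$family_j == "B", ]
  expect_equal(ab$n_same_sequence, 2L)
  expect_equal(ab$n_residue_overlap, 1L)   # s1 only
  expect_equal(ab$n_adjacent, 1L)          # s2: gap 5 <= 10
  expect_false(any(st$family_i == "C" | st$family_j == "C"))
})
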