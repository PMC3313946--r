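test_that("injective mapping enumeration matches the combinatorics", {
  m <- enumerate_mappings(3, 4)
  expect_equal(nrow(m), 24L)
  expect_equal(anyDuplicated(m), 0L)
  expect_true(all(apply(m, 1, function(x) !anyDuplicated(x))))
  # each fixed stimulus-response association lies in exactly 6 mappings
  for (s in 1:3) for (r in 1:4) expect_equal(sum(m[, s] == r), 6L)
  # a fixed pair of associations lies in exactly 2 mappings
  expect_equal(sum(m[, 1] == 1 & m[, 2] == 2), 2L)
  expect_equal(nrow(enumerate_mappings(1, 4)), 4L)
  expect_error(enumerate_mappings(4, 3), "injective")
})

test_that("open sessions use all 24 mappings with no successive overlap", {
  proto <- generate_open_session(7)
  expect_equal(nrow(proto$episodes), 25L)
  seq <- proto$episodes$mapping
  expect_equal(sort(unique(seq[1:24])), 1:24)
  expect_equal(seq[25], seq[1])
  for (e in 1:24) {
    expect_equal(mapping_overlap(proto$mappings[seq[e], ],
                                 proto$mappings[seq[e + 1], ]), 0L)
  }
  expect_true(all(proto$episodes$length >= 36 & proto$episodes$length <= 54))
})

test_that("recurrent sessions have 8/8/9 repetitions of disjoint mappings", {
  proto <- generate_recurrent_session(11)
  seq <- proto$episodes$mapping
  expect_equal(length(seq), 25L)
  expect_equal(sort(as.vector(table(seq))), c(8L, 8L, 9L))
  expect_true(all(diff(seq) != 0L))        # no immediate repeats
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(mapping_overlap(proto$mappings[i, ], proto$mappings[j, ]), 0L)
  }
  # transition frequencies exactly equalized (Eulerian construction)
  trans <- table(factor(seq[-25], levels = 1:3), factor(seq[-1], levels = 1:3))
  expect_true(all(trans[row(trans) != col(trans)] == 4L))
})

test_that("the four-mapping session uses fully incongruent mappings", {
  proto <- generate_recurrent_session(5, n_mappings = 4L)
  expect_equal(nrow(proto$episodes), 24L)
  expect_equal(as.vector(table(proto$episodes$mapping)), rep(6L, 4))
  expect_true(all(diff(proto$episodes$mapping) != 0L))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(mapping_overlap(proto$mappings[i, ], proto$mappings[j, ]), 0L)
  }
})

test_that("cued sessions implement the control/transfer/open design", {
  ses <- generate_cued_sessions(13)
  s1 <- ses$session1; s2 <- ses$session2
  expect_equal(nrow(s1$episodes), 25L)
  expect_equal(sum(s2$episodes$condition == "rehearsal"), 13L)
  expect_equal(s2$episodes$condition[1:13], rep("rehearsal", 13))
  expect_equal(sum(s2$episodes$condition == "control"), 4L)
  expect_equal(sum(s2$episodes$condition == "transfer"), 6L)
  expect_equal(sum(s2$episodes$condition == "open"), 2L)

  # cues predict mappings with 100% reliability in session 1
  cue_map <- unique(data.frame(
    cue = s1$trials$cue,
    mapping = s1$episodes$mapping[s1$trials$episode_index]))
  expect_equal(anyDuplicated(cue_map$cue), 0L)

  # at most one cue change within any episode
  for (e in unique(s1$trials$episode_index)) {
    cues <- s1$trials$cue[s1$trials$episode_index == e]
    expect_lte(sum(diff(cues) != 0), 1L)
  }

  # transfer/open episodes carry cues never seen in session 1
  test_rows <- s2$trials[s2$trials$condition %in% c("transfer", "open"), ]
  expect_equal(length(intersect(unique(test_rows$cue),
                                unique(s1$trials$cue))), 0L)
  # control episodes reuse the dual-cue mapping with its learned cues
  ctrl <- s2$trials[s2$trials$condition == "control", ]
  expect_true(all(ctrl$cue %in% c(3L, 4L)))
  # the open-episode mapping is incongruent with all recurrent mappings
  open_map <- unique(s2$episodes$mapping[s2$episodes$condition == "open"])
  for (m in 1:3) {
    expect_equal(mapping_overlap(s2$mappings[open_map, ], s2$mappings[m, ]), 0L)
  }
})

test_that("every stimulus appears in every episode", {
  proto <- generate_open_session(3)
  counts <- tapply(proto$trials$stimulus, proto$trials$episode_index,
                   function(s) length(unique(s)))
  expect_true(all(counts == 3L))
})

test_that("probabilistic feedback matches the 90/10 schedule", {
  mapping <- c(2L, 3L, 1L)
  set.seed(99)
  hits <- replicate(1e5, sample_feedback(mapping, 1L, 2L))
  expect_lt(abs(mean(hits) - 0.9), 3 * sqrt(0.9 * 0.1 / 1e5))
  set.seed(100)
  miss <- replicate(2e4, sample_feedback(mapping, 1L, 4L))
  expect_lt(abs(mean(miss) - 0.1), 3 * sqrt(0.9 * 0.1 / 2e4))
  # determinism under a fixed seed
  set.seed(7); a <- replicate(100, sample_feedback(mapping, 2L, 3L))
  set.seed(7); b <- replicate(100, sample_feedback(mapping, 2L, 3L))
  expect_identical(a, b)
})

test_that("protocols survive a JSON round trip and regenerate from seed", {
  proto <- generate_recurrent_session(17)
  path <- tempfile(fileext = ".json")
  write_protocol(proto, path)
  back <- read_protocol(path)
  expect_equal(back$mappings, proto$mappings)
  expect_equal(back$episodes$mapping, proto$episodes$mapping)
  expect_equal(back$trials$stimulus, proto$trials$stimulus)
  expect_equal(back$trials$correct_response, proto$trials$correct_response)
  regen <- generate_recurrent_session(17)
  expect_identical(regen$trials, proto$trials)
  unlink(path)
})
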