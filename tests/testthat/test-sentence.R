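test_that("feature indexes decode to lead pairs, inverting the flattening", {
  expect_equal(feature_symbol_pair(1), c(from = 1L, to = 1L))
  expect_equal(feature_symbol_pair(144), c(from = 12L, to = 12L))
  expect_equal(feature_symbol_pair(24), c(from = 2L, to = 12L))
  # exhaustive round trip over all 144 cells
  probe <- matrix(seq(0.001, 0.144, by = 0.001), 12, 12, byrow = TRUE)
  fv <- flatten_features(probe)
  for (u in 1:144) {
    pr <- feature_symbol_pair(u)
    expect_identical(fv[u], probe[pr[1], pr[2]])
  }
  expect_error(feature_symbol_pair(0), class = "cardioish_index_error")
  expect_error(feature_symbol_pair(145), class = "cardioish_index_error")
})

test_that("sentences concatenate decoded symbol pairs in selection order", {
  s1 <- build_sentence(1L)
  expect_equal(format(s1), "Ld1Ld1")
  expect_length(s1$tokens, 2L)
  s2 <- build_sentence(c(24L, 1L))
  expect_equal(format(s2), "Ld2V6LLd1Ld1")
  expect_equal(s2$sind, c(2L, 12L, 1L, 1L))
  set.seed(3)
  for (n in c(3, 7, 20)) {
    s <- build_sentence(sample.int(144, n))
    expect_length(s$tokens, 2L * n)
    expect_equal(s$nosf, n)
  }
  expect_warning(s0 <- build_sentence(integer(0)), "Empty")
  expect_length(s0$tokens, 0L)
  expect_error(build_sentence(c(1L, 200L)), class = "cardioish_index_error")
})

test_that("tokenization splits 3-character symbols and validates them", {
  expect_equal(tokenize_sentence("AVLV1SV2S"), c("AVL", "V1S", "V2S"))
  expect_identical(tokenize_sentence(""), character(0))
  expect_error(tokenize_sentence("AVLV1"), class = "cardioish_parse_error")
  expect_error(tokenize_sentence("AVLXYZ"), class = "cardioish_parse_error")
  # round trip through the rendered form
  s <- build_sentence(c(5L, 100L, 31L))
  expect_identical(tokenize_sentence(format(s)), s$tokens)
})

test_that("the published example sentences reproduce their frequency rows", {
  mi <- read_sentence(example_sentence_path("mi"))
  expect_length(mi$tokens, 194L)   # sum of the printed frequencies
  dist_mi <- symbol_distribution(mi$tokens)
  expect_equal(dist_mi$count, mi_frequency_counts)
  expect_equal(dist_mi$count[dist_mi$symbol == "Ld3"], 13L)

  mental <- read_sentence(example_sentence_path("mental"))
  expect_length(mental$tokens, sum(mental_frequency_counts))
  expect_equal(symbol_distribution(mental$tokens)$count, mental_frequency_counts)
})

test_that("sentence entropies reproduce the published worked examples", {
  expect_equal(round(shannon_entropy(mi_frequency_counts), 4), 3.5752)
  expect_equal(round(shannon_entropy(mental_frequency_counts), 4), 3.5637)
  expect_equal(round(shannon_entropy(rep(5, 12)), 4), 3.5850)
  expect_equal(round(log2(12), 4), 3.5850)
  expect_equal(shannon_entropy(c(10, rep(0, 11))), 0)
})

test_that("symbol distributions are proper and bounded by log2(12)", {
  s <- build_sentence(c(3L, 50L, 50L, 121L))
  d <- symbol_distribution(s)
  expect_equal(sum(d$probability), 1)
  expect_equal(sum(d$count), 2L * s$nosf)
  h <- attr(d, "entropy_bits")
  expect_gte(h, 0)
  expect_lte(h, log2(12))
  expect_error(symbol_distribution(character(0)), class = "cardioish_data_error")
})

test_that("sentence transition tables count consecutive token pairs", {
  t1 <- sentence_transition_table(c("Ld1", "Ld1"))
  expect_equal(t1["Ld1", "Ld1"], 1L)
  expect_equal(sum(t1), 1L)
  t2 <- sentence_transition_table(tokenize_sentence("Ld2V6LLd1Ld1"))
  expect_equal(t2["Ld2", "V6L"], 1L)
  expect_equal(t2["V6L", "Ld1"], 1L)
  expect_equal(t2["Ld1", "Ld1"], 1L)
  expect_equal(sum(t2), 3L)
  set.seed(4)
  s <- build_sentence(sample.int(144, 12))
  expect_equal(sum(sentence_transition_table(s)), length(s$tokens) - 1L)
  expect_warning(empty <- sentence_transition_table(character(0)), "two tokens")
  expect_equal(sum(empty), 0L)
})
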