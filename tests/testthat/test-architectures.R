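test_that("architecture network counts adjacencies over unique architectures", {
  net <- build_architecture_network(list(c("A", "B", "C"), c("A", "B")))
  ed <- igraph::as_data_frame(net)
  expect_equal(ed$weight[ed$from == "A" & ed$to == "B"], 2)
  expect_equal(ed$weight[ed$from == "B" & ed$to == "C"], 1)
  expect_false(any(ed$from == "B" & ed$to == "A"))  # directed N->C

  dup <- build_architecture_network(rep(list(c("A", "B")), 5))
  expect_equal(igraph::E(dup)$weight, 1)           # dedupe collapses copies
  nodedup <- build_architecture_network(rep(list(c("A", "B")), 5), dedupe = FALSE)
  expect_equal(igraph::E(nodedup)$weight, 5)

  loop <- build_architecture_network(list(c("A", "A")))
  ed <- igraph::as_data_frame(loop)
  expect_equal(ed, data.frame(from = "A", to = "A", weight = 1))

  solo <- build_architecture_network(list("A", c("B", "C")))
  expect_true("A" %in% igraph::V(solo)$name)       # node only, no edge
  expect_equal(igraph::degree(solo, "A"), c(A = 0))
})

test_that("network weights match brute-force pair counting on random architectures", {
  set.seed(10)
  doms <- LETTERS[1:6]
  archs <- lapply(1:50, function(i)
    sample(doms, sample(1:4, 1), replace = TRUE))
  net <- build_architecture_network(archs)
  uniq <- unique(archs)
  ed <- igraph::as_data_frame(net)
  for (r in seq_len(nrow(ed))) {
    cnt <- sum(vapply(uniq, function(a) {
      if (length(a) < 2L) return(FALSE)
      any(a[-length(a)] == ed$from[r] & a[-1] == ed$to[r])
    }, logical(1)))
    expect_equal(ed$weight[r], cnt)
  }
  # completeness: every adjacent pair in some unique architecture has an edge
  for (a in uniq) {
    if (length(a) < 2L) next
    for (i in seq_len(length(a) - 1L))
      expect_true(igraph::are_adjacent(net, a[i], a[i + 1L]))
  }
})

test_that("retrieval network applies the strict p-value rule and keeps best hits", {
  ht <- data.frame(query = c("X", "X", "X", "Y"),
                   hit = c("Y", "Y", "Z", "Z"),
                   p_value = c(1e-3, 1e-8, 1e-4, 1e-6))
  net <- build_retrieval_network(ht, p_threshold = 1e-4)
  ed <- igraph::as_data_frame(net)
  expect_equal(ed$weight[ed$from == "X" & ed$to == "Y"], 8)   # min-p rule
  expect_false(any(ed$from == "X" & ed$to == "Z"))            # p == 1e-4 excluded
  expect_equal(ed$weight[ed$from == "Y" & ed$to == "Z"], 6)

  # duplicates with worse p never change the network
  worse <- rbind(ht, data.frame(query = "Y", hit = "Z", p_value = 0.5))
  net2 <- build_retrieval_network(worse, p_threshold = 1e-4)
  expect_equal(igraph::as_data_frame(net2), ed)

  expect_error(build_retrieval_network(
    data.frame(query = "A", hit = "B", p_value = 0)), "> 0")
})

test_that("positional counts classify occurrences and build the slot expectation", {
  pc <- positional_counts("X", list(c("X", "A"), c("X", "B", "C")))
  expect_equal(c(pc$n_Nterm, pc$n_internal, pc$n_Cterm), c(2L, 0L, 0L))
  expect_equal(pc$slot_expectation,
               c(1 / 2 + 1 / 3, 0 + 1 / 3, 1 / 2 + 1 / 3) / 2)
  expect_equal(sum(pc$slot_expectation), 1)

  internal <- positional_counts("X", list(c("A", "X", "B")))
  expect_equal(internal$n_internal, 1L)

  # single-domain architectures are excluded from counting
  mixed <- positional_counts("X", list("X", c("X", "A")))
  expect_equal(mixed$n_Nterm + mixed$n_internal + mixed$n_Cterm, 1L)
  expect_error(positional_counts("X", list("X")), "absent")
})

test_that("positional bias chi-squared reproduces the closed-form case", {
  pc <- structure(list(domain = "X", n_Nterm = 10L, n_internal = 0L,
                       n_Cterm = 0L, slot_expectation = rep(1 / 3, 3)),
                  class = "positional_counts")
  res <- positional_bias_test(pc)
  expect_equal(res$chi2, 20.0)
  expect_equal(res$df, 2L)
  expect_equal(res$p, exp(-10), tolerance = 1e-12)
  # cross-check against the standard goodness-of-fit implementation
  ref <- suppressWarnings(stats::chisq.test(c(10, 0, 0), p = rep(1 / 3, 3)))
  expect_equal(res$chi2, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  flat <- structure(list(domain = "X", n_Nterm = 5L, n_internal = 5L,
                         n_Cterm = 5L, slot_expectation = rep(1 / 3, 3)),
                    class = "positional_counts")
  res0 <- positional_bias_test(flat)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)

  k2 <- structure(list(domain = "X", n_Nterm = 3L, n_internal = 1L,
                       n_Cterm = 2L, slot_expectation = c(0.5, 0, 0.5)),
                  class = "positional_counts")
  expect_error(positional_bias_test(k2), "merge")
})

test_that("a planted strong N-terminal bias is detected with high power", {
  set.seed(31)
  pvals <- replicate(30, {
    archs <- generate_architectures(100L, "X",
                                    position_probs = c(0.9, 0.05, 0.05),
                                    k_range = c(2L, 5L))
    positional_bias_test(positional_counts("X", archs))$p
  })
  expect_gte(mean(pvals < 0.01), 0.95)
})
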