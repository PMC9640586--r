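test_that("haplotype collapsing counts identical sequences and labels by first occurrence", {
  aln <- aligned_sequences(paste0("s", 1:5),
                           c("ACGT", "ACGT", "ACGT", "ACGA", "ACGA"))
  tab <- collapse_haplotypes(aln)
  expect_equal(tab$haplotype_id, c("A", "B"))
  expect_equal(tab$count, c(3L, 2L))
  expect_equal(tab$frequency, c(0.6, 0.4))
  expect_equal(sum(tab$count), nrow(aln))

  # single sequence
  one <- collapse_haplotypes(aligned_sequences("x", "ACGT"))
  expect_equal(one$frequency, 1)

  # two haplotypes at 7/13 and 6/13 print as 53.8 / 46.2
  aln2 <- aligned_sequences(paste0("s", 1:13),
                            c(rep("AAAA", 7), rep("AAAT", 6)))
  tab2 <- collapse_haplotypes(aln2)
  expect_equal(round(100 * tab2$frequency, 1), c(53.8, 46.2))

  # order invariance up to label permutation: counts preserved
  perm <- aln2[c(13:1), ]
  class(perm) <- class(aln2)
  tab3 <- collapse_haplotypes(perm)
  expect_equal(sort(tab3$count), sort(tab2$count))

  # an N-bearing sequence is its own haplotype (exact-match identity)
  alnN <- aligned_sequences(c("a", "b"), c("ACGT", "ACGN"))
  expect_equal(nrow(collapse_haplotypes(alnN)), 2L)

  # per-locality tallies
  alnL <- aligned_sequences(paste0("s", 1:4), c("AA", "AA", "AT", "AT"),
                            locality = c("x", "y", "x", "x"))
  pl <- attr(collapse_haplotypes(alnL), "per_locality")
  expect_equal(as.integer(pl["x", ]), c(1L, 2L))
})

test_that("alignment ingestion enforces equal lengths and a clean alphabet", {
  expect_error(aligned_sequences(c("a", "b"), c("ACGT", "ACG")), "b")
  expect_error(aligned_sequences("a", "ACXT"), "invalid residue")
  # lowercase uppercased
  expect_equal(aligned_sequences("a", "acgt")$residues, "ACGT")
})

test_that("pairwise differences use pairwise deletion of gaps and ambiguities", {
  expect_equal(pairwise_differences("AAAATTTTCC", "AAAATTTTCC"),
               list(diff_count = 0L, compared_sites = 10L))
  expect_equal(pairwise_differences("AAAATTTTCC", "AAAATTTTGG"),
               list(diff_count = 2L, compared_sites = 10L))
  # hand count: gap site and N site excluded
  expect_equal(pairwise_differences("AA-ANTTT", "AAAAATTT"),
               list(diff_count = 0L, compared_sites = 6L))
  # symmetry
  a <- "ACGTNRG-"; b <- "ACTT-AGC"
  expect_equal(pairwise_differences(a, b), pairwise_differences(b, a))
  expect_error(pairwise_differences("ACG", "AC"), "unequal")
})

test_that("coalescent sampling-sufficiency formula and its inverse agree with printed values", {
  expect_equal(prob_all_haplotypes_sampled(39), 0.95)
  expect_equal(prob_all_haplotypes_sampled(1), 0)
  expect_equal(prob_all_haplotypes_sampled(199), 0.99)
  expect_error(prob_all_haplotypes_sampled(0), ">= 1")

  expect_identical(min_n_for_prob(0.95), 39L)
  expect_identical(min_n_for_prob(0), 1L)
  expect_identical(min_n_for_prob(0.99), 199L)
  expect_error(min_n_for_prob(1), "unreachable")

  # round trip: the inverse at the achieved probability returns at most n
  for (n in c(1L, 2L, 5L, 13L, 39L, 100L, 1234L)) {
    expect_identical(min_n_for_prob(prob_all_haplotypes_sampled(n)), n)
    p_below <- max(0, prob_all_haplotypes_sampled(n) - 1e-6)
    expect_lte(min_n_for_prob(p_below), n)
  }
})

test_that("detection sample-size formula matches analytic values and is monotone", {
  expect_equal(min_detection_sample_size(0.5, 0.75), 2.0)
  expect_equal(min_detection_sample_size(0.462, 0.95), 4.83,
               tolerance = 5e-3)
  expect_identical(min_detection_sample_size(0.462, 0.95, ceiling = TRUE), 5)
  # strictly decreasing in p, increasing in beta; unbounded as p -> 0
  expect_gt(min_detection_sample_size(0.01, 0.95),
            min_detection_sample_size(0.1, 0.95))
  ps <- c(0.05, 0.1, 0.25, 0.5, 0.9)
  expect_true(all(diff(min_detection_sample_size(ps, 0.95)) < 0))
  bs <- c(0.5, 0.75, 0.9, 0.99)
  expect_true(all(diff(min_detection_sample_size(0.3, bs)) > 0))
  expect_error(min_detection_sample_size(1, 0.95), "p_freq")
  expect_error(min_detection_sample_size(0.5, 0), "beta")
})

test_that("iterative sufficiency trace updates the rare frequency step by step", {
  # alternating stream, equal final counts: p = 0.5, n = ln(.05)/ln(.5)
  tr <- iterative_sufficiency(rep(c("A", "B"), 5), beta = 0.95)
  expect_equal(nrow(tr), 10L)
  expect_equal(tr$rare_frequency[10], 0.5)
  expect_equal(attr(tr, "final"), log(0.05) / log(0.5))
  expect_equal(round(attr(tr, "final"), 2), 4.32)

  # first step has one haplotype: not computable
  expect_true(is.na(tr$n_min_detect[1]))

  # a single-haplotype stream is never computable
  allA <- iterative_sufficiency(rep("A", 6))
  expect_true(all(is.na(allA$n_min_detect)))

  # 13-sample stream ending at 7/6 matches the direct formula call
  stream <- c(rep("A", 7), rep("B", 6))
  tr13 <- iterative_sufficiency(stream, beta = 0.95)
  expect_equal(tr13$rare_frequency[13], 6 / 13)
  expect_equal(tr13$n_min_detect[13],
               min_detection_sample_size(6 / 13, 0.95))

  # deterministic for a fixed ordering
  expect_identical(as.data.frame(tr13),
                   as.data.frame(iterative_sufficiency(stream, beta = 0.95)))
  expect_error(iterative_sufficiency("A"), "at least 2")
})
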