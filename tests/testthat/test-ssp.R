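toy_msa <- function() {
  labeled_msa(
    c(
      t1 = "AC-DEF", s2 = "ACADEF", s3 = "ACVDEF",
      s4 = "GCWDEF", s5 = "GCWDEF", s6 = "GCYDEF"
    ),
    labels = c("S1", "S1", "S1", "S2", "S2", "S2"),
    template = "t1"
  )
}

test_that("pairwise identity ignores doubly gapped columns", {
  expect_equal(pairwise_identity("ACDEF", "ACDEF"), 1.0)
  expect_equal(pairwise_identity("AAAAA", "CCCCC"), 0.0)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV"), 0.9)
  # gap vs residue is a mismatch; gap vs gap drops out of the denominator
  expect_equal(pairwise_identity("A-C-", "AAC-"), 2 / 3)
  expect_error(pairwise_identity("AC", "ACD"), "equal length")
})

test_that("redundancy filtering keeps one representative per linkage cluster", {
  msa <- labeled_msa(
    c(
      t1 = "ACDEFGHIKL", dup = "ACDEFGHIKL", near = "ACDEFGHIKV",
      far = "WWWWWWWWWW"
    ),
    labels = c("S1", "S1", "S1", "S2"), template = "t1"
  )
  # t1~dup are identical and collapse; identity(t1, near) = 0.9 < 0.95 so
  # near survives at the default threshold but merges at 0.85
  kept <- filter_redundant(msa, threshold = 0.95)
  expect_setequal(kept$id, c("t1", "near", "far"))
  kept2 <- filter_redundant(msa, threshold = 0.85)
  expect_setequal(kept2$id, c("t1", "far"))

  # chain A~B~C with A-C below threshold still forms one single-linkage
  # cluster; brute-force transitive closure agrees
  chain <- labeled_msa(
    c(
      a = "AAAAAAAAAAAAAAAAAAAA",
      b = "AAAAAAAAAAAAAAAAAAAC",
      c = "AAAAAAAAAAAAAAAAAACC",
      out = "WWWWWWWWWWWWWWWWWWWW"
    ),
    labels = rep("S1", 4), template = "a"
  )
  # a-b 0.95, b-c 0.95, a-c 0.90; at threshold 0.94 a,b,c merge
  kept3 <- filter_redundant(chain, threshold = 0.94)
  expect_setequal(kept3$id, c("a", "out"))
  # brute-force closure oracle
  ids <- chain$id
  idm <- outer(seq_along(ids), seq_along(ids), Vectorize(function(i, j) {
    pairwise_identity(chain$seq[i], chain$seq[j])
  }))
  adj <- idm > 0.94
  reach <- adj | diag(4)
  for (k in 1:4) reach <- reach | (reach %*% reach > 0)
  expect_equal(sum(!duplicated(apply(reach, 1, paste, collapse = ""))), length(kept3$id))

  # template always retained even when not first in its cluster
  msa2 <- labeled_msa(
    c(first = "ACDEFGHIKL", tmpl = "ACDEFGHIKL"),
    labels = c("S1", "S1"), template = "tmpl"
  )
  expect_equal(filter_redundant(msa2, 0.95)$id, "tmpl")
})

test_that("bits-per-column separates self from shuffled sequences", {
  tmpl <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR"
  self_bits <- bits_per_column(tmpl, tmpl)
  expect_gt(self_bits, 0.25)
  withr::with_seed(7, {
    shuffled <- paste(sample(strsplit(tmpl, "")[[1]]), collapse = "")
  })
  expect_lt(bits_per_column(shuffled, tmpl), self_bits)
  expect_error(bits_per_column("", tmpl), "empty")
})

test_that("the bits filter discards strictly-below-threshold sequences only", {
  msa <- labeled_msa(
    c(
      t1 = "MKTAYIAKQRQISFVKSHFSRQ",
      same = "MKTAYIAKQRQISFVKSHFSRQ",
      junk = "GGGGGGGGGGGGGGGGGGGGGG"
    ),
    labels = c("S1", "S1", "S2"), template = "t1"
  )
  bits_junk <- bits_per_column("GGGGGGGGGGGGGGGGGGGGGG", msa$seq[1])
  kept <- filter_low_scoring(msa, threshold = 0.25)
  expect_true("same" %in% kept$id)
  expect_equal("junk" %in% kept$id, bits_junk >= 0.25)
  # boundary: a sequence exactly at its own threshold value is retained
  kept_at <- filter_low_scoring(msa, threshold = bits_junk)
  expect_true("junk" %in% kept_at$id)
})

test_that("specificity score is mutual information over the column", {
  col <- c(rep("E", 6), rep("A", 6))
  lab <- rep(c("S1", "S2"), each = 6)
  expect_equal(specificity_score(col, lab, correction = "none"), 1.0)

  # identical distribution in both subfamilies: zero before correction
  col2 <- rep(c("E", "A"), 6)
  expect_equal(specificity_score(col2, lab, correction = "none"), 0, tolerance = 1e-12)

  # 12-sequence toy column equals the brute-force contingency-table MI
  set.seed(77)
  col3 <- sample(c("A", "D", "N", "-"), 12, replace = TRUE, prob = c(.4, .3, .2, .1))
  col3[1:2] <- c("A", "A") # ensure both subfamilies have >= 2 non-gaps
  col3[7:8] <- c("D", "D")
  expect_equal(
    specificity_score(col3, lab, correction = "none"),
    mi_from_table(col3, lab),
    tolerance = 1e-12
  )
  # Miller-Madow shifts by the analytic bias term
  keep <- col3 != "-"
  tab <- table(col3[keep], lab[keep])
  n <- sum(tab)
  corr <- ((sum(rowSums(tab) > 0) - 1) + (sum(colSums(tab) > 0) - 1) -
    (sum(tab > 0) - 1)) / (2 * n * log(2))
  expect_equal(
    specificity_score(col3, lab, correction = "miller-madow"),
    max(mi_from_table(col3, lab) + corr, 0),
    tolerance = 1e-12
  )

  expect_error(specificity_score(c("E", "A"), c("S1", "S2")), ">= 2")
})

test_that("frequency tables format like 'N(50%) D(50%)'", {
  col <- c(rep("N", 10), rep("D", 10), rep("H", 4))
  lab <- c(rep("S1", 20), rep("S4", 4))
  ft <- frequency_table(col, lab)
  fmt <- format_frequencies(ft)
  expect_equal(unname(fmt["S1"]), "D(50%) N(50%)")
  expect_equal(unname(fmt["S4"]), "H(100%)")
  ft2 <- frequency_table(c("A", "A", "A", "G"), rep("S1", 4))
  expect_equal(unname(format_frequencies(ft2)), "A(75%) G(25%)")
  # gaps are excluded from the percentages
  ft3 <- frequency_table(c("A", "A", "-", "-"), rep("S1", 4))
  expect_equal(unname(format_frequencies(ft3)), "A(100%)")
})

test_that("columns map to template residue numbers by non-gap counting", {
  msa <- toy_msa() # template t1 = "AC-DEF"
  expect_equal(map_column_to_template(msa, 1)$resno, 1L)
  expect_true(is.na(map_column_to_template(msa, 3)$resno))
  expect_equal(map_column_to_template(msa, 4)$resno, 3L)
  # independent cumulative count over every column
  tmpl <- strsplit("AC-DEF", "")[[1]]
  for (j in seq_along(tmpl)) {
    expected <- if (tmpl[j] == "-") NA_integer_ else sum(tmpl[1:j] != "-")
    expect_equal(map_column_to_template(msa, j)$resno, expected)
  }
})

test_that("rank_ssp ranks planted columns first and is order-invariant", {
  msa <- gen_labeled_msa(
    seqs_per_subfamily = c(8, 8), n_columns = 30, n_planted = 2,
    noise = 0, background_conservation = 1, seed = 101
  )
  planted <- attr(msa, "planted_columns")
  cfg <- ssp_config(seed = 11, n_permutations = 200)
  ranked <- rank_ssp(msa, cfg)
  expect_setequal(head(ranked$column, 2), planted)
  # noise-free planted columns in 2 equal subfamilies score exactly 1 bit
  # before correction
  cfg_plain <- ssp_config(seed = 11, n_permutations = 200, correction = "none")
  ranked_plain <- rank_ssp(msa, cfg_plain)
  expect_equal(ranked_plain$score[ranked_plain$column %in% planted], c(1, 1))
  # noise-free background columns score 0
  expect_equal(max(ranked_plain$score[!ranked_plain$column %in% planted]), 0)

  # shuffling sequence order together with labels leaves scores unchanged
  perm <- withr::with_seed(5, sample(nrow(msa)))
  shuffled <- labeled_msa(
    setNames(msa$seq[perm], msa$id[perm]), msa$subfamily[perm],
    template = attr(msa, "template")
  )
  ranked_shuf <- rank_ssp(shuffled, cfg)
  expect_equal(
    ranked_shuf$score[order(ranked_shuf$column)],
    ranked$score[order(ranked$column)],
    tolerance = 1e-12
  )
})

test_that("a label-independent alignment shows only the nominal false-positive rate", {
  # identical sequences in every subfamily: every column's residue
  # distribution is label-independent
  seqs <- setNames(rep("ACDEFGHIKLMNPQRSTVWY", 12), paste0("s", 1:12))
  msa <- labeled_msa(seqs, rep(c("S1", "S2", "S3"), each = 4), template = "s1")
  ranked <- rank_ssp(msa, ssp_config(seed = 21, n_permutations = 200))
  expect_true(all(ranked$score == 0 | ranked$p_value > 0.05))
  expect_error(
    rank_ssp(
      labeled_msa(seqs[1:4], rep("S1", 4), template = "s1"),
      ssp_config(seed = 21, n_permutations = 200)
    ),
    "2 subfamilies"
  )
})

test_that("high-gap columns are skipped and flagged", {
  msa <- labeled_msa(
    c(a = "A-AA", b = "A-AA", c = "C-CC", d = "C-CC", e = "CACC", f = "CACC"),
    labels = c("S1", "S1", "S2", "S2", "S2", "S2"), template = "a"
  )
  ranked <- rank_ssp(msa, ssp_config(seed = 31, n_permutations = 100, max_gap_fraction = 0.5))
  expect_equal(attr(ranked, "skipped_columns"), 2L)
  expect_false(2 %in% ranked$column)
})
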