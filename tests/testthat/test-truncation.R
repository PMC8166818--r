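test_that("translation follows the standard code with first-stop semantics", {
  expect_equal(translate_cds("ATGAAATAA"), list(protein = "MK", stop_codon = 3L))
  expect_equal(translate_cds("ATGTGA"), list(protein = "M", stop_codon = 2L))
  expect_equal(translate_cds("ATGCTGACCTAA"),
               list(protein = "MLT", stop_codon = 4L))
  # N translates to X and never terminates
  expect_equal(translate_cds("ATGTNATAA")$protein, "MX")
  expect_error(translate_cds("AT"), "shorter")
  # trailing partial codon ignored
  expect_equal(translate_cds("ATGAAAT")$protein, "MK")

  for (seed in 1:25) {
    cds <- generate_random_cds(sample(10:60, 1), seed)
    expect_equal(translate_cds(cds), oracle_translate(cds))
  }
})

test_that("pairwise CDS alignment is optimal and classifies columns", {
  ref <- "ATGCTGACCTAA"
  pair <- paralog_pair(ref, ref)
  aln <- align_paralogs(pair)
  expect_true(all(aln$columns$class == "match"))
  expect_equal(gsub("-", "", aln$ref), ref)

  # one deleted base -> exactly one single-base deletion column
  pair2 <- paralog_pair(ref, "ATGTGACCTAA")
  aln2 <- align_paralogs(pair2)
  expect_equal(sum(aln2$columns$class == "deletion_in_alt"), 1L)
  expect_equal(gsub("-", "", aln2$alt), "ATGTGACCTAA")

  # one substitution -> zero gaps, one substitution column
  pair3 <- paralog_pair("ATGTTACGTTAA", "ATGTGACGTTAA")
  aln3 <- align_paralogs(pair3)
  expect_equal(sum(aln3$columns$class == "substitution"), 1L)
  expect_false(any(grepl("-", c(aln3$ref, aln3$alt))))

  # returned score equals the DP optimum from an independent full matrix
  for (seed in 1:8) {
    a <- generate_random_cds(sample(8:30, 1), seed)
    b <- plant_with_retry(sample(c("deletion_frameshift", "substitution_nonsense",
                                   "insertion_frameshift"), 1),
                          seed = seed, n_codons = 30L)$plant$cds
    aln <- align_paralogs(paralog_pair(a, b))
    expect_equal(aln$score, oracle_align_score(a, b))
  }
})

test_that("worked termination examples are typed correctly", {
  # deletion of base 4 from ATG CTG ACC TAA: M-L-T-* becomes M-*
  pair <- paralog_pair("ATGCTGACCTAA", "ATGTGACCTAA")
  rep <- classify_mechanism(pair)
  expect_true(rep$premature)
  expect_equal(rep$alt_stop_codon_index, 2L)
  expect_equal(rep$mechanism, "deletion_frameshift")
  expect_equal(rep$causal_edit$type, "deletion")

  # sense codon TTA corrected to the stop TGA by one mid-base substitution
  pair2 <- paralog_pair("ATGTTACGTTAA", "ATGTGACGTTAA")
  rep2 <- classify_mechanism(pair2)
  expect_equal(rep2$mechanism, "substitution_nonsense")
  expect_equal(rep2$alt_stop_codon_index, 2L)
  expect_equal(rep2$causal_edit$coordinate, 5)

  # identical paralogs: no premature stop, mechanism none
  rep3 <- classify_mechanism(paralog_pair("ATGCTGACCTAA", "ATGCTGACCTAA"))
  expect_false(rep3$premature)
  expect_equal(rep3$mechanism, "none")
})

test_that("planted mutations are recovered with exact coordinates", {
  mechs <- c("insertion_stop", "substitution_nonsense",
             "deletion_frameshift", "insertion_frameshift")
  for (m in mechs) {
    for (seed in 1:10) {
      pr <- plant_with_retry(m, seed = 100 * match(m, mechs) + seed)
      rep <- classify_mechanism(paralog_pair(pr$ref, pr$plant$cds))
      expect_equal(rep$mechanism, m, label = sprintf("%s seed %d", m, seed))
      expect_equal(rep$causal_edit$coordinate, pr$plant$truth$coordinate,
                   label = sprintf("%s seed %d coordinate", m, seed))
      expect_equal(rep$alt_stop_codon_index, pr$plant$truth$stop_codon)
      expect_true(rep$alt_stop_codon_index >= pr$plant$truth$target_codon)
      expect_true(rep$alt_stop_codon_index < rep$ref_length_codons)
    }
  }
})

test_that("anchor offsets and the termination window behave as specified", {
  # reference: M K R L L L L L L L * ; derived stops at codon 8 (offset 5
  # from the arginine at codon 3; TTA -> TGA is a single substitution)
  ref <- paste0("ATG", "AAA", "CGT", strrep("TTA", 7), "TAA")
  plant <- plant_truncation(ref, "substitution_nonsense", 8L, seed = 1)
  rep <- classify_mechanism(paralog_pair(ref, plant$cds))
  expect_equal(rep$anchor_offset, 5L)
  expect_true(rep$within_window)
  expect_true(termination_window_check(rep))
  expect_false(termination_window_check(rep, run_config(window_lo = 1,
                                                        window_hi = 3)))

  # no arginine anywhere upstream: indeterminate, not FALSE
  ref2 <- paste0("ATG", strrep("TTA", 9), "TAA")
  plant2 <- plant_truncation(ref2, "substitution_nonsense", 6L, seed = 1)
  rep2 <- classify_mechanism(paralog_pair(ref2, plant2$cds))
  expect_false(rep2$anchor_found)
  expect_true(is.na(termination_window_check(rep2)))

  expect_error(termination_window_check(
    classify_mechanism(paralog_pair(ref, ref))), "premature")
})

test_that("paralog pair validation enforces the reference ORF contract", {
  expect_error(paralog_pair("ATGAAA", "ATGTAA"), "stop")        # no ref stop
  expect_error(paralog_pair("ATGTAATAA", "ATGTAA"), "stop")     # internal stop
  expect_error(paralog_pair("ATGAAATAA", "TTGTAA"), "ATG")
  expect_error(paralog_pair("ATGAAATA", "ATGTAA"), "multiple of 3")
})
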