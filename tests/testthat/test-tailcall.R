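test_that("tail classification follows the four-class definition", {
  res <- classify_tail(c("", "AAAAAAA", "AAATT", "TT", "AAGAA", "AAAUU"))
  expect_equal(res$tail_class, c("NONE", "A", "AU", "U", "OTHER", "AU"))
  expect_equal(res$a_len, c(0L, 7L, 3L, 0L, 0L, 3L))
  expect_equal(res$u_len, c(0L, 0L, 2L, 2L, 0L, 2L))
  expect_error(classify_tail("AAXTT"), "A/C/G/T/U/N")
})

test_that("tolerant classification corrects isolated substitutions in long tails", {
  # one G inside a 12-A run: OTHER in strict mode, A with tolerance 1
  expect_equal(classify_tail("AAAAAGAAAAAA")$tail_class, "OTHER")
  expect_equal(classify_tail("AAAAAGAAAAAA", tolerance = 1)$tail_class, "A")
  expect_equal(classify_tail("AAAAAGAAAAAA", tolerance = 1)$a_len, 12L)
  # two isolated errors need tolerance 2
  expect_equal(classify_tail("AAGAAAAACAAA", tolerance = 1)$tail_class,
               "OTHER")
  expect_equal(classify_tail("AAGAAAAACAAA", tolerance = 2)$tail_class, "A")
  # short tails are never corrected
  expect_equal(classify_tail("AAGAA", tolerance = 2)$tail_class, "OTHER")
})

test_that("the templated end anchors at the terminus and yields the NTA", {
  refs <- test_refs()
  ref <- refs[refs$name == "L1rep", ]
  amp <- ref$sequence
  suffix30 <- substr(amp, nchar(amp) - 29, nchar(amp))

  res <- anchor_templated_end(amp, paste0(suffix30, "AAAAA"), ref)
  expect_equal(res$fate, "ok")
  expect_equal(res$anchor, nchar(amp) - 1L)
  expect_equal(res$nta, "AAAAA")

  # no tail at all
  res0 <- anchor_templated_end(amp, suffix30, ref)
  expect_equal(res0$nta, "")

  # one mismatch in a 40-nt templated span is inside the 0.05 budget
  tf <- paste0(substr(amp, 21, 60), "AAA")
  substr(tf, 5, 5) <- if (substr(tf, 5, 5) == "A") "C" else "A"
  res1 <- anchor_templated_end(amp, tf, ref, max_mismatch_rate = 0.05)
  expect_equal(res1$fate, "ok")
  expect_equal(res1$nta, "AAA")

  # random segment does not anchor
  set.seed(4)
  junk <- paste0(sample(c("C", "G"), 60, TRUE), collapse = "")
  expect_equal(anchor_templated_end(junk, junk, ref)$fate, "unanchored")
  expect_equal(anchor_templated_end("ACGT", "ACGT", ref)$fate, "short_anchor")
})

test_that("terminal reference-matching As are assigned to the template", {
  # reference ending ...GAA: a read ending GAAAA carries only 2 extra As
  ref <- tibble::tibble(
    name = "endsA",
    sequence = paste0("CATCCCACTATATCGCTCCGTGTATATCGAGTCATTCGTTG", "GAA"),
    primer_offset = 0L)
  ref$length <- nchar(ref$sequence)
  tf <- paste0(ref$sequence, "AA")
  res <- anchor_templated_end(ref$sequence, tf, ref)
  expect_equal(res$fate, "ok")
  expect_equal(res$nta, "AA")
  expect_equal(res$anchor, ref$length - 1L)
})

test_that("length estimation prefers R2, falls back to R1, then censors", {
  # exact from R2
  est <- estimate_length("AAAA", NA_character_, FALSE, window = 80)
  expect_equal(est$total_len, 4L)
  expect_false(est$censored)
  # R2 overran the payload; R1 view bounded by the adapter is exact
  est1 <- estimate_length(NA_character_, strrep("A", 12), TRUE, window = 80)
  expect_equal(est1$total_len, 12L)
  expect_false(est1$censored)
  # neither view bounded: censored at the window, class preserved from
  # the R1 prefix plus the terminal R2 suffix
  est2 <- estimate_length(NA_character_, strrep("A", 40), FALSE,
                          r2_partial = paste0(strrep("A", 70), "TT"),
                          window = 80)
  expect_true(est2$censored)
  expect_equal(est2$total_len, 80L)
  expect_equal(est2$tail_class, "AU")
  expect_equal(est2$u_len, 2L)
  expect_equal(est2$a_len, 78L)
  # agreeing complete views
  est3 <- estimate_length(strrep("A", 40), strrep("A", 40), TRUE, window = 80)
  expect_equal(est3$total_len, 40L)
  # no evidence at all
  expect_equal(estimate_length(NA_character_, NA_character_, FALSE)$fate,
               "no_tail_evidence")
})

test_that("reported lengths never decrease when the window grows", {
  refs <- test_refs()
  p <- test_params(a_len_dist = list(dist = "uniform", min = 60, max = 110),
                   copy_dist = list(dist = "constant", value = 1))
  set.seed(12)
  mols <- simulate_molecules(300, p, refs)
  reads <- render_reads(mols, p, refs, sample = "wt")
  parsed <- parse_read_pairs(reads, one_sample_sheet())
  small <- call_tails(parsed, refs, window = 70)
  large <- call_tails(parsed, refs, window = 90)
  ok <- small$fate == "ok" & large$fate == "ok"
  expect_true(all(large$total_len[ok] >= small$total_len[ok]))
})

test_that("error-free reads recover class and lengths exactly end to end", {
  refs <- test_refs()
  p <- test_params(a_len_dist = list(dist = "uniform", min = 1, max = 74),
                   u_len_dist = list(dist = "uniform", min = 1, max = 5))
  set.seed(13)
  chain <- run_chain(1500, p, refs)
  expect_true(all(chain$calls$fate == "ok"))
  cmp <- truth_join(chain)
  expect_equal(nrow(cmp), 1500L)
  expect_true(all(cmp$true_class == cmp$tail_class))
  expect_true(all(cmp$a_len.true == cmp$a_len.called))
  expect_true(all(cmp$u_len.true == cmp$u_len.called))
  expect_true(all(!cmp$censored))
})

test_that("reads are routed to their generating amplicon", {
  refs <- test_refs()
  p <- test_params(copy_dist = list(dist = "constant", value = 1))
  set.seed(14)
  mols <- simulate_molecules(300, p, refs)
  reads <- render_reads(mols, p, refs, sample = "wt")
  parsed <- parse_read_pairs(reads, one_sample_sheet())
  calls <- call_tails(parsed, refs)
  by_id <- mols$reference[match(sub(".*:(mol\\d+):.*", "\\1", calls$read_id),
                                mols$molecule_id)]
  expect_equal(calls$reference, by_id)
})
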