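test_that("demultiplexing assigns by nearest index with tie protection", {
  sheet <- tibble::tibble(sample = c("wt", "ko"),
                          index = c("ACGTCA", "TGCAGT"))
  expect_equal(demultiplex("ACGTCA", sheet), "wt")
  expect_equal(demultiplex("ACGTCC", sheet, max_index_mismatch = 1), "wt")
  expect_equal(demultiplex("ACGTCC", sheet, max_index_mismatch = 0),
               "undetermined")
  # equidistant from both indices -> undetermined
  half <- "ACGAGT"  # 3 mismatches to each
  d1 <- sum(strsplit(half, "")[[1]] != strsplit("ACGTCA", "")[[1]])
  d2 <- sum(strsplit(half, "")[[1]] != strsplit("TGCAGT", "")[[1]])
  expect_equal(d1, d2)
  expect_equal(demultiplex(half, sheet), "undetermined")

  dup <- tibble::tibble(sample = c("a", "b"), index = c("ACGTCA", "ACGTCA"))
  expect_error(demultiplex("ACGTCA", dup), "duplicate")
  close_idx <- tibble::tibble(sample = c("a", "b"),
                              index = c("ACGTCA", "ACGTCG"))
  expect_error(demultiplex("ACGTCA", close_idx), "Hamming")
})

test_that("R2 parsing extracts UMI, delimiter and terminal base", {
  layout <- read_layout()
  umi <- strrep("G", 15)
  r2 <- paste0(umi, "CTAG", "AATTTGGG")
  p <- parse_r2(r2, layout)
  expect_equal(p$fate, "ok")
  expect_equal(p$umi, umi)
  expect_equal(p$payload, "AATTTGGG")
  expect_equal(p$r2_terminal_base, "A")

  # one substitution in the delimiter is tolerated at the default
  r2_sub <- paste0(umi, "CTTG", "AATTT")
  expect_equal(parse_r2(r2_sub, layout)$fate, "ok")
  expect_equal(parse_r2(r2_sub, read_layout(max_delim_mismatch = 0))$fate,
               "no_delimiter")

  expect_equal(parse_r2(paste0(umi, "GA"), layout)$fate, "too_short")
  expect_equal(parse_r2(paste0(umi, "GGGG", "AAAA"), layout)$fate,
               "no_delimiter")
})

test_that("orientation reverse-complements the payload and preserves Ns", {
  expect_equal(orient("AATTTG"), "CAAATT")
  expect_equal(orient("NNNN"), "NNNN")
  expect_equal(orient(orient("ACGTN")), "ACGTN")
})

test_that("every read pair gets exactly one fate and counts are conserved", {
  refs <- test_refs()
  p <- test_params()
  set.seed(5)
  mols <- simulate_molecules(400, p, refs)
  reads <- render_reads(mols, p, refs, sample = "wt")
  # corrupt some reads: unknown index, truncated R2, broken delimiter
  reads$comment_r1[1:5] <- "1:N:0:TTTTTT"
  reads$r2[6:10] <- substr(reads$r2[6:10], 1, 10)
  substr(reads$r2[11:15], 16, 19) <- "GGGG"
  parsed <- parse_read_pairs(reads, one_sample_sheet())
  expect_equal(nrow(parsed), nrow(reads))
  fates <- dplyr::count(parsed, fate)
  expect_setequal(fates$fate,
                  c("ok", "undetermined_index", "too_short", "no_delimiter"))
  expect_equal(sum(fates$n), nrow(reads))
  expect_equal(fates$n[fates$fate == "undetermined_index"], 5L)
  expect_equal(fates$n[fates$fate == "too_short"], 5L)
  expect_equal(fates$n[fates$fate == "no_delimiter"], 5L)
  report <- demux_report(parsed)
  expect_equal(sum(report$reads), nrow(reads))
})

test_that("error-free simulated reads all parse to the generating sample", {
  refs <- test_refs()
  p <- test_params()
  set.seed(6)
  mols <- simulate_molecules(500, p, refs)
  reads <- render_reads(mols, p, refs, sample = "wt")
  parsed <- parse_read_pairs(reads, one_sample_sheet())
  expect_true(all(parsed$fate == "ok"))
  expect_true(all(parsed$sample == "wt"))
  expect_true(all(nchar(parsed$umi) == 15L))
  # the sense-oriented tail-facing segment ends at the 3' terminus
  m1 <- mols[mols$molecule_id == sub(".*:(mol\\d+):.*", "\\1",
                                     parsed$read_id[1]), ]
  tf <- parsed$tail_facing[1]
  expected_tail <- paste0(strrep("A", m1$a_len), strrep("T", m1$u_len))
  if (nchar(expected_tail)) {
    expect_equal(substr(tf, nchar(tf) - nchar(expected_tail) + 1, nchar(tf)),
                 expected_tail)
  }
})

test_that("in-line R1 index demultiplexing is supported via the layout", {
  refs <- test_refs()
  p <- test_params()
  set.seed(8)
  mols <- simulate_molecules(50, p, refs)
  reads <- render_reads(mols, p, refs, sample = "wt")
  reads$r1 <- paste0(p$index, reads$r1)
  layout <- read_layout(index_source = "r1_prefix")
  parsed <- parse_read_pairs(reads, one_sample_sheet(), layout)
  expect_true(all(parsed$fate == "ok"))
  expect_true(all(parsed$sample == "wt"))
  # the index prefix is stripped from the template-facing segment
  expect_false(any(startsWith(parsed$template_facing, p$index)))
})
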