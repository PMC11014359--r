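# Shared fixtures: the synthetic example amplicons shipped with the
# package, spanning read lengths (R1 160 / R2 120 keeps tails up to the
# 0-80 window fully observable), and a one-sample sheet.

test_refs <- function(include_l1 = FALSE) {
  refs <- read_amplicons(
    system.file("extdata/synthetic_amplicons.fa", package = "tailrace"),
    system.file("extdata/amplicon_config.yaml", package = "tailrace"))
  if (include_l1) refs else refs[refs$name != "L1_3end", ]
}

test_diagnostics <- function(refs = test_refs(include_l1 = TRUE)) {
  read_diagnostics(
    system.file("extdata/synthetic_l1_diagnostics.tsv", package = "tailrace"),
    refs)
}

test_params <- function(...) {
  library_params(error_rate = 0, read_len_r1 = 160L, read_len_r2 = 120L, ...)
}

one_sample_sheet <- function(index = "ACGTCA", sample = "wt") {
  tibble::tibble(sample = sample, index = index)
}

# simulate -> parse -> call -> dedup in one go
run_chain <- function(n, params, refs, sample = "wt", window = 80L,
                      dedup_mode = "exact") {
  mols <- simulate_molecules(n, params, refs)
  reads <- render_reads(mols, params, refs, sample = sample)
  parsed <- parse_read_pairs(reads, one_sample_sheet(params$index, sample))
  calls <- call_tails(parsed, refs, window = window,
                      adapter = revcomp(params$delimiter))
  list(mols = mols, reads = reads, parsed = parsed, calls = calls,
       dedup = dedup_calls(calls, mode = dedup_mode))
}

# join dedup output back to ground truth by UMI
truth_join <- function(chain) {
  dplyr::inner_join(chain$mols, chain$dedup, by = "umi",
                    suffix = c(".true", ".called"))
}
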