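#' Library-preparation and sequencing parameters for the simulator
#'
#' Bundles the knobs of the simulated 3' RACE-seq chemistry: the mixture
#' of non-templated 3'-end classes, tail-length distributions, PCR copy
#' distribution, per-base substitution error rate, the adapter layout
#' (15-nt UMI, delimiter, 6-nt sample index) and read lengths. Defaults
#' emulate a wild-type-like library: mostly poly(A) tails with ~17%
#' uridylated molecules (AU + U) and ~6% tailless, A-tails from a
#' zero-truncated negative binomial with mean 45, U-stretches averaging
#' 2 nt, and modest PCR duplication.
#'
#' @param class_probs named probability vector over the four tail classes
#'   `A`, `AU`, `U`, `NONE`; must sum to 1.
#' @param a_len_dist,u_len_dist tail-length distributions, each a list
#'   with a `dist` element: `"nbinom"` (`mu`, `size`; zero-truncated),
#'   `"geometric"` (`mean`; support >= 1), `"uniform"` (`min`, `max`) or
#'   `"constant"` (`value`).
#' @param copy_dist PCR copy-number distribution over positive integers:
#'   `"shifted_poisson"` (`lambda`; 1 + Poisson), `"geometric"` (`mean`)
#'   or `"constant"` (`value`).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param read_len_r1,read_len_r2 read lengths; the default 100/100 gives
#'   an 81-nt R2 payload after the 15-nt UMI and 4-nt delimiter, matching
#'   a 0-80 observable tail window.
#' @param umi_len UMI length (15 in the assayed chemistry).
#' @param index 6-nt sample index.
#' @param delimiter fixed sequence separating the UMI from the payload in
#'   R2. The default is a declared placeholder; set it to the adapter
#'   actually used.
#' @param adapter_tail fixed adapter sequence sequenced in R1 after the
#'   reverse-complemented delimiter and UMI.
#' @return a list of class `library_params`.
#' @export
library_params <- function(class_probs = c(A = 0.77, AU = 0.15, U = 0.02,
                                           NONE = 0.06),
                           a_len_dist = list(dist = "nbinom", mu = 45, size = 5),
                           u_len_dist = list(dist = "geometric", mean = 2),
                           copy_dist = list(dist = "shifted_poisson", lambda = 2),
                           error_rate = 0.001,
                           read_len_r1 = 100L, read_len_r2 = 100L,
                           umi_len = 15L, index = "ACGTCA",
                           delimiter = "CTAG",
                           adapter_tail = "AGATCGGAAGAGCACACGTCTG") {
  if (!setequal(names(class_probs), c("A", "AU", "U", "NONE"))) {
    abort("class_probs must be named over {A, AU, U, NONE}")
  }
  class_probs <- class_probs[c("A", "AU", "U", "NONE")]
  if (abs(sum(class_probs) - 1) > 1e-9 || any(class_probs < 0)) {
    abort("class_probs must be a probability vector summing to 1")
  }
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  if (nchar(index) != 6L || !dna_alphabet_ok(index)) {
    abort("index must be a 6-nt DNA string")
  }
  for (d in list(a_len_dist, u_len_dist, copy_dist)) check_dist(d)
  structure(list(
    class_probs = class_probs, a_len_dist = a_len_dist,
    u_len_dist = u_len_dist, copy_dist = copy_dist,
    error_rate = error_rate,
    read_len_r1 = as.integer(read_len_r1),
    read_len_r2 = as.integer(read_len_r2),
    umi_len = as.integer(umi_len), index = index,
    delimiter = delimiter, adapter_tail = adapter_tail
  ), class = "library_params")
}

check_dist <- function(d) {
  known <- c("nbinom", "geometric", "uniform", "constant", "shifted_poisson")
  if (is.null(d$dist) || !d$dist %in% known) {
    abort(sprintf("unknown distribution '%s'", d$dist %||% "<missing>"))
  }
  need <- switch(d$dist,
    nbinom = c("mu", "size"), geometric = "mean",
    uniform = c("min", "max"), constant = "value",
    shifted_poisson = "lambda")
  if (!all(need %in% names(d))) {
    abort(sprintf("distribution '%s' needs parameter(s): %s",
                  d$dist, paste(need, collapse = ", ")))
  }
  vals <- unlist(d[need])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort(sprintf("invalid parameters for distribution '%s'", d$dist))
  }
  invisible(TRUE)
}

# draw n integers >= 1 from a tail-length or copy-number distribution
draw_positive <- function(n, d) {
  x <- switch(d$dist,
    nbinom = rnbinom(n, mu = d$mu, size = d$size),
    geometric = 1L + rgeom(n, prob = 1 / d$mean),
    uniform = sample(seq.int(d$min, d$max), n, replace = TRUE),
    constant = rep(as.integer(d$value), n),
    shifted_poisson = 1L + rpois(n, d$lambda))
  # zero-truncate by redrawing (only the nbinom branch can produce 0)
  while (any(x < 1L)) {
    k <- which(x < 1L)
    x[k] <- rnbinom(length(k), mu = d$mu, size = d$size)
  }
  as.integer(x)
}

#' Simulate ground-truth molecules
#'
#' Draws `n` RNA 3'-end molecules: a reference amplicon, a tail class
#' from `class_probs`, A- and U-stretch lengths from the configured
#' distributions, a PCR copy count, and a uniformly random UMI. The
#' returned tibble is the ground-truth table every downstream stage is
#' tested against.
#'
#' @param n number of molecules (>= 1).
#' @param params a [library_params()] object.
#' @param refs amplicon tibble from [read_amplicons()].
#' @param ref_weights optional sampling weights over `refs$name`.
#' @return tibble with one row per molecule: `molecule_id`, `reference`,
#'   `subfamily`, `templated_end`, `a_len`, `u_len`, `true_class`,
#'   `pcr_copies`, `umi`.
#' @export
simulate_molecules <- function(n, params, refs, ref_weights = NULL) {
  stopifnot(inherits(params, "library_params"))
  if (n < 1L) abort("n must be >= 1")
  if (nrow(refs) == 0L) abort("refs must contain at least one amplicon")
  ridx <- sample.int(nrow(refs), n, replace = TRUE, prob = ref_weights)
  cls <- sample(c("A", "AU", "U", "NONE"), n, replace = TRUE,
                prob = params$class_probs)
  a_len <- integer(n)
  u_len <- integer(n)
  has_a <- cls %in% c("A", "AU")
  has_u <- cls %in% c("AU", "U")
  a_len[has_a] <- draw_positive(sum(has_a), params$a_len_dist)
  u_len[has_u] <- draw_positive(sum(has_u), params$u_len_dist)
  tibble(
    molecule_id = sprintf("mol%07d", seq_len(n)),
    reference = refs$name[ridx],
    subfamily = refs$subfamily[ridx],
    templated_end = refs$length[ridx] - 1L,
    a_len = a_len, u_len = u_len, true_class = cls,
    pcr_copies = draw_positive(n, params$copy_dist),
    umi = distinct_umis(n, params$umi_len)
  )
}

# uniform random UMIs, redrawn to be pairwise distinct: at library scale
# the 4^15 space makes true collisions negligible, and distinct tags are
# what the UMI is for — one tag, one molecule
distinct_umis <- function(n, width) {
  umi <- random_dna(n, width)
  while (anyDuplicated(umi)) {
    dup <- which(duplicated(umi))
    umi[dup] <- random_dna(length(dup), width)
  }
  umi
}

# i.i.d. substitution errors at `rate` per base
add_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    seqs[i] <- paste0(ch, collapse = "")
  }
  seqs
}

#' Render paired sequencing reads from simulated molecules
#'
#' Emits `pcr_copies` read pairs per molecule following the library
#' layout: R1 is the sense strand from the nested forward-primer site
#' through the templated region, the poly(A)/U tail (U written as T) and
#' into the adapter; R2 starts with the 15-nt UMI, then the delimiter,
#' then the reverse complement of tail and templated region — so the
#' first sequenced base after the delimiter is the complement of the
#' molecule's 3'-terminal nucleotide. Substitution errors are applied
#' i.i.d. at `error_rate`. Read names encode the molecule id (for
#' test-only traceability) and carry the sample index in the Illumina
#' header-comment position.
#'
#' @param molecules tibble from [simulate_molecules()].
#' @param params a [library_params()] object.
#' @param refs amplicon tibble from [read_amplicons()].
#' @param sample sample name used in read ids.
#' @return tibble with columns `read_id`, `comment_r1`, `comment_r2`,
#'   `r1`, `r2`, `molecule_id`.
#' @export
render_reads <- function(molecules, params, refs, sample = "sample1") {
  stopifnot(inherits(params, "library_params"))
  seqs <- setNames(refs$sequence, refs$name)
  offs <- setNames(refs$primer_offset, refs$name)
  templated <- substr(seqs[molecules$reference],
                      offs[molecules$reference] + 1L,
                      molecules$templated_end + 1L)
  tail_seq <- paste0(strrep("A", molecules$a_len), strrep("T", molecules$u_len))
  sense <- paste0(templated, tail_seq)
  r1_full <- paste0(sense, revcomp(params$delimiter), revcomp(molecules$umi),
                    params$adapter_tail)
  r2_full <- paste0(molecules$umi, params$delimiter, revcomp(sense))
  per_mol <- tibble(
    molecule_id = molecules$molecule_id,
    r1 = substr(r1_full, 1L, params$read_len_r1),
    r2 = substr(r2_full, 1L, params$read_len_r2),
    pcr_copies = molecules$pcr_copies
  )
  reads <- tidyr::uncount(per_mol, weights = .data$pcr_copies, .id = "copy")
  reads <- reads |>
    mutate(
      read_id = sprintf("%s:%s:cp%d", sample, .data$molecule_id, .data$copy),
      comment_r1 = sprintf("1:N:0:%s", params$index),
      comment_r2 = sprintf("2:N:0:%s", params$index),
      r1 = add_seq_errors(.data$r1, params$error_rate),
      r2 = add_seq_errors(.data$r2, params$error_rate)
    ) |>
    select("read_id", "comment_r1", "comment_r2", "r1", "r2", "molecule_id")
  reads
}

# write one FASTQ (constant Q40 qualities; gz when the path ends in .gz)
write_fastq <- function(seqs, ids, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate a complete sample library on disk
#'
#' Convenience wrapper: draws molecules, renders reads, and writes
#' `<sample>_R1.fastq.gz` / `<sample>_R2.fastq.gz`, a ground-truth TSV
#' and a JSON run manifest echoing the parameters.
#'
#' @param n number of molecules.
#' @param params a [library_params()] object.
#' @param refs amplicon tibble.
#' @param dir output directory (created if needed).
#' @param sample sample name.
#' @param seed optional integer seed for reproducibility.
#' @return invisibly, a list with `molecules`, `reads`, and the written
#'   file paths.
#' @export
simulate_sample <- function(n, params, refs, dir, sample = "sample1",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  molecules <- simulate_molecules(n, params, refs)
  reads <- render_reads(molecules, params, refs, sample = sample)
  r1_path <- file.path(dir, paste0(sample, "_R1.fastq.gz"))
  r2_path <- file.path(dir, paste0(sample, "_R2.fastq.gz"))
  write_fastq(reads$r1, paste(reads$read_id, reads$comment_r1), r1_path)
  write_fastq(reads$r2, paste(reads$read_id, reads$comment_r2), r2_path)
  truth_path <- file.path(dir, paste0(sample, "_truth.tsv"))
  readr::write_tsv(molecules, truth_path)
  manifest <- list(sample = sample, n_molecules = n,
                   n_read_pairs = nrow(reads), seed = seed,
                   params = unclass(params))
  manifest_path <- file.path(dir, paste0(sample, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(molecules = molecules, reads = reads,
                 r1 = r1_path, r2 = r2_path, truth = truth_path,
                 manifest = manifest_path))
}
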