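#' Read layout and parsing tolerances
#'
#' Describes the structural layout of a read pair: where the 6-nt sample
#' index lives, the R2 structure (`[UMI][delimiter][payload]`), and the
#' mismatch tolerances used while matching them.
#'
#' @param umi_len UMI length (default 15).
#' @param delimiter fixed sequence separating UMI from payload in R2.
#' @param index_len sample-index length (default 6).
#' @param max_index_mismatch maximum Hamming distance when demultiplexing.
#' @param max_delim_mismatch maximum substitutions tolerated in the
#'   delimiter match.
#' @param index_source `"header"` (Illumina `1:N:0:INDEX` comment) or
#'   `"r1_prefix"` (in-line index at the start of R1).
#' @param min_mean_q reads with mean Phred quality below this floor get
#'   the `low_q` flag (they still parse; summaries exclude them).
#' @return a list of class `read_layout`.
#' @export
read_layout <- function(umi_len = 15L, delimiter = "CTAG", index_len = 6L,
                        max_index_mismatch = 1L, max_delim_mismatch = 1L,
                        index_source = c("header", "r1_prefix"),
                        min_mean_q = 20) {
  index_source <- match.arg(index_source)
  stopifnot(umi_len >= 1L, nchar(delimiter) >= 1L, index_len >= 1L)
  structure(list(umi_len = as.integer(umi_len), delimiter = delimiter,
                 index_len = as.integer(index_len),
                 max_index_mismatch = as.integer(max_index_mismatch),
                 max_delim_mismatch = as.integer(max_delim_mismatch),
                 index_source = index_source, min_mean_q = min_mean_q),
            class = "read_layout")
}

#' Load a sample sheet
#'
#' @param path TSV with columns `sample` and `index` (6-nt DNA).
#' @return tibble with `sample`, `index`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), index = readr::col_character()))
  validate_sample_sheet(sheet)
  sheet
}

validate_sample_sheet <- function(sheet, max_index_mismatch = 1L) {
  if (anyDuplicated(sheet$index)) {
    abort("sample sheet contains duplicate indices")
  }
  if (anyDuplicated(sheet$sample)) {
    abort("sample sheet contains duplicate sample names")
  }
  if (nrow(sheet) > 1L) {
    d <- utils::combn(nrow(sheet), 2L)
    dist <- vapply(seq_len(ncol(d)), function(j) {
      hamming_to_cpp(sheet$index[d[1L, j]], sheet$index[d[2L, j]])
    }, integer(1))
    if (any(dist <= 2L * max_index_mismatch)) {
      abort(sprintf(
        "indices must differ at Hamming distance > %d for unambiguous demultiplexing",
        2L * max_index_mismatch))
    }
  }
  invisible(sheet)
}

#' Read a pair of FASTQ files into a tibble
#'
#' @param r1_path,r2_path FASTQ paths (optionally gzipped); records must
#'   be in the same order in both files.
#' @return tibble with `read_id`, `comment_r1`, `comment_r2`, `r1`, `r2`,
#'   `mean_q1`, `mean_q2`.
#' @export
read_paired_fastq <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(s1) != length(s2)) abort("R1 and R2 have different read counts")
  split_hdr <- function(x) {
    id <- sub("\\s.*$", "", names(x))
    comment <- ifelse(grepl("\\s", names(x)), sub("^\\S+\\s+", "", names(x)), "")
    list(id = id, comment = comment)
  }
  h1 <- split_hdr(s1)
  h2 <- split_hdr(s2)
  if (!identical(h1$id, h2$id)) abort("R1/R2 read ids do not pair up")
  q1 <- as.character(S4Vectors::mcols(s1)[["qualities"]])
  q2 <- as.character(S4Vectors::mcols(s2)[["qualities"]])
  tibble(read_id = unname(h1$id), comment_r1 = unname(h1$comment),
         comment_r2 = unname(h2$comment),
         r1 = unname(as.character(s1)), r2 = unname(as.character(s2)),
         mean_q1 = mean_phred(q1), mean_q2 = mean_phred(q2))
}

#' Demultiplex observed indices against a sample sheet
#'
#' Assigns each observed index to the unique nearest sheet index within
#' `max_index_mismatch` substitutions; anything else (including a tie) is
#' `"undetermined"`.
#'
#' @param observed character vector of observed index sequences.
#' @param sheet sample-sheet tibble (`sample`, `index`).
#' @param max_index_mismatch maximum Hamming distance.
#' @return character vector of sample labels or `"undetermined"`.
#' @export
demultiplex <- function(observed, sheet, max_index_mismatch = 1L) {
  validate_sample_sheet(sheet, max_index_mismatch)
  if (length(observed) == 0L) return(character(0))
  dmat <- vapply(sheet$index, function(ix) hamming_to_cpp(observed, ix),
                 integer(length(observed)))
  dmat <- matrix(dmat, nrow = length(observed))
  dmat[is.na(dmat)] <- .Machine$integer.max
  best <- apply(dmat, 1L, min)
  n_best <- rowSums(dmat == best)
  ok <- best <= max_index_mismatch & n_best == 1L
  out <- rep("undetermined", length(observed))
  out[ok] <- sheet$sample[apply(dmat[ok, , drop = FALSE], 1L, which.min)]
  out
}

#' Parse R2 reads into UMI, payload and terminal base
#'
#' R2 is laid out as `[UMI][delimiter][payload]`; the first payload base
#' is the sequenced complement of the molecule's 3'-terminal nucleotide.
#'
#' @param r2 character vector of R2 sequences.
#' @param layout a [read_layout()].
#' @return tibble with `umi`, `payload`, `r2_terminal_base` and `fate`
#'   (`"ok"`, `"too_short"` or `"no_delimiter"`); failed rows have NA
#'   fields.
#' @export
parse_r2 <- function(r2, layout = read_layout()) {
  ulen <- layout$umi_len
  dlen <- nchar(layout$delimiter)
  min_len <- ulen + dlen + 1L
  n <- length(r2)
  fate <- rep("ok", n)
  fate[nchar(r2) < min_len] <- "too_short"
  delim_obs <- substr(r2, ulen + 1L, ulen + dlen)
  dmm <- hamming_to_cpp(delim_obs, layout$delimiter)
  fate[fate == "ok" & (is.na(dmm) | dmm > layout$max_delim_mismatch)] <-
    "no_delimiter"
  ok <- fate == "ok"
  umi <- ifelse(ok, substr(r2, 1L, ulen), NA_character_)
  payload <- ifelse(ok, substr(r2, ulen + dlen + 1L, nchar(r2)), NA_character_)
  tibble(umi = umi, payload = payload,
         r2_terminal_base = ifelse(ok, substr(payload, 1L, 1L), NA_character_),
         fate = fate)
}

#' Orient a parsed R2 payload to the sense strand
#'
#' The R2 payload reads from inside the adapter toward the template, so
#' its reverse complement is the sense-strand segment that ends at the
#' molecule's 3' terminus.
#'
#' @param payload character vector of R2 payloads.
#' @return character vector `tail_facing` (sense 5' to 3').
#' @export
orient <- function(payload) {
  revcomp(payload)
}

#' Demultiplex and parse a table of read pairs
#'
#' Runs index demultiplexing, R2 structural parsing and sense
#' orientation over a read-pair tibble (from [read_paired_fastq()] or
#' [render_reads()]). Every input pair receives exactly one fate, so
#' fates sum to the input count.
#'
#' @param reads tibble with `read_id`, `r1`, `r2` and (for header-based
#'   demultiplexing) `comment_r1`; optional `mean_q1`/`mean_q2`.
#' @param sheet sample-sheet tibble.
#' @param layout a [read_layout()].
#' @return tibble with one row per input pair: `read_id`, `sample`,
#'   `fate`, `umi`, `tail_facing`, `template_facing`,
#'   `r2_terminal_base`, `qc_flags`.
#' @export
parse_read_pairs <- function(reads, sheet, layout = read_layout()) {
  n <- nrow(reads)
  if (layout$index_source == "header") {
    if (!"comment_r1" %in% names(reads)) {
      abort("header demultiplexing needs a comment_r1 column")
    }
    observed <- stringr::str_match(reads$comment_r1,
                                   "^\\d:[NY]:\\d+:([ACGTN]+)")[, 2L]
    template_facing <- reads$r1
  } else {
    observed <- substr(reads$r1, 1L, layout$index_len)
    template_facing <- substr(reads$r1, layout$index_len + 1L,
                              nchar(reads$r1))
  }
  sample <- demultiplex(observed, sheet, layout$max_index_mismatch)
  p2 <- parse_r2(reads$r2, layout)
  fate <- ifelse(sample == "undetermined", "undetermined_index", p2$fate)
  ok <- fate == "ok"
  qc <- rep("", n)
  if (all(c("mean_q1", "mean_q2") %in% names(reads))) {
    lowq <- !is.na(reads$mean_q1) & !is.na(reads$mean_q2) &
      pmin(reads$mean_q1, reads$mean_q2) < layout$min_mean_q
    qc[lowq] <- "low_q"
  }
  tibble(
    read_id = as.character(reads$read_id),
    sample = as.character(ifelse(ok, sample, NA_character_)),
    fate = as.character(fate),
    umi = as.character(ifelse(ok, p2$umi, NA_character_)),
    tail_facing = as.character(ifelse(ok, orient(p2$payload), NA_character_)),
    template_facing = as.character(ifelse(ok, template_facing, NA_character_)),
    r2_terminal_base = as.character(ifelse(ok, p2$r2_terminal_base,
                                           NA_character_)),
    qc_flags = as.character(qc)
  )
}

#' Demultiplexing report
#'
#' @param parsed output of [parse_read_pairs()].
#' @return tibble of read counts by sample and fate; counts sum to the
#'   number of input pairs.
#' @export
demux_report <- function(parsed) {
  parsed |>
    mutate(sample = ifelse(is.na(.data$sample), "-", .data$sample)) |>
    count(.data$sample, .data$fate, name = "reads") |>
    arrange(desc(.data$reads))
}
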