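#' Load reference amplicon 3'-end sequences
#'
#' Reads a FASTA of targeted amplicon 3'-end sequences (sense strand, 5'
#' to 3', ending at the annotated templated 3' terminus) together with a
#' sidecar configuration giving, per record, the 0-based offset of the
#' nested forward-primer site and optional subfamily label and notes.
#'
#' @param fasta path to a FASTA file (optionally gzipped).
#' @param config either a path to a YAML file or a named list; one entry
#'   per FASTA record, each a list with elements `primer_offset`
#'   (integer >= 0, default 0), `subfamily` (optional label) and `notes`.
#' @return a tibble with columns `name`, `sequence`, `length`,
#'   `primer_offset`, `subfamily`, `notes`; one row per amplicon.
#' @export
read_amplicons <- function(fasta, config) {
  # read as raw strings first: the DNA parser silently drops invalid
  # codes, and the contract is to reject them naming the record
  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) == 0L) {
    warn(sprintf("FASTA '%s' contains no records", fasta))
    return(tibble(name = character(), sequence = character(),
                  length = integer(), primer_offset = integer(),
                  subfamily = character(), notes = character()))
  }
  # first whitespace-delimited token is the record name
  nms <- sub("\\s.*$", "", names(seqs))
  sequences <- toupper(as.character(seqs))
  names(sequences) <- NULL
  bad <- !dna_alphabet_ok(sequences)
  if (any(bad)) {
    abort(sprintf(
      "record '%s' contains characters outside A/C/G/T/N", nms[which(bad)[1]]
    ))
  }
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    config <- config[["amplicons"]] %||% config
  }
  missing_cfg <- setdiff(nms, names(config))
  if (length(missing_cfg) > 0L) {
    abort(sprintf("no configuration entry for record(s): %s",
                  paste(missing_cfg, collapse = ", ")))
  }
  missing_rec <- setdiff(names(config), nms)
  if (length(missing_rec) > 0L) {
    abort(sprintf("configuration names record(s) absent from FASTA: %s",
                  paste(missing_rec, collapse = ", ")))
  }
  amp <- tibble(
    name = nms,
    sequence = sequences,
    length = nchar(sequences),
    primer_offset = unname(vapply(config[nms], function(e)
      as.integer(e[["primer_offset"]] %||% 0L), integer(1))),
    subfamily = unname(vapply(config[nms], function(e)
      as.character(e[["subfamily"]] %||% NA_character_), character(1))),
    notes = unname(vapply(config[nms], function(e)
      as.character(e[["notes"]] %||% ""), character(1)))
  )
  if (any(amp$primer_offset < 0L | amp$primer_offset >= amp$length)) {
    abort("primer_offset must satisfy 0 <= primer_offset < length(sequence)")
  }
  amp
}

#' Load a subfamily diagnostic-nucleotide table
#'
#' The table lists, for one or more reference amplicons, the positions
#' whose base distinguishes LINE-1 subfamilies (e.g. L1-HS from the older
#' L1-PA classes), and the base each subfamily is expected to carry
#' there. Positions are 1-based in the file and converted to 0-based
#' internally.
#'
#' @param path TSV with columns `reference`, `position` (1-based),
#'   `subfamily`, `base`.
#' @param amplicons amplicon tibble from [read_amplicons()]; used to
#'   validate positions.
#' @return tibble with columns `reference`, `pos0`, `subfamily`, `base`.
#' @export
read_diagnostics <- function(path, amplicons = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    reference = readr::col_character(), position = readr::col_integer(),
    subfamily = readr::col_character(), base = readr::col_character()
  ))
  if (!all(tab$base %in% c("A", "C", "G", "T"))) {
    abort("diagnostic bases must be A/C/G/T")
  }
  tab <- tab |> mutate(pos0 = .data$position - 1L) |>
    select("reference", "pos0", "subfamily", "base")
  # every subfamily must have a base at every diagnostic position
  grid <- tab |> count(.data$reference, .data$pos0) |> pull(n)
  n_sub <- length(unique(tab$subfamily))
  if (any(grid != n_sub)) {
    abort("every subfamily needs a base at every diagnostic position")
  }
  if (!is.null(amplicons)) {
    chk <- tab |> left_join(amplicons |> select("name", "length"),
                            by = c(reference = "name"))
    if (any(is.na(chk$length)) || any(chk$pos0 < 0L | chk$pos0 >= chk$length)) {
      abort("diagnostic positions must index into a loaded reference amplicon")
    }
  }
  tab
}

#' Assign an L1 subfamily to a templated read segment
#'
#' Compares the segment's bases at the diagnostic positions it covers
#' with each subfamily's expected bases. The unique subfamily matching at
#' every covered position wins; more than one match (for example when the
#' segment covers no discriminating position) gives `"ambiguous"`, as
#' does a segment matching no subfamily (with a mismatch flag); a segment
#' covering zero diagnostic positions gives `"uninformative"`. Ns in the
#' segment carry no information.
#'
#' @param segment DNA string aligned to the reference.
#' @param alignment_start 0-based reference offset of the segment start.
#' @param diagnostics diagnostic tibble from [read_diagnostics()].
#' @param reference name of the reference amplicon the segment maps to.
#' @return single character label: a subfamily name, `"ambiguous"` or
#'   `"uninformative"`; attribute `mismatch` is TRUE when no subfamily
#'   matched a covered position.
#' @export
assign_subfamily <- function(segment, alignment_start, diagnostics,
                             reference = diagnostics$reference[1]) {
  stopifnot(length(segment) == 1L, alignment_start >= 0L)
  d <- diagnostics |> filter(.data$reference == !!reference)
  len <- nchar(segment)
  covered <- d |>
    filter(.data$pos0 >= alignment_start, .data$pos0 < alignment_start + len)
  if (nrow(covered) == 0L) {
    return(structure("uninformative", mismatch = FALSE))
  }
  obs <- substring(segment, covered$pos0 - alignment_start + 1L,
                   covered$pos0 - alignment_start + 1L)
  informative <- obs %in% c("A", "C", "G", "T")
  covered <- covered[informative, , drop = FALSE]
  obs <- obs[informative]
  if (nrow(covered) == 0L) {
    return(structure("uninformative", mismatch = FALSE))
  }
  match_by_sub <- covered |> mutate(obs = obs) |>
    group_by(.data$subfamily) |>
    summarise(all_match = all(.data$base == .data$obs), .groups = "drop")
  winners <- match_by_sub$subfamily[match_by_sub$all_match]
  if (length(winners) == 1L) {
    structure(winners, mismatch = FALSE)
  } else if (length(winners) > 1L) {
    structure("ambiguous", mismatch = FALSE)
  } else {
    structure("ambiguous", mismatch = TRUE)
  }
}

#' Add subfamily labels to a table of tail calls
#'
#' Applies [assign_subfamily()] to each row's templated segment
#' (`template_facing`, anchored at the reference's `primer_offset`).
#'
#' @param calls tibble of tail calls carrying `reference` and
#'   `template_facing` columns.
#' @param diagnostics tibble from [read_diagnostics()].
#' @param amplicons amplicon tibble (for `primer_offset`).
#' @return `calls` with `subfamily` and `subfamily_mismatch` columns
#'   replaced by the diagnostic assignment.
#' @export
assign_subfamilies <- function(calls, diagnostics, amplicons) {
  offs <- setNames(amplicons$primer_offset, amplicons$name)
  res <- purrr::map2(calls$template_facing, calls$reference, function(seg, ref) {
    if (is.na(seg) || is.na(ref) || !ref %in% diagnostics$reference) {
      return(structure(NA_character_, mismatch = FALSE))
    }
    assign_subfamily(seg, offs[[ref]], diagnostics, ref)
  })
  calls$subfamily <- vapply(res, as.character, character(1))
  calls$subfamily_mismatch <- vapply(res, function(x)
    isTRUE(attr(x, "mismatch")), logical(1))
  calls
}
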