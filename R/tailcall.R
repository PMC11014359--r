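#' Classify a non-templated addition into the four tail classes
#'
#' The 3' RACE-seq classes are: `A` (only adenosines), `AU` (an
#' adenosine run appended with one or more uridines), `U` (only
#' uridines), `NONE` (no non-templated bases). Anything else is `OTHER`,
#' which is reported separately and excluded from four-class fractions.
#' U and T are treated as equivalent; the 3' terminus is the last
#' character.
#'
#' With `tolerance > 0`, up to `tolerance` isolated non-conforming bases
#' (a single base whose two neighbours agree with each other) inside a
#' tail of length >= 10 are corrected to the local run's base before
#' pattern matching — a light error-tolerant mode for real reads.
#'
#' @param nta character vector of sense-oriented NTA sequences (may
#'   contain empty strings).
#' @param tolerance number of isolated substitutions to forgive
#'   (default 0, strict).
#' @return tibble with `tail_class`, `a_len`, `u_len`, one row per
#'   input.
#' @export
#' @examples
#' classify_tail(c("", "AAAAAAA", "AAATT", "TT", "AAGAA"))
classify_tail <- function(nta, tolerance = 0L) {
  x <- chartr("Uu", "Tt", toupper(nta))
  if (any(stringr::str_detect(x[!is.na(x)], "[^ACGTN]"))) {
    abort("NTA sequences may only contain A/C/G/T/U/N")
  }
  cls <- dplyr::case_when(
    is.na(x) ~ NA_character_,
    x == "" ~ "NONE",
    stringr::str_detect(x, "^A+$") ~ "A",
    stringr::str_detect(x, "^A+T+$") ~ "AU",
    stringr::str_detect(x, "^T+$") ~ "U",
    TRUE ~ "OTHER"
  )
  if (tolerance > 0L) {
    idx <- which(cls == "OTHER" & nchar(x) >= 10L)
    for (i in idx) {
      ch <- strsplit(x[i], "", fixed = TRUE)[[1]]
      fixed <- 0L
      for (p in seq(2L, length(ch) - 1L)) {
        if (fixed >= tolerance) break
        if (ch[p - 1L] == ch[p + 1L] && ch[p] != ch[p - 1L] &&
            ch[p - 1L] %in% c("A", "T")) {
          ch[p] <- ch[p - 1L]
          fixed <- fixed + 1L
        }
      }
      y <- paste0(ch, collapse = "")
      cls[i] <- dplyr::case_when(
        stringr::str_detect(y, "^A+$") ~ "A",
        stringr::str_detect(y, "^A+T+$") ~ "AU",
        stringr::str_detect(y, "^T+$") ~ "U",
        TRUE ~ "OTHER")
      x[i] <- y
    }
  }
  u_len <- ifelse(cls %in% c("AU", "U"),
                  nchar(stringr::str_extract(x, "T+$")), 0L)
  u_len[is.na(u_len)] <- 0L
  a_len <- dplyr::case_when(
    cls == "A" ~ nchar(x),
    cls == "AU" ~ nchar(x) - u_len,
    TRUE ~ 0L)
  tibble(tail_class = cls, a_len = as.integer(a_len),
         u_len = as.integer(u_len))
}

#' Anchor the templated 3' end and extract the NTA
#'
#' Finds the boundary between templated sequence and non-templated
#' addition for one reference amplicon. The templated portion is the
#' maximal prefix-anchored alignment of the read segments to the
#' reference ending at (or, with `max_end_trim > 0`, just before) the
#' annotated 3' terminus; terminal reference-matching As are assigned to
#' the template (greedy templated extension, implemented by scanning for
#' the minimal NTA). Alignments are accepted when their mismatch rate is
#' at most `max_mismatch_rate`.
#'
#' @param template_facing R1-derived sense segments starting at the
#'   forward-primer site.
#' @param tail_facing sense segments ending at the 3' terminus (reverse
#'   complement of the R2 payload).
#' @param ref one row of an amplicon tibble (or a list with `sequence`
#'   and `primer_offset`).
#' @param max_mismatch_rate maximum mismatch fraction over an aligned
#'   span.
#' @param min_anchor minimum aligned span (nt) to accept an anchor.
#' @param max_end_trim how far before the annotated terminus the
#'   templated end may stop (default 0: molecules end at the terminus).
#' @return tibble with `anchor` (0-based offset of the last templated
#'   base), `nta` (sense NTA from the tail-facing view; NA when the view
#'   never reaches template, i.e. the tail overruns it), and `fate`
#'   (`"ok"`, `"tail_overrun"`, `"unanchored"`, `"short_anchor"`).
#' @export
anchor_templated_end <- function(template_facing, tail_facing, ref,
                                 max_mismatch_rate = 0.05, min_anchor = 10L,
                                 max_end_trim = 0L) {
  amp_seq <- substr(ref$sequence, ref$primer_offset + 1L, nchar(ref$sequence))
  ref_rc <- revcomp(amp_seq)
  payload <- revcomp(tail_facing)
  sc <- boundary_scan_cpp(payload, ref_rc, max_mismatch_rate,
                          as.integer(min_anchor), as.integer(max_end_trim))
  pm <- prefix_mismatch_cpp(template_facing, amp_seq)
  r1_anchored <- !is.na(pm$span) & pm$span >= min_anchor &
    pm$mm <= floor(max_mismatch_rate * pm$span)
  len_tf <- nchar(tail_facing)
  t <- sc$nta_len
  nta <- ifelse(is.na(t), NA_character_,
                substr(tail_facing, len_tf - t + 1L, len_tf))
  anchor <- ifelse(is.na(t), NA_integer_,
                   nchar(ref$sequence) - 1L - sc$end_trim)
  fate <- dplyr::case_when(
    !is.na(t) ~ "ok",
    r1_anchored ~ "tail_overrun",
    !is.na(pm$span) & pm$span < min_anchor ~ "short_anchor",
    TRUE ~ "unanchored"
  )
  tibble(anchor = anchor, nta = nta, fate = fate)
}

#' Combine R1 and R2 views into one tail-length estimate
#'
#' R2 defines the 3'-terminal modification, so an R2 view that reaches
#' templated sequence gives the exact tail; otherwise an R1 view bounded
#' by the adapter gives the exact tail; otherwise the tail overruns both
#' views and is right-censored at the observable window (reported
#' downstream as the ">= window + 1" category). Censored calls are still
#' classified, from the concatenated partial views: the R1 view shows
#' the tail's 5' part and the R2 view its 3'-terminal part, which is
#' what determines uridylation.
#'
#' @param r2_view sense NTA from R2, or NA when R2 never reached
#'   template.
#' @param r1_view sense NTA prefix from R1 (possibly truncated), or NA.
#' @param r1_complete logical: the R1 view is bounded by the adapter.
#' @param r2_partial the tail suffix R2 did observe when it never
#'   reached template (the whole sense-oriented payload), or NA. Its
#'   last base is the 3'-terminal nucleotide, so it settles uridylation
#'   even for censored tails.
#' @param window observable tail window (nt), default 80.
#' @param tolerance passed to [classify_tail()].
#' @return tibble with `tail_class`, `a_len`, `u_len`, `total_len`,
#'   `censored`, `fate`.
#' @export
estimate_length <- function(r2_view, r1_view, r1_complete,
                            r2_partial = NA_character_,
                            window = 80L, tolerance = 0L) {
  use_r2 <- !is.na(r2_view)
  use_r1 <- !use_r2 & !is.na(r1_view) & r1_complete
  no_evidence <- is.na(r2_view) & is.na(r1_view) & is.na(r2_partial)
  # when the tail overruns both views, the class comes from the
  # 3'-terminal R2 evidence (which holds the complete terminal U run);
  # an adenosine-leading R1 prefix only tells us the tail starts in A,
  # encoded by prepending a single A so a terminal U run reads as AU
  nta <- dplyr::case_when(
    use_r2 ~ r2_view,
    use_r1 ~ r1_view,
    !is.na(r2_partial) & !is.na(r1_view) &
      stringr::str_starts(r1_view, "A") ~ paste0("A", r2_partial),
    !is.na(r2_partial) ~ r2_partial,
    TRUE ~ r1_view
  )
  cl <- classify_tail(ifelse(no_evidence, NA_character_, nta), tolerance)
  exact <- use_r2 | use_r1
  over <- exact & (cl$a_len + cl$u_len) > window
  censored <- (!exact & !no_evidence) | over
  out <- cl
  # censored tails occupy the full window; the terminal U count is exact
  # (it sits entirely inside the R2 view) so only the A run is clipped
  cens_au <- censored & out$tail_class == "AU"
  cens_a <- censored & out$tail_class == "A"
  cens_u <- censored & out$tail_class == "U"
  out$u_len[cens_au] <- pmin(out$u_len[cens_au], window - 1L)
  out$a_len[cens_au] <- window - out$u_len[cens_au]
  out$a_len[cens_a] <- window
  out$u_len[cens_u] <- window
  censored <- censored & out$tail_class %in% c("A", "AU", "U")
  out$total_len <- pmin(out$a_len + out$u_len, window)
  out$censored <- censored
  out$fate <- ifelse(no_evidence, "no_tail_evidence", "ok")
  out
}

#' Call tails on parsed read pairs
#'
#' For each parsed pair: assigns the best-matching reference amplicon by
#' positional comparison of the template-facing segment, anchors the
#' templated 3' end, extracts and classifies the NTA, and estimates its
#' length with right-censoring at `window`. Every input row keeps
#' exactly one fate, so fates sum to the input count.
#'
#' @param parsed tibble from [parse_read_pairs()].
#' @param refs amplicon tibble from [read_amplicons()].
#' @param window observable tail window (nt); default 80.
#' @param max_mismatch_rate anchor acceptance threshold.
#' @param min_anchor minimum anchored span (nt).
#' @param max_end_trim see [anchor_templated_end()].
#' @param tolerance see [classify_tail()].
#' @param adapter sequence expected in R1 immediately after the tail
#'   (the reverse complement of the delimiter for this chemistry).
#' @return tibble with one row per input pair: identification columns,
#'   `reference`, `subfamily`, `tail_class`, `a_len`, `u_len`,
#'   `total_len`, `censored`, `window`, `anchor`, `fate`, `qc_flags`,
#'   plus `template_facing` retained for subfamily diagnostics.
#' @export
call_tails <- function(parsed, refs, window = 80L, max_mismatch_rate = 0.05,
                       min_anchor = 10L, max_end_trim = 0L, tolerance = 0L,
                       adapter = revcomp("CTAG")) {
  n <- nrow(parsed)
  out <- parsed |>
    select("read_id", "sample", "umi", "fate", "qc_flags",
           "tail_facing", "template_facing", "r2_terminal_base")
  out$reference <- NA_character_
  out$subfamily <- NA_character_
  out$tail_class <- NA_character_
  out$a_len <- NA_integer_
  out$u_len <- NA_integer_
  out$total_len <- NA_integer_
  out$censored <- NA
  out$window <- as.integer(window)
  out$anchor <- NA_integer_
  ok <- which(out$fate == "ok")
  if (length(ok) == 0L) return(out |> select(-"tail_facing"))

  # reference assignment: best positional match of the template-facing
  # segment against each amplicon (from its primer site)
  amp_seqs <- substr(refs$sequence, refs$primer_offset + 1L,
                     nchar(refs$sequence))
  tf <- out$template_facing[ok]
  rate_mat <- matrix(NA_real_, nrow = length(ok), ncol = nrow(refs))
  span_mat <- matrix(NA_integer_, nrow = length(ok), ncol = nrow(refs))
  for (j in seq_len(nrow(refs))) {
    pm <- prefix_mismatch_cpp(tf, amp_seqs[j])
    rate_mat[, j] <- pm$mm / pmax(pm$span, 1L)
    span_mat[, j] <- pm$span
  }
  best_j <- max.col(-rate_mat, ties.method = "first")
  best_rate <- rate_mat[cbind(seq_along(ok), best_j)]
  best_span <- span_mat[cbind(seq_along(ok), best_j)]
  short <- best_span < min_anchor
  unanch <- !short & best_rate > max_mismatch_rate
  out$fate[ok[short]] <- "short_anchor"
  out$fate[ok[unanch]] <- "unanchored"
  anchored <- ok[!short & !unanch]
  ref_of <- refs$name[best_j][!short & !unanch]
  out$reference[anchored] <- ref_of

  for (rn in unique(ref_of)) {
    rows <- anchored[ref_of == rn]
    ref <- refs[refs$name == rn, ]
    amp_seq <- substr(ref$sequence, ref$primer_offset + 1L,
                      nchar(ref$sequence))
    ae <- anchor_templated_end(out$template_facing[rows],
                               out$tail_facing[rows], ref,
                               max_mismatch_rate, min_anchor, max_end_trim)
    # R1 view of the tail: bases after the templated span, bounded by
    # the adapter when it is found
    tl <- nchar(amp_seq)
    r1 <- out$template_facing[rows]
    rest <- ifelse(nchar(r1) > tl, substr(r1, tl + 1L, nchar(r1)), "")
    apos <- find_motif_cpp(rest, adapter, 1L, 0L,
                           min(4L, nchar(adapter)))
    r1_complete <- !is.na(apos)
    r1_view <- ifelse(r1_complete, substr(rest, 1L, apos - 1L), rest)
    # a read ending inside the adapter shows only a sub-overlap prefix
    # of it; strip that fragment so it cannot contaminate the tail view
    trimmed <- r1_complete
    for (k in rev(seq_len(min(nchar(adapter), 4L) - 1L))) {
      part <- !trimmed & nchar(r1_view) >= k &
        substr(r1_view, nchar(r1_view) - k + 1L, nchar(r1_view)) ==
          substr(adapter, 1L, k)
      part[is.na(part)] <- FALSE
      r1_view[part] <- substr(r1_view[part], 1L,
                              nchar(r1_view[part]) - k)
      trimmed <- trimmed | part
    }
    r1_view[!nzchar(rest) & !r1_complete] <- NA_character_
    r2_view <- ifelse(ae$fate == "ok", ae$nta, NA_character_)
    # composition evidence for overrun tails: retry the boundary with a
    # 1-nt anchor to shave any sub-anchor templated prefix off the
    # payload (not trusted for length, only for class)
    r2_partial <- rep(NA_character_, length(rows))
    fail <- ae$fate == "tail_overrun"
    if (any(fail)) {
      tfv <- out$tail_facing[rows][fail]
      sc2 <- boundary_scan_cpp(revcomp(tfv), revcomp(amp_seq),
                               max_mismatch_rate, 1L,
                               as.integer(max_end_trim))
      r2_partial[fail] <- ifelse(
        is.na(sc2$nta_len), tfv,
        substr(tfv, nchar(tfv) - sc2$nta_len + 1L, nchar(tfv)))
    }
    usable <- ae$fate %in% c("ok", "tail_overrun")
    est <- estimate_length(r2_view[usable],
                           r1_view[usable], r1_complete[usable],
                           r2_partial[usable],
                           window = window, tolerance = tolerance)
    urows <- rows[usable]
    out$tail_class[urows] <- est$tail_class
    out$a_len[urows] <- est$a_len
    out$u_len[urows] <- est$u_len
    out$total_len[urows] <- est$total_len
    out$censored[urows] <- est$censored
    out$anchor[urows] <- ae$anchor[usable]
    out$fate[urows] <- est$fate
    out$fate[rows[!usable]] <- ae$fate[!usable]
    # R1/R2 agreement check where both views are complete
    both <- usable & ae$fate == "ok" & r1_complete
    conflict <- both & !is.na(r1_view) & nchar(r1_view) != nchar(r2_view)
    if (any(conflict)) {
      cr <- rows[conflict]
      out$qc_flags[cr] <- ifelse(nzchar(out$qc_flags[cr]),
                                 paste0(out$qc_flags[cr], ",r1_r2_conflict"),
                                 "r1_r2_conflict")
    }
  }
  out |> select(-"tail_facing")
}
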