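#' Group tail calls by UMI
#'
#' Exact mode keys groups on the identical 15-nt UMI. Directional mode
#' additionally merges a UMI into another UMI at Hamming distance 1 that
#' is at least twice as abundant (counts compared as `n_parent >=
#' 2 * n_child - 1`, the standard directional rule), which absorbs
#' PCR/sequencing-error derivatives of an abundant UMI.
#'
#' @param calls tail-call tibble from [call_tails()]; must come from a
#'   single sample and a single reference amplicon.
#' @param mode `"exact"` (default; with a 15-nt UMI, collisions are
#'   negligible at library scale) or `"directional-1mm"`.
#' @return `calls` with a `umi_group` column naming each row's group
#'   representative UMI.
#' @export
group_umis <- function(calls, mode = c("exact", "directional-1mm")) {
  mode <- match.arg(mode)
  if (dplyr::n_distinct(calls$sample) > 1L) {
    abort("group_umis expects calls from a single sample")
  }
  if (dplyr::n_distinct(calls$reference, na.rm = TRUE) > 1L) {
    abort("group_umis expects calls from a single reference amplicon")
  }
  calls$umi_group <- calls$umi
  if (mode == "exact" || nrow(calls) == 0L) return(calls)

  counts <- calls |> count(.data$umi, name = "n_reads") |>
    arrange(desc(.data$n_reads), .data$umi)
  parent <- setNames(counts$umi, counts$umi)
  umis <- counts$umi
  width <- nchar(umis[1])
  # bucket UMIs by each position-masked key; pairs sharing a key are at
  # Hamming distance <= 1
  nvec <- setNames(counts$n_reads, counts$umi)
  for (p in seq_len(width)) {
    key <- paste0(substr(umis, 1L, p - 1L), ".", substr(umis, p + 1L, width))
    buckets <- split(umis, key)
    for (b in buckets) {
      if (length(b) < 2L) next
      b <- b[order(-nvec[b], b)]
      big <- b[1]
      for (small in b[-1]) {
        if (parent[small] != small || parent[big] == small) next
        if (nvec[big] >= 2L * nvec[small] - 1L) {
          parent[small] <- big
        }
      }
    }
  }
  # path-compress one level (chains beyond depth 2 are vanishingly rare)
  parent <- setNames(parent[parent], names(parent))
  calls$umi_group <- unname(parent[calls$umi])
  calls
}

#' Consensus tail call for one UMI group
#'
#' Class is decided by plurality; ties break toward the class of the
#' member with the longest uncensored evidence, then by lexicographic
#' class order (A < AU < NONE < OTHER < U) for determinism. Lengths are
#' the member medians within the winning class; the consensus is
#' censored only if every winning-class member is censored.
#'
#' @param group tibble of member calls sharing one UMI.
#' @return one-row tibble with the consensus call and `group_size`.
#' @export
consensus_call <- function(group) {
  stopifnot(nrow(group) >= 1L)
  tab <- group |> count(.data$tail_class, name = "votes")
  top <- tab |> filter(.data$votes == max(.data$votes)) |> pull(.data$tail_class)
  if (length(top) > 1L) {
    tied <- group |> filter(.data$tail_class %in% top)
    best_len <- tied |>
      mutate(evidence = ifelse(.data$censored, -1L, .data$total_len)) |>
      filter(.data$evidence == max(.data$evidence))
    top <- sort(unique(best_len$tail_class))[1]
  }
  win <- group |> filter(.data$tail_class == top)
  med_int <- function(x) if (nrow(win) == 0L) NA_real_ else median(x)
  tibble(
    sample = group$sample[1],
    umi = group$umi_group[1] %||% group$umi[1],
    reference = group$reference[1],
    subfamily = group$subfamily[1],
    tail_class = top,
    a_len = med_int(win$a_len),
    u_len = med_int(win$u_len),
    total_len = med_int(win$total_len),
    censored = all(win$censored),
    window = group$window[1],
    group_size = nrow(group)
  )
}

#' Collapse PCR duplicates by UMI
#'
#' Groups calls by (sample, reference, UMI) and reduces each group to a
#' single consensus call, so each original molecule contributes once.
#' Rows without a successful tail call (`fate != "ok"`) and low-quality
#' reads are dropped first.
#'
#' @param calls tail-call tibble from [call_tails()].
#' @param mode UMI grouping mode, see [group_umis()].
#' @return tibble of consensus calls with a `group_size` column.
#' @export
dedup_calls <- function(calls, mode = c("exact", "directional-1mm")) {
  mode <- match.arg(mode)
  usable <- calls |>
    filter(.data$fate == "ok",
           !stringr::str_detect(.data$qc_flags, "low_q"))
  if (nrow(usable) == 0L) {
    return(usable |>
             mutate(umi_group = character(0), group_size = integer(0)) |>
             select("sample", "umi", "reference", "subfamily", "tail_class",
                    "a_len", "u_len", "total_len", "censored", "window",
                    "group_size"))
  }
  if (mode == "exact") {
    usable$umi_group <- usable$umi
  } else {
    usable <- usable |>
      group_by(.data$sample, .data$reference) |>
      dplyr::group_split() |>
      purrr::map(group_umis, mode = mode) |>
      bind_rows()
  }
  # vectorised consensus, same rule as consensus_call(): plurality, ties
  # toward the longest uncensored evidence, then lexicographic class
  per_class <- usable |>
    group_by(.data$sample, .data$reference, .data$umi_group,
             .data$window, .data$tail_class) |>
    summarise(votes = n(), subfamily = dplyr::first(.data$subfamily),
              evidence = max(ifelse(.data$censored, -1L, .data$total_len)),
              a_len = median(.data$a_len), u_len = median(.data$u_len),
              total_len = median(.data$total_len),
              censored = all(.data$censored), .groups = "drop")
  sizes <- usable |>
    count(.data$sample, .data$reference, .data$umi_group, name = "group_size")
  per_class |>
    group_by(.data$sample, .data$reference, .data$umi_group) |>
    arrange(desc(.data$votes), desc(.data$evidence), .data$tail_class,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    left_join(sizes, by = c("sample", "reference", "umi_group")) |>
    rename(umi = "umi_group") |>
    select("sample", "umi", "reference", "subfamily", "tail_class",
           "a_len", "u_len", "total_len", "censored", "window", "group_size")
}
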