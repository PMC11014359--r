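TAIL_CLASSES <- c("A", "AU", "U", "NONE")

#' Per-sample tail-class counts and fractions
#'
#' Fractions are computed over the four tail classes (A, AU, U, NONE);
#' `OTHER` calls are counted but excluded from the denominator, matching
#' the four-class figure convention. The uridylated fraction is AU + U.
#'
#' @param calls deduplicated tail-call tibble.
#' @param stratum column to stratify by in addition to `sample`
#'   (`"reference"` or `"subfamily"`).
#' @return tibble with one row per (sample, stratum, class):
#'   `n`, `fraction` (NA for OTHER), `n_molecules` (four-class total),
#'   `uridylated` (AU + U fraction, repeated within the group).
#' @export
class_fractions <- function(calls, stratum = "reference") {
  grp <- c("sample", stratum)
  counts <- calls |>
    mutate(tail_class = factor(.data$tail_class,
                               levels = c(TAIL_CLASSES, "OTHER"))) |>
    count(dplyr::across(dplyr::all_of(grp)), .data$tail_class,
          name = "n", .drop = FALSE)
  counts |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    mutate(
      n_molecules = sum(.data$n[.data$tail_class %in% TAIL_CLASSES]),
      fraction = ifelse(.data$tail_class %in% TAIL_CLASSES,
                        .data$n / .data$n_molecules, NA_real_),
      uridylated = sum(.data$n[.data$tail_class %in% c("AU", "U")]) /
        .data$n_molecules
    ) |>
    ungroup() |>
    mutate(tail_class = as.character(.data$tail_class))
}

#' Three-way tail-length classes
#'
#' Counts tails of one class into short (1-32 nt), mid (33-64 nt) and
#' long (>= 65 nt) length classes; censored calls belong to the top
#' class. The three counts conserve the class total.
#'
#' @param calls deduplicated tail-call tibble.
#' @param tail_class which class to bin (default `"A"`).
#' @param stratum stratification column.
#' @return tibble with `length_class` in `{"1-32", "33-64", ">=65"}` and
#'   `n` per (sample, stratum).
#' @export
length_classes <- function(calls, tail_class = "A", stratum = "reference") {
  grp <- c("sample", stratum)
  lv <- c("1-32", "33-64", ">=65")
  calls |>
    filter(.data$tail_class == !!tail_class) |>
    mutate(length_class = factor(dplyr::case_when(
      .data$censored ~ ">=65",
      .data$total_len >= 65 ~ ">=65",
      .data$total_len >= 33 ~ "33-64",
      TRUE ~ "1-32"), levels = lv)) |>
    count(dplyr::across(dplyr::all_of(grp)), .data$length_class,
          name = "n", .drop = FALSE)
}

#' Per-length tail histogram with a terminal censored category
#'
#' Counts tails of one class at each length from 1 to `window`, plus the
#' `">=window+1"` category holding right-censored calls. The histogram
#' total equals the class count.
#'
#' @param calls deduplicated tail-call tibble.
#' @param tail_class class to tabulate.
#' @param stratum stratification column.
#' @return tibble with `length` (character: `"1"` ... `"80"`, `">=81"`
#'   for the default window) and `n`.
#' @export
tail_length_hist <- function(calls, tail_class = "A", stratum = "reference") {
  grp <- c("sample", stratum)
  sub <- calls |> filter(.data$tail_class == !!tail_class)
  win <- if (nrow(calls)) calls$window[1] else 80L
  lv <- c(as.character(seq_len(win)), paste0(">=", win + 1L))
  sub |>
    mutate(length = factor(
      ifelse(.data$censored, paste0(">=", win + 1L),
             as.character(.data$total_len)), levels = lv)) |>
    count(dplyr::across(dplyr::all_of(grp)), .data$length,
          name = "n", .drop = FALSE)
}

bin_10nt_label <- function(total_len, censored, window) {
  lo <- (pmax(total_len, 1L) - 1L) %/% 10L * 10L + 1L
  ifelse(censored | total_len > window, paste0(">=", window + 1L),
         paste0(lo, "-", lo + 9L))
}

bin_10nt_levels <- function(window) {
  lo <- seq(1L, window, by = 10L)
  c(paste0(lo, "-", lo + 9L), paste0(">=", window + 1L))
}

#' Tail-class composition by total length in 10-nt bins
#'
#' For each 10-nt bin of total tail length, the share of A-, AU- and
#' U-tails. No-tail molecules are excluded: within each bin the three
#' tailed classes sum to 1.
#'
#' @param calls deduplicated tail-call tibble.
#' @param stratum stratification column.
#' @return tibble with `bin`, `tail_class`, `n` and `fraction` (within
#'   bin, over tailed classes).
#' @export
ten_nt_bins <- function(calls, stratum = "reference") {
  grp <- c("sample", stratum)
  win <- if (nrow(calls)) calls$window[1] else 80L
  calls |>
    filter(.data$tail_class %in% c("A", "AU", "U")) |>
    mutate(bin = factor(bin_10nt_label(.data$total_len, .data$censored,
                                       .data$window),
                        levels = bin_10nt_levels(win)),
           tail_class = factor(.data$tail_class, levels = c("A", "AU", "U"))) |>
    count(dplyr::across(dplyr::all_of(grp)), .data$bin, .data$tail_class,
          name = "n", .drop = FALSE) |>
    group_by(dplyr::across(dplyr::all_of(c(grp, "bin")))) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(fraction = ifelse(is.nan(.data$fraction), NA_real_,
                             .data$fraction)) |>
    mutate(tail_class = as.character(.data$tail_class))
}

#' U-stretch length by total tail length (10-nt bins)
#'
#' Joint counts of the uridine-stretch length within uridylated tails
#' (AU and U classes), against the total tail length in 10-nt bins.
#'
#' @param calls deduplicated tail-call tibble.
#' @param stratum stratification column.
#' @return tibble with `bin`, `u_len`, `n`.
#' @export
u_by_total <- function(calls, stratum = "reference") {
  grp <- c("sample", stratum)
  win <- if (nrow(calls)) calls$window[1] else 80L
  calls |>
    filter(.data$tail_class %in% c("AU", "U")) |>
    mutate(bin = factor(bin_10nt_label(.data$total_len, .data$censored,
                                       .data$window),
                        levels = bin_10nt_levels(win))) |>
    count(dplyr::across(dplyr::all_of(grp)), .data$bin, .data$u_len,
          name = "n")
}

#' Median tail lengths per class
#'
#' Medians of the reported lengths, with censored calls included at the
#' window value — consistent with reporting within the observable 0-80
#' window, and biased low relative to the uncensored truth when
#' censoring is heavy (noted in the output).
#'
#' @param calls deduplicated tail-call tibble.
#' @param stratum stratification column.
#' @return tibble with `tail_class`, `n`, `median_total`, `median_a`,
#'   `median_u` and `prop_censored` per (sample, stratum).
#' @export
median_lengths <- function(calls, stratum = "reference") {
  grp <- c("sample", stratum)
  calls |>
    filter(.data$tail_class %in% c("A", "AU", "U")) |>
    group_by(dplyr::across(dplyr::all_of(c(grp, "tail_class")))) |>
    summarise(n = n(),
              median_total = median(.data$total_len),
              median_a = median(.data$a_len),
              median_u = median(.data$u_len),
              prop_censored = mean(.data$censored),
              .groups = "drop")
}

#' Full per-sample summary
#'
#' Bundles the class fractions, length-class counts, per-length
#' histograms, 10-nt-bin composition, U-by-total counts and medians for
#' a set of deduplicated calls.
#'
#' @param calls deduplicated tail-call tibble.
#' @param stratum stratification column (`"reference"` or
#'   `"subfamily"`).
#' @return an object of class `tail_summary` (a named list of tibbles).
#' @export
summarize_tails <- function(calls, stratum = "reference") {
  structure(list(
    stratum = stratum,
    n_molecules = nrow(calls),
    classes = class_fractions(calls, stratum),
    length_classes_a = length_classes(calls, "A", stratum),
    length_classes_au = length_classes(calls, "AU", stratum),
    hist_a = tail_length_hist(calls, "A", stratum),
    hist_au = tail_length_hist(calls, "AU", stratum),
    ten_nt = ten_nt_bins(calls, stratum),
    u_by_total = u_by_total(calls, stratum),
    medians = median_lengths(calls, stratum)
  ), class = "tail_summary")
}

#' @export
print.tail_summary <- function(x, ...) {
  cat("<tail_summary> ", x$n_molecules, " molecules, stratified by ",
      x$stratum, "\n\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @describeIn summarize_tails long tibble of class counts and fractions.
#' @param x a `tail_summary`.
#' @param ... unused.
#' @export
tidy.tail_summary <- function(x, ...) {
  x$classes
}

#' @describeIn summarize_tails one row per (sample, stratum): molecule
#'   count, four class fractions, uridylated fraction and median tail
#'   lengths.
#' @export
glance.tail_summary <- function(x, ...) {
  wide <- x$classes |>
    filter(.data$tail_class %in% TAIL_CLASSES) |>
    select(dplyr::all_of(c("sample", x$stratum)), "n_molecules",
           "uridylated", "tail_class", "fraction") |>
    tidyr::pivot_wider(names_from = "tail_class", values_from = "fraction",
                       names_prefix = "frac_")
  med <- x$medians |>
    select(dplyr::all_of(c("sample", x$stratum)), "tail_class",
           "median_total") |>
    tidyr::pivot_wider(names_from = "tail_class",
                       values_from = "median_total",
                       names_prefix = "median_")
  left_join(wide, med, by = c("sample", x$stratum))
}

#' Export summary tables as TSV
#'
#' Writes one tidy, deterministic TSV per figure-style output.
#'
#' @param summary a `tail_summary` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
export_summaries <- function(summary, dir) {
  stopifnot(inherits(summary, "tail_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- c("classes", "length_classes_a", "length_classes_au",
             "hist_a", "hist_au", "ten_nt", "u_by_total", "medians")
  paths <- vapply(parts, function(p) {
    path <- file.path(dir, paste0(p, ".tsv"))
    readr::write_tsv(summary[[p]], path)
    path
  }, character(1))
  invisible(paths)
}
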