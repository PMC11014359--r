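mk_dedup <- function(tail_class, total_len = 10L, u_len = 0L,
                     censored = FALSE, sample = "wt", reference = "L1rep",
                     window = 80L) {
  n <- max(length(tail_class), length(total_len), length(censored))
  tibble::tibble(
    sample = sample, umi = replicate(n, paste0(sample(LETTERS, 15, TRUE),
                                               collapse = "")),
    reference = reference, subfamily = NA_character_,
    tail_class = rep_len(tail_class, n),
    u_len = rep_len(as.integer(u_len), n),
    total_len = rep_len(as.integer(total_len), n),
    censored = rep_len(censored, n), window = window, group_size = 1L) |>
    dplyr::mutate(a_len = pmax(total_len - u_len, 0L), .before = "u_len")
}

test_that("class fractions are computed over the four classes", {
  calls <- mk_dedup(rep(c("A", "AU", "U", "NONE"), c(50, 25, 15, 10)))
  cf <- class_fractions(calls)
  expect_equal(sum(cf$fraction, na.rm = TRUE), 1, tolerance = 1e-9)
  frac <- setNames(cf$fraction, cf$tail_class)
  expect_equal(unname(frac[c("A", "AU", "U", "NONE")]),
               c(0.50, 0.25, 0.15, 0.10))
  expect_equal(unique(cf$uridylated), 0.40)
  expect_equal(unique(cf$n_molecules), 100L)
})

test_that("OTHER calls are excluded from four-class denominators", {
  calls <- mk_dedup(rep(c("A", "AU", "U", "NONE", "OTHER"),
                        c(50, 25, 15, 10, 20)))
  cf <- class_fractions(calls)
  expect_equal(unique(cf$n_molecules), 100L)
  expect_true(is.na(cf$fraction[cf$tail_class == "OTHER"]))
  expect_equal(cf$n[cf$tail_class == "OTHER"], 20L)
  all_none <- class_fractions(mk_dedup(rep("NONE", 30)))
  expect_equal(unique(all_none$uridylated), 0)
})

test_that("length classes split at 32/64 with censored calls on top", {
  calls <- mk_dedup("A", total_len = c(32L, 33L, 64L, 65L))
  lc <- length_classes(calls)
  expect_equal(setNames(lc$n, lc$length_class),
               c("1-32" = 1L, "33-64" = 2L, ">=65" = 1L))
  cens <- mk_dedup("A", total_len = 80L, censored = TRUE)
  lc2 <- length_classes(cens)
  expect_equal(lc2$n[lc2$length_class == ">=65"], 1L)
  empty <- length_classes(mk_dedup("A", total_len = 1L)[0, ])
  expect_equal(sum(empty$n), 0L)
})

test_that("per-length histograms conserve class counts and hold the censored bin", {
  calls <- mk_dedup(rep(c("A", "AU"), c(30, 10)),
                    total_len = c(rep(40L, 29), 80L, rep(12L, 10)),
                    censored = rep(c(FALSE, TRUE, FALSE), c(29, 1, 10)))
  h <- tail_length_hist(calls, "A")
  expect_equal(sum(h$n), 30L)
  expect_equal(nlevels(h$length), 81L)
  expect_equal(h$n[h$length == ">=81"], 1L)
  expect_equal(h$n[h$length == "40"], 29L)
})

test_that("10-nt bins exclude no-tail molecules and sum to one per bin", {
  calls <- mk_dedup(rep(c("A", "AU", "U", "NONE"), c(12, 6, 2, 5)),
                    total_len = rep(c(15L, 15L, 15L, 0L), c(12, 6, 2, 5)))
  tb <- ten_nt_bins(calls)
  in_bin <- tb[tb$bin == "11-20", ]
  expect_equal(sum(in_bin$n), 20L)  # NONE excluded
  expect_equal(sum(in_bin$fraction), 1)
  expect_equal(in_bin$fraction[in_bin$tail_class == "A"], 12 / 20)
  ub <- u_by_total(calls)
  expect_equal(sum(ub$n), 8L)
})

test_that("median lengths follow the even/odd middle rules", {
  odd <- mk_dedup("A", total_len = c(1L, 2L, 3L))
  expect_equal(median_lengths(odd)$median_total, 2)
  even <- mk_dedup("A", total_len = c(10L, 20L, 30L, 40L))
  expect_equal(median_lengths(even)$median_total, 25)
  # censored calls enter at the window value
  cens <- mk_dedup("A", total_len = c(10L, 80L, 80L),
                   censored = c(FALSE, TRUE, TRUE))
  expect_equal(median_lengths(cens)$median_total, 80)
  expect_equal(median_lengths(cens)$prop_censored, 2 / 3)
})

chisq_2x2_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("the chi-square statistic matches the 2x2 closed form", {
  ct <- compare_class_fractions(c(A = 90, AU = 10), c(A = 10, AU = 90))
  expect_equal(ct$statistic, 128.0)
  expect_equal(ct$statistic, chisq_2x2_closed_form(90, 10, 10, 90))
  expect_equal(ct$df, 1)
  expect_equal(ct$p.value, stats::pchisq(128, df = 1, lower.tail = FALSE))

  ident <- compare_class_fractions(c(A = 5, AU = 5), c(A = 5, AU = 5))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)

  expect_error(compare_class_fractions(c(A = 5, AU = 0), c(A = 5, AU = 0)),
               "pool")

  set.seed(31)
  for (i in 1:1000) {
    tab <- matrix(sample(1:200, 4, TRUE), 2)
    got <- compare_class_fractions(c(A = tab[1, 1], B = tab[1, 2]),
                                   c(A = tab[2, 1], B = tab[2, 2]))
    expect_equal(got$statistic,
                 chisq_2x2_closed_form(tab[1, 1], tab[1, 2],
                                       tab[2, 1], tab[2, 2]))
  }
})

test_that("Mann-Whitney p-values match full enumeration for small samples", {
  # enumeration oracle: all C(6,3) = 20 assignments of ranks to group A
  enum_p <- function(a, b) {
    pooled <- c(a, b)
    u_stat <- function(ia) {
      ra <- rank(pooled)[ia]
      sum(ra) - length(ia) * (length(ia) + 1) / 2
    }
    obs <- u_stat(seq_along(a))
    us <- apply(utils::combn(length(pooled), length(a)), 2, u_stat)
    mu <- length(a) * length(b) / 2
    mean(abs(us - mu) >= abs(obs - mu))
  }
  expect_equal(enum_p(1:3, 4:6), 0.1)
  mw <- compare_length_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p.value, 0.1)
  expect_equal(mw$statistic, 0)

  set.seed(32)
  a <- sample(seq(1, 199, by = 2), 5)  # odd values
  b <- sample(seq(2, 200, by = 2), 6)  # even values: no ties possible
  expect_equal(compare_length_distributions(a, b)$p.value, enum_p(a, b))

  ident <- compare_length_distributions(c(3, 3, 5, 9), c(3, 3, 5, 9))
  expect_equal(ident$p.value, 1)
  expect_error(compare_length_distributions(numeric(0), 1:3), "non-empty")

  # power on clearly shifted samples
  set.seed(33)
  x <- rnbinom(500, mu = 30, size = 5)
  y <- rnbinom(500, mu = 45, size = 5)
  expect_lt(compare_length_distributions(x, y)$p.value, 1e-6)
})

test_that("tail tests tidy into one-row tibbles and adjust across strata", {
  t1 <- compare_class_fractions(c(A = 90, AU = 10), c(A = 10, AU = 90),
                                labels = c("wt", "ko"))
  td <- tidy(t1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$label_a, "wt")
  expect_equal(glance(t1)$statistic, td$statistic)
  many <- dplyr::bind_rows(td, tidy(compare_length_distributions(1:3, 4:6)))
  adj <- adjust_comparisons(many)
  expect_true(all(adj$p.adjusted >= adj$p.value - 1e-12))
})

test_that("summaries export deterministic TSV tables", {
  calls <- mk_dedup(rep(c("A", "AU", "U", "NONE"), c(12, 6, 2, 5)),
                    total_len = rep(c(15L, 25L, 3L, 0L), c(12, 6, 2, 5)))
  ts <- summarize_tails(calls)
  expect_s3_class(ts, "tail_summary")
  g <- glance(ts)
  expect_equal(g$n_molecules, 25L)
  expect_equal(g$frac_A, 12 / 25)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- export_summaries(ts, dir1)
  p2 <- export_summaries(ts, dir2)
  expect_true(all(file.exists(p1)))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # count conservation in the exported class table
  cls <- readr::read_tsv(p1[["classes"]], show_col_types = FALSE)
  expect_equal(sum(cls$n), 25L)
})
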