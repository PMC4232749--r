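flat_track <- function(value = 2, len = 1000, chrom = "chrA") {
  as_signal_track(tibble::tibble(chrom = chrom, start = 0, end = len,
                                 value = value), label = "flat")
}

test_that("bedGraph and fixedStep wiggle tracks load as segment tables", {
  bg <- withr::local_tempfile(lines = c("chrA\t0\t100\t1.5",
                                        "chrA\t200\t300\t2.5",
                                        "chrB\t0\t50\t-1"),
                              fileext = ".bedgraph")
  tr <- read_signal(bg, label = "toy")
  expect_s3_class(tr, "fs_signal_track")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$start[1], 0)
  expect_equal(tr$value, c(1.5, 2.5, -1))

  wig <- withr::local_tempfile(
    lines = c("fixedStep chrom=chrA start=1 step=100 span=100",
              "1", "2", "3", "4", "5"), fileext = ".wig")
  tw <- read_signal(wig)
  expect_equal(nrow(tw), 5)
  expect_equal(tw$end - tw$start, rep(100, 5))
  expect_equal(tw$start[1], 0)
  expect_equal(tw$value, 1:5)

  expect_error(as_signal_track(tibble::tibble(
    chrom = "chrA", start = c(0, 50), end = c(100, 150), value = 1)),
    "overlapping")
  expect_error(as_signal_track(tibble::tibble(
    chrom = "chrA", start = -5, end = 10, value = 1)), "negative")
})

test_that("interval means are length-weighted over covered bases", {
  tr <- as_signal_track(tibble::tibble(
    chrom = "chrA", start = c(0, 100), end = c(100, 400), value = c(1, 3)))
  # hand-computed: (1*100 + 3*300) / 400
  expect_equal(interval_mean(tr, "chrA", 0, 400), 2.5)
  expect_equal(interval_mean(flat_track(7), "chrA", 10, 900), 7)
  # gap handling: excluded by default, zeros on request
  expect_error(interval_mean(tr, "chrA", 500, 600),
               class = "fragsites_undefined_mean")
  expect_equal(interval_mean(tr, "chrA", 0, 500), 2.5)        # gap excluded
  expect_equal(interval_mean(tr, "chrA", 0, 500, gaps_as_zero = TRUE),
               (1 * 100 + 3 * 300) / 500)
})

test_that("interval means are additive under coverage weighting", {
  tr <- as_signal_track(tibble::tibble(
    chrom = "chrA", start = c(0, 100, 300), end = c(100, 250, 500),
    value = c(1, 4, -2)))
  m1 <- interval_mean(tr, "chrA", 0, 200)
  m2 <- interval_mean(tr, "chrA", 200, 500)
  w1 <- 200; w2 <- 50 + 200  # covered bases in each half
  expect_equal(interval_mean(tr, "chrA", 0, 500),
               (m1 * w1 + m2 * w2) / (w1 + w2))
})

test_that("signal deltas subtract the site's own chromosome mean", {
  sites <- toy_sites(data.frame(fra = c("S1", "S2"), chrom = "chrA",
                                start = c(101, 801), end = c(200, 900)))
  expect_equal(signal_delta(flat_track(), sites)$delta, c(0, 0))

  # planted shift: site occupies 100 bp of a 1000 bp chromosome
  shifted <- as_signal_track(tibble::tibble(
    chrom = "chrA", start = c(0, 100, 200), end = c(100, 200, 1000),
    value = c(1, 1 + 2, 1)))
  one <- toy_sites(data.frame(fra = "S", chrom = "chrA", start = 101, end = 200))
  expect_equal(signal_delta(shifted, one)$delta, 2 * (1 - 100 / 1000))

  # site covering the whole chromosome has delta exactly 0
  whole <- toy_sites(data.frame(fra = "W", chrom = "chrA", start = 1, end = 1000))
  expect_equal(signal_delta(shifted, whole)$delta, 0)
})

test_that("deltas are invariant to a global track shift", {
  sites <- toy_sites(data.frame(fra = c("S1", "S2"), chrom = "chrA",
                                start = c(51, 501), end = c(150, 700)))
  withr::local_seed(11)
  vals <- rnorm(10)
  tr <- as_signal_track(tibble::tibble(chrom = "chrA", start = (0:9) * 100,
                                       end = (1:10) * 100, value = vals))
  tr_shift <- as_signal_track(tibble::tibble(chrom = "chrA", start = (0:9) * 100,
                                             end = (1:10) * 100, value = vals + 13))
  expect_equal(signal_delta(tr, sites)$delta, signal_delta(tr_shift, sites)$delta)
})

test_that("sites on uncovered chromosomes get NA deltas with a warning", {
  sites <- toy_sites(data.frame(fra = c("A1", "B1"), chrom = c("chrA", "chrB"),
                                start = 1, end = 100))
  expect_warning(d <- signal_delta(flat_track(), sites), "undefined")
  expect_equal(d$delta, c(0, NA))
})

test_that("group comparison matches a textbook ANOVA computed by hand", {
  deltas <- tibble::tibble(
    site_id = "S", track_label = paste0("mark:", c("c1", "c1", "c1", "c2", "c2", "c2")),
    delta = c(1, 2, 3, 2, 3, 4))
  fit <- compare_groups(deltas, grouping = c(c1 = "g1", c2 = "g2"))
  # oracle: explicit sums of squares
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4); grand <- mean(c(g1, g2))
  ssb <- 3 * (mean(g1) - grand)^2 + 3 * (mean(g2) - grand)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(fit$statistic, f_oracle)
  expect_equal(fit$statistic, 1.5)
  expect_equal(fit$p.value, pf(f_oracle, 1, 4, lower.tail = FALSE))
  expect_equal(fit$df, c(1, 4))
  expect_equal(as.numeric(fit$group_means), c(2, 3))
})

test_that("identical group distributions give F = 0 and short groups fail", {
  deltas <- tibble::tibble(
    site_id = "S", track_label = paste0("m:", c("a", "a", "b", "b")),
    delta = c(1, 2, 1, 2))
  fit <- compare_groups(deltas, grouping = c(a = "g1", b = "g2"))
  expect_equal(fit$statistic, 0)
  short <- tibble::tibble(site_id = "S", track_label = c("m:a", "m:a", "m:b"),
                          delta = c(1, 2, 3))
  expect_error(compare_groups(short, c(a = "g1", b = "g2")), ">= 2 values")
  constant <- tibble::tibble(site_id = "S",
                             track_label = paste0("m:", c("a", "a", "b", "b")),
                             delta = rep(5, 4))
  expect_error(compare_groups(constant, c(a = "g1", b = "g2")), "undefined")
})

test_that("a large planted group shift is detected at p < 0.001", {
  withr::local_seed(3)
  n <- 20; sigma <- 1
  deltas <- tibble::tibble(
    site_id = "S",
    track_label = paste0("m:", rep(c("a", "b"), each = n)),
    delta = c(rnorm(n, 0, sigma), rnorm(n, 5 * sigma, sigma)))
  fit <- compare_groups(deltas, c(a = "g1", b = "g2"))
  expect_lt(fit$p.value, 0.001)
})

test_that("box summaries follow the five-number + 1.5 IQR convention", {
  one <- distribution_summary(42)
  expect_true(all(one$stats == 42))
  expect_length(one$outliers, 0)

  nine <- distribution_summary(1:9)
  expect_equal(unname(nine$stats["median"]), 5)
  expect_equal(unname(nine$stats[c("q1", "q3")]),
               unname(quantile(1:9, c(.25, .75), type = 7)))
  expect_length(nine$outliers, 0)

  spiked <- distribution_summary(c(1:9, 100))
  # oracle by hand: q3 + 1.5*IQR fence
  q <- quantile(c(1:9, 100), c(.25, .75), type = 7)
  expect_equal(spiked$outliers, 100)
  expect_gt(100, q[2] + 1.5 * (q[2] - q[1]))
  hinge <- distribution_summary(1:9, rule = "hinges")
  expect_equal(unname(hinge$stats[c("q1", "q3")]), c(3, 7))
  expect_error(distribution_summary(numeric(0)), "no values")
})

test_that("the default cell grouping covers the seven reference lines", {
  g <- default_cell_groups()
  expect_setequal(names(g), c("K562", "GM12878", "H1-hESC", "NHEK", "HSMM",
                              "HUVEC", "NHLF"))
  expect_equal(length(unique(g)), 3)
  deltas <- tibble::tibble(site_id = rep(c("S1", "S2"), each = 7),
                           track_label = rep(paste0("H3K27ac:", names(g)), 2),
                           delta = c(1, 1.2, 0.8, 2, 2.2, 1.9, 2.1,
                                     0.9, 1.1, 1.0, 2.1, 2.0, 1.8, 2.2))
  fit <- compare_groups(deltas)
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 3)
})
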