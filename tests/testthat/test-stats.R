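test_that("one-way ANOVA matches hand computation and the F(1, n-2) = t^2 identity", {
  # SSB = 13.5, SSW = 4, MSW = 1 => F = 13.5 on df (1, 4)
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$p, stats::pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    res <- one_way_anova(c(x, y), rep(c("g1", "g2"), c(n1, n2)))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("ANOVA is shift-invariant, scale-invariant in F, and numerically robust", {
  set.seed(11)
  x <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  f0 <- one_way_anova(x, g)$F
  expect_equal(one_way_anova(x + 1e4, g)$F, f0, tolerance = 1e-6)
  expect_equal(one_way_anova(3.7 * x, g)$F, f0, tolerance = 1e-9)
  # huge offset in one value: finite result, no overflow
  y <- x; y[1] <- y[1] + 1e9
  expect_true(is.finite(one_way_anova(y, g)$F))
})

test_that("ANOVA degenerate and usage errors are specific", {
  expect_equal(one_way_anova(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$F, 0)
  expect_equal(one_way_anova(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$p, 1)
  expect_error(one_way_anova(rep(5, 6), rep(c("a", "b"), each = 3)),
               class = "tremorkit_degenerate_error")
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")),
               class = "tremorkit_usage_error")
  expect_error(one_way_anova(1:3, rep("a", 3)),
               class = "tremorkit_usage_error")
})

make_features <- function(n_pd = 6, n_co = 6, delta = 0, seed = 1,
                          segments = c("upper_arm", "forearm", "hand"),
                          sides = c("left", "right")) {
  set.seed(seed)
  subj <- tibble::tibble(
    subject_id = c(sprintf("PD%02d", seq_len(n_pd)),
                   sprintf("CO%02d", seq_len(n_co))),
    group = rep(c("PD", "CO"), c(n_pd, n_co)))
  grid <- tidyr::expand_grid(subj, side = sides, segment = segments)
  vals <- lapply(feature_metrics(), function(mcol)
    rnorm(nrow(grid)) + ifelse(grid$group == "PD", delta, 0))
  grid <- dplyr::bind_cols(grid, setNames(vals, feature_metrics()))
  grid$updrs21 <- ifelse(grid$group == "PD",
                         as.integer(runif(nrow(grid)) < 0.3), NA_integer_)
  grid
}

test_that("PD-vs-CO comparison covers every metric x side x segment cell", {
  feats <- make_features(delta = 3)
  cmp <- compare_pd_vs_co(feats)
  expect_equal(nrow(cmp), 12 * 2 * 3)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_true(all(cmp$F >= 0))
  expect_identical(cmp$significant, cmp$p < 0.05)
  expect_true(all(cmp$n1 == 6 & cmp$n2 == 6))
  # delta = 3 SDs: essentially everything separates
  expect_gt(mean(cmp$significant), 0.9)
  # group summaries equal direct recomputation
  row <- cmp[cmp$metric == "rms_kin_gyr" & cmp$side == "left" &
               cmp$segment == "hand", ]
  ref <- feats[feats$side == "left" & feats$segment == "hand", ]
  expect_equal(row$mean2, mean(ref$rms_kin_gyr[ref$group == "PD"]))
  expect_equal(row$sd2, sd(ref$rms_kin_gyr[ref$group == "PD"]))
  expect_equal(row$mean1, mean(ref$rms_kin_gyr[ref$group == "CO"]))
  # glance/tidy round out the broom surface
  g <- glance(cmp)
  expect_equal(g$n_tests, 72)
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_false(inherits(tidy(cmp), "tremor_comparison"))
})

test_that("comparisons require both groups and n >= 2 per cell", {
  feats <- make_features()
  expect_error(compare_pd_vs_co(dplyr::filter(feats, group == "PD")),
               class = "tremorkit_usage_error")
  one <- dplyr::filter(feats, group == "CO" | subject_id == "PD01")
  expect_error(compare_pd_vs_co(one), class = "tremorkit_usage_error")
})

test_that("null features yield near-alpha significance rates", {
  feats <- make_features(n_pd = 10, n_co = 10, delta = 0, seed = 99)
  cmp <- compare_pd_vs_co(feats)
  # 72 independent null tests: expect around 5% flagged
  expect_lt(mean(cmp$significant), 0.2)
})

test_that("score stratification reports group sizes and handles exclusions", {
  feats <- make_features(n_pd = 18, n_co = 2, seed = 3)
  # fix the right-side scores: 14 zeros, 4 ones
  right_pd <- feats$group == "PD" & feats$side == "right"
  scores <- rep(c(0L, 1L), c(14, 4))[match(feats$subject_id[right_pd],
                                           sprintf("PD%02d", 1:18))]
  feats$updrs21[right_pd] <- scores
  cmp <- compare_updrs(feats, side = "right")
  expect_equal(unique(cmp$n1), 14)
  expect_equal(unique(cmp$n2), 4)
  expect_equal(nrow(cmp), 12 * 3)
  expect_equal(attr(cmp, "group_labels"), c("Right 0", "Right 1"))

  # a level-2 side is dropped with a warning, comparison still 0 vs 1
  feats2 <- feats
  feats2$updrs21[feats2$subject_id == "PD01" & feats2$side == "right"] <- 2L
  expect_warning(cmp2 <- compare_updrs(feats2, side = "right"),
                 "scores 0 and 1")
  expect_equal(unique(cmp2$n1), 13)

  # all-zero scores: stratification impossible
  feats3 <- feats
  feats3$updrs21[feats3$group == "PD"] <- 0L
  expect_error(compare_updrs(feats3, side = "right"),
               class = "tremorkit_stratification_error")
})

test_that("summary rendering formats means and flags significance", {
  feats <- make_features(delta = 3)
  cmp <- compare_pd_vs_co(feats)
  out <- render_summary_tables(cmp)
  expect_equal(nrow(out), nrow(cmp))
  expect_true(all(grepl("±", out$CO)))
  expect_identical(out$sig == "*", cmp$significant)
  txt <- render_summary_tables(cmp[1, ], format = "text")
  expect_type(txt, "character")
  expect_error(render_summary_tables(cmp[0, ]),
               class = "tremorkit_usage_error")
})
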