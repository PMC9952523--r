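anova_fixture <- function() {
  tibble::tibble(
    gait_score = rep(c("A", "B", "C"), each = 4),
    value = c(1, 2, 3, 4, 2, 3, 4, 5, 6, 7, 8, 9)
  )
}

test_that("one-way ANOVA matches the closed-form sums of squares", {
  # hand computation: group means 2.5/3.5/7.5, grand 4.5,
  # SSb = 4*(4+1+9) = 56, SSw = 3*5 = 15, F = 28/(5/3) = 16.8
  a <- one_way_anova(anova_fixture())
  expect_equal(a$F, 16.8)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 9L)
  expect_equal(a$p_value, stats::pf(16.8, 2, 9, lower.tail = FALSE))
  expect_false(a$degenerate)
})

test_that("degenerate variance structures are flagged with conventional p", {
  flat <- tibble::tibble(gait_score = rep(c("A", "B", "C"), each = 2),
                         value = rep(1, 6))
  a <- one_way_anova(flat)
  expect_equal(a$p_value, 1)
  expect_true(a$degenerate)

  sep <- tibble::tibble(gait_score = rep(c("A", "B", "C"), each = 2),
                        value = rep(c(0, 10, 20), each = 2))
  a2 <- one_way_anova(sep)
  expect_equal(a2$p_value, 0)
  expect_equal(a2$F, Inf)
  expect_true(a2$degenerate)

  expect_error(one_way_anova(tibble::tibble(gait_score = c("A", "A", "B"),
                                            value = 1:3)), "2 values")
})

test_that("pooled SE is sqrt(MS_within / n), with per-group fallback", {
  se <- pooled_se(anova_fixture())
  expect_equal(as.numeric(se), sqrt((5 / 3) / 4))
  # within-group variance 16 (deviations +-2*sqrt(3)), n = 4 -> SE 2
  s3 <- 2 * sqrt(3)
  d <- tibble::tibble(gait_score = rep(c("A", "B"), each = 4),
                      value = c(4 - s3, 4 - s3, 4 + s3, 4 + s3,
                                14 - s3, 14 - s3, 14 + s3, 14 + s3))
  expect_equal(as.numeric(pooled_se(d)), 2)
  flat <- tibble::tibble(gait_score = rep(c("A", "B"), each = 3),
                         value = rep(2, 6))
  expect_equal(as.numeric(pooled_se(flat)), 0)
  unb <- tibble::tibble(gait_score = c("A", "A", "B", "B", "B"),
                        value = c(1, 2, 3, 4, 5))
  se_u <- pooled_se(unb)
  expect_true(is.na(as.numeric(se_u)))
  per <- attr(se_u, "per_group")
  expect_equal(per$n, c(2L, 3L))
})

test_that("ANOVA and LSD agree with the reference linear-model route", {
  for (seed in 1:12) {
    set.seed(seed)
    d <- tibble::tibble(gait_score = rep(c("0", "1", "2"), each = 4),
                        value = rnorm(12, mean = rep(c(0, 1, 3), each = 4)))
    ours <- one_way_anova(d)
    ref <- stats::anova(stats::lm(value ~ gait_score, data = d))
    expect_equal(ours$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(ours$ms_within, ref$`Mean Sq`[2], tolerance = 1e-10)
    # pairwise t against a direct computation from the reference MSw
    lsd <- fisher_lsd(d)
    msw <- ref$`Mean Sq`[2]
    for (i in seq_len(nrow(lsd$pairwise))) {
      g1 <- lsd$pairwise$group1[i]; g2 <- lsd$pairwise$group2[i]
      m1 <- mean(d$value[d$gait_score == g1])
      m2 <- mean(d$value[d$gait_score == g2])
      tref <- (m1 - m2) / sqrt(msw * (1 / 4 + 1 / 4))
      pref <- 2 * stats::pt(abs(tref), 9, lower.tail = FALSE)
      expect_equal(lsd$pairwise$p_value[i], pref, tolerance = 1e-10)
    }
  }
})

test_that("letter displays encode exactly the pairwise significance relation", {
  for (seed in 1:25) {
    set.seed(100 + seed)
    k <- sample(3:5, 1)
    d <- tibble::tibble(
      gait_score = rep(letters[1:k], each = 4),
      value = rnorm(4 * k, mean = rep(runif(k, 0, 3), each = 4))
    )
    lsd <- fisher_lsd(d, alpha = 0.05)
    lt <- lsd$letters
    share <- function(g1, g2) {
      l1 <- strsplit(lt$letter[lt$group == g1], "")[[1]]
      l2 <- strsplit(lt$letter[lt$group == g2], "")[[1]]
      length(intersect(l1, l2)) > 0
    }
    for (i in seq_len(nrow(lsd$pairwise))) {
      expect_equal(share(lsd$pairwise$group1[i], lsd$pairwise$group2[i]),
                   lsd$pairwise$p_value[i] > 0.05)
    }
  }
})

test_that("letter patterns cover the canonical all-same / all-differ / chain cases", {
  close_d <- tibble::tibble(gait_score = rep(c("0", "1", "2"), each = 4),
                            value = c(10.0, 10.2, 9.9, 10.1,
                                      10.1, 10.0, 10.2, 9.8,
                                      9.9, 10.1, 10.0, 10.2))
  expect_equal(unique(fisher_lsd(close_d)$letters$letter), "a")

  far_d <- tibble::tibble(gait_score = rep(c("0", "1", "2"), each = 4),
                          value = rep(c(0, 10, 20), each = 4) +
                            rep(c(-0.1, 0.1, -0.1, 0.1), 3))
  expect_equal(fisher_lsd(far_d)$letters$letter, c("a", "b", "c"))

  # only the extremes differ -> a / ab / b
  chain <- tibble::tibble(gait_score = rep(c("H", "M", "L"), each = 4),
                          value = c(11, 12, 13, 14, 9.5, 10.5, 11.5, 12.5,
                                    8, 9, 10, 11))
  lsd <- fisher_lsd(chain)
  sig <- lsd$pairwise$p_value <= 0.05
  expect_equal(sum(sig), 1L)             # exactly one significant pair
  expect_equal(lsd$letters$letter, c("a", "ab", "b"))
  expect_equal(lsd$letters$group, c("H", "M", "L"))
})

test_that("ANOVA is invariant to shifts and positive scalings", {
  d <- anova_fixture()
  base <- one_way_anova(d)
  sh <- d; sh$value <- sh$value + 100
  sc <- d; sc$value <- sc$value * 7.3
  expect_equal(one_way_anova(sh)$F, base$F, tolerance = 1e-12)
  expect_equal(one_way_anova(sc)$F, base$F, tolerance = 1e-12)
  expect_equal(one_way_anova(sc)$p_value, base$p_value, tolerance = 1e-12)
})

test_that("compare_metrics excludes NA birds and tidies per group", {
  set.seed(77)
  d <- tibble::tibble(
    bird_id = sprintf("b%02d", 1:12),
    gait_score = rep(0:2, each = 4),
    speed_x_avg = rnorm(12, rep(c(200, 60, 20), each = 4), 10),
    forward_duration_avg = c(rnorm(8, rep(c(0.8, 0.3), each = 4), 0.05),
                             NA, NA, NA, NA)
  )
  cmp <- compare_metrics(d)
  g <- glance(cmp)
  expect_equal(nrow(g), 2L)
  expect_equal(g$n_excluded[g$metric == "forward_duration_avg"], 4L)
  expect_equal(g$n_used[g$metric == "forward_duration_avg"], 8L)
  td <- tidy(cmp)
  expect_true(all(c("metric", "gait_score", "mean", "letter", "p_value")
                  %in% names(td)))
  expect_equal(nrow(td[td$metric == "speed_x_avg", ]), 3L)
})

test_that("metric_table mirrors the means-table layout", {
  empty <- structure(list(results = tibble::tibble(), alpha = 0.05),
                     class = "gait_comparison")
  expect_equal(nrow(metric_table(empty)), 0L)

  set.seed(9)
  d <- tibble::tibble(
    bird_id = sprintf("b%02d", 1:12),
    gait_score = rep(0:2, each = 4),
    speed_x_avg = rnorm(12, rep(c(200, 60, 20), each = 4), 10),
    speed_x_max = rnorm(12, rep(c(360, 120, 70), each = 4), 20)
  )
  tab <- metric_table(compare_metrics(d))
  expect_equal(nrow(tab), 5L)            # 3 scores + s.e. + p-value
  expect_equal(tab$row, c("0", "1", "2", "s.e.", "p-value"))
  expect_match(tab$average[1], "^[0-9.]+ [a-z]+$")
  expect_false(any(is.na(tab$maximum)))
})
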