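test_that("tier counts per region match brute-force position filtering", {
  seq <- random_protein(300, seed = 15)
  subs <- enumerate_saturation(seq)
  set.seed(16)
  tab <- panel_scores(subs, humdiv = runif(nrow(subs)),
                      humvar = runif(nrow(subs)),
                      provean = rnorm(nrow(subs), -3, 2))
  tiers <- tier_table(tab)
  rc <- count_tiers_by_region(tiers)

  reg <- default_regions()
  for (i in seq_len(nrow(reg))) {
    inside <- tiers[tiers$position >= reg$start[i] &
                      tiers$position <= reg$end[i], ]
    row <- rc[rc$region == reg$name[i], ]
    expect_equal(row$total, nrow(inside))
    expect_equal(row$total, 19L * (reg$end[i] - reg$start[i] + 1L))
    expect_equal(row$P3, sum(inside$tier == "P3"))
    expect_equal(row$B3, sum(inside$tier == "B3"))
  }
  # TEY motif spans 3 positions -> 57 substitutions
  expect_equal(rc$total[rc$region == "TEY motif"], 57L)
  # regions plus "other" partition the table
  expect_equal(sum(rc$total), nrow(tiers))

  all_p3 <- tiers; all_p3$tier <- factor("P3", levels = levels(tiers$tier))
  rc2 <- count_tiers_by_region(all_p3)
  expect_true(all(rc2$pct_P3[rc2$total > 0] == 100))
})

test_that("two-proportion z test matches the chi-square oracle", {
  cases <- list(c(50, 100, 30, 100), c(10, 40, 20, 60), c(3, 10, 9, 12))
  set.seed(17)
  for (i in 1:10) {
    n1 <- sample(10:200, 1); n2 <- sample(10:200, 1)
    cases[[length(cases) + 1]] <- c(sample(1:(n1 - 1), 1), n1,
                                    sample(1:(n2 - 1), 1), n2)
  }
  for (cs in cases) {
    res <- two_proportion_test(cs[1], cs[2], cs[3], cs[4])
    chi <- suppressWarnings(
      stats::prop.test(c(cs[1], cs[3]), c(cs[2], cs[4]), correct = FALSE))
    expect_equal(res$z^2, unname(chi$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, chi$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate and extreme proportion comparisons behave", {
  eq <- two_proportion_test(5, 10, 10, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  expect_false(eq$significant)

  none <- two_proportion_test(0, 10, 0, 10) # pooled proportion 0
  expect_true(is.na(none$z))
  expect_equal(none$p_value, 1)

  sep <- two_proportion_test(10, 10, 0, 10)
  expect_true(sep$significant)
  expect_true(sep$p_value < 0.05)
})

test_that("critical vs non-critical pooling and complementarity", {
  seq <- random_protein(300, seed = 18)
  subs <- enumerate_saturation(seq)

  # region-dependent scores: critical positions strongly damaging
  reg <- default_regions()
  crit_pos <- unlist(mapply(function(s, e) s:e, reg$start[reg$critical],
                            reg$end[reg$critical]))
  in_crit <- subs$position %in% crit_pos
  set.seed(19)
  p_damaging <- ifelse(in_crit, 0.95, 0.70)
  damaging <- runif(nrow(subs)) < p_damaging
  tab <- panel_scores(subs,
                      humdiv = ifelse(damaging, 0.99, 0.1),
                      humvar = ifelse(damaging, 0.99, 0.1),
                      provean = ifelse(damaging, -8, 0))
  tiers <- tier_table(tab)
  rc <- count_tiers_by_region(tiers)
  res <- critical_vs_noncritical(rc)

  # ~25-point gap at n in the hundreds per group: clearly significant
  expect_true(res$pathogenic$significant)
  expect_true(res$pathogenic$p1 > res$pathogenic$p2)
  # benign test is the complement: equal |z|, opposite sign
  expect_equal(res$benign$z, -res$pathogenic$z)
  expect_equal(res$benign$p_value, res$pathogenic$p_value)
  expect_equal(nrow(res$per_window), 2L)

  # identical tier distributions -> not significant
  flat <- rc
  flat[, c("P3", "P2", "B2", "B3")] <-
    matrix(rep(c(76, 19, 0, 0), each = nrow(rc)), nrow = nrow(rc)) *
    flat$total / 95
  flat$P3 <- round(0.8 * flat$total); flat$P2 <- flat$total - flat$P3
  flat$B2 <- 0L; flat$B3 <- 0L
  res2 <- critical_vs_noncritical(flat)
  expect_false(res2$pathogenic$significant)
})

test_that("power check: a 20-point gap at n around 500 per group is detected", {
  res <- two_proportion_test(round(0.9 * 500), 500, round(0.7 * 500), 500)
  expect_true(res$significant)
  expect_true(res$p_value < 1e-6)
})
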