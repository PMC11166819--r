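test_that("identical group means give F near zero and p near one", {
  set.seed(1)
  gs <- group_summary(c("a", "b", "c"), mean = c(5, 5, 5),
                      sd = c(1, 2, 1.5), n = c(8, 8, 8))
  res <- one_way_anova(gs)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("summary-mode and raw-mode ANOVA agree to 1e-10", {
  set.seed(2)
  for (i in 1:5) {
    df <- exact_group_data(means = rnorm(3, 10, 4), sds = runif(3, 0.5, 3),
                           ns = sample(5:15, 3),
                           groups = c("control", "small_CDH", "large_CDH"))
    raw <- one_way_anova(df, "y")
    summ <- one_way_anova(summarize_groups(df, "y"))
    expect_equal(raw$F, summ$F, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
    expect_identical(raw$df, summ$df)
  }
})

test_that("groups of size one are rejected", {
  df <- data.frame(group = c("a", "a", "b"), y = c(1, 2, 3))
  expect_error(one_way_anova(df, "y"), "n >= 2")
  expect_error(group_summary(c("a", "b"), c(1, 2), c(1, 1), c(1, 5)),
               "n >= 2")
})

test_that("Tukey-Kramer from summaries matches TukeyHSD on matching raw data", {
  set.seed(3)
  for (i in 1:5) {
    ns <- if (i <= 2) rep(9, 3) else sample(4:12, 3)  # equal and unequal n
    df <- exact_group_data(means = rnorm(3, 0, 5), sds = runif(3, 0.5, 2),
                           ns = ns, groups = c("g1", "g2", "g3"))
    gs <- summarize_groups(df, "y")
    ref <- TukeyHSD(aov(y ~ factor(group), data = df))[[1]]
    for (pair in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))) {
      mine <- posthoc_from_summary(gs, pair, "tukey_kramer")
      row <- ref[paste(pair[2], pair[1], sep = "-"), ]
      expect_equal(mine$mean_difference, unname(row["diff"]),
                   tolerance = 1e-8)
      expect_equal(mine$ci_low, unname(row["lwr"]), tolerance = 1e-8)
      expect_equal(mine$ci_high, unname(row["upr"]), tolerance = 1e-8)
      expect_equal(mine$p_adjusted, unname(row["p adj"]), tolerance = 1e-8)
    }
  }
})

test_that("Games-Howell approaches Tukey under equal variances and widens under unequal ones", {
  gs <- group_summary(c("a", "b", "c"), mean = c(0, 1, 2),
                      sd = c(1.5, 1.5, 1.5), n = c(30, 30, 30))
  tk <- posthoc_from_summary(gs, c("a", "b"), "tukey_kramer")
  gh <- posthoc_from_summary(gs, c("a", "b"), "games_howell")
  expect_equal(gh$mean_difference, tk$mean_difference)
  expect_equal(gh$ci_high - gh$ci_low, tk$ci_high - tk$ci_low,
               tolerance = 0.03)
  gs2 <- group_summary(c("a", "b", "c"), mean = c(0, 1, 2),
                       sd = c(0.5, 4, 0.5), n = c(10, 10, 10))
  gh_ab <- posthoc_from_summary(gs2, c("a", "b"), "games_howell")
  gh_ac <- posthoc_from_summary(gs2, c("a", "c"), "games_howell")
  expect_gt(gh_ab$ci_high - gh_ab$ci_low, gh_ac$ci_high - gh_ac$ci_low)
})

test_that("identical summaries give zero difference and p near one", {
  gs <- group_summary(c("a", "b"), mean = c(3, 3), sd = c(1, 1), n = c(6, 6))
  r <- posthoc_from_summary(gs, c("a", "b"), "tukey_kramer")
  expect_equal(r$mean_difference, 0)
  expect_gt(r$p_adjusted, 0.999)
  expect_error(posthoc_from_summary(gs, c("a", "b"), "banana"), "method")
})

# Independent split-plot oracle: explicit sums of squares for a balanced
# two-level within factor.
mixed_anova_oracle <- function(tab, outcome) {
  y <- cbind(tab[[paste0(outcome, "_nonaff")]],
             tab[[paste0(outcome, "_aff")]])
  g <- as.character(tab$group)
  k <- length(unique(g)); n <- nrow(y)
  gm <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(c(y[, 1], y[, 2]), rep(g, 2), mean)
  side_mean <- colMeans(y)
  cell_mean <- rbind(tapply(y[, 1], g, mean), tapply(y[, 2], g, mean))
  ng <- table(g)[names(grp_mean)]
  ss_group <- 2 * sum(ng * (grp_mean - gm)^2)
  ss_subj <- 2 * sum((subj_mean - grp_mean[g])^2)
  ss_side <- n * sum((side_mean - gm)^2)
  ss_int <- sum(rep(ng, 2) *
                  (t(cell_mean[, names(grp_mean)]) -
                     outer(grp_mean, side_mean, `+`) + gm)^2)
  resid <- y
  for (s in 1:2) resid[, s] <- y[, s] - cell_mean[s, ][g] -
    subj_mean + grp_mean[g]
  ss_err <- sum(resid^2)
  list(F_group = (ss_group / (k - 1)) / (ss_subj / (n - k)),
       F_side = ss_side / (ss_err / (n - k)),
       F_int = (ss_int / (k - 1)) / (ss_err / (n - k)))
}

test_that("mixed ANOVA matches the explicit split-plot partitioning", {
  set.seed(5)
  for (i in 1:3) {
    tab <- generate_cohort_table(cohort_sim_config(seed = i))
    fit <- mixed_anova_group_side(tab, "vdp")
    orc <- mixed_anova_oracle(tab, "vdp")
    expect_equal(fit$F[fit$effect == "group"], orc$F_group,
                 tolerance = 1e-8)
    expect_equal(fit$F[fit$effect == "side"], orc$F_side, tolerance = 1e-8)
    expect_equal(fit$F[fit$effect == "group:side"], orc$F_int,
                 tolerance = 1e-8)
  }
})

test_that("duplicated side values give zero side and interaction F", {
  tab <- generate_cohort_table(cohort_sim_config(seed = 6))
  tab$vdp_aff <- tab$vdp_nonaff
  fit <- mixed_anova_group_side(tab, "vdp")
  expect_equal(fit$F[fit$effect == "side"], 0)
  expect_equal(fit$F[fit$effect == "group:side"], 0)
})

test_that("subjects missing a side are dropped with a message", {
  tab <- generate_cohort_table(cohort_sim_config(seed = 7))
  tab$vdp_aff[1] <- NA
  expect_message(fit <- mixed_anova_group_side(tab, "vdp"), "1 subjects")
  expect_equal(nrow(fit), 3)
  tab$vdp_aff[tab$group == "large_CDH"] <- NA
  expect_error(suppressMessages(mixed_anova_group_side(tab, "vdp")),
               "fewer than 2")
})

test_that("Bonferroni side contrasts scale raw paired-t p values by the group count", {
  tab <- generate_cohort_table(cohort_sim_config(seed = 8))
  res <- bonferroni_side_posthoc(tab, "qdp")
  expect_equal(nrow(res), 3)
  for (g in res$group) {
    d <- tab$qdp_aff[tab$group == g] - tab$qdp_nonaff[tab$group == g]
    raw <- t.test(d)
    expect_equal(res$p_adjusted[res$group == g],
                 min(1, 3 * raw$p.value), tolerance = 1e-10)
    ci <- t.test(d, conf.level = 1 - 0.05 / 3)$conf.int
    expect_equal(res$ci_low[res$group == g], ci[1], tolerance = 1e-10)
    expect_equal(res$ci_high[res$group == g], ci[2], tolerance = 1e-10)
  }
})

test_that("zero within-pair differences give p = 1 and a degenerate interval at 0", {
  tab <- generate_cohort_table(cohort_sim_config(seed = 9))
  tab$vdp_aff <- tab$vdp_nonaff
  res <- bonferroni_side_posthoc(tab, "vdp")
  expect_true(all(res$p_adjusted == 1))
  expect_true(all(res$ci_low == 0 & res$ci_high == 0))
})

test_that("a planted side difference of 14.8 (sd 3, n 6) is detected reliably", {
  hits <- 0L
  for (r in 1:200) {
    set.seed(r)
    tab <- data.frame(
      id = sprintf("s%02d", 1:18),
      group = rep(c("control", "small", "large"), each = 6),
      x_nonaff = rnorm(18, 8, 3),
      x_aff = rnorm(18, 8, 3))
    large <- tab$group == "large"
    tab$x_aff[large] <- rnorm(6, 8 + 14.8, 3)
    res <- bonferroni_side_posthoc(tab, "x")
    if (res$p_adjusted[res$group == "large"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Spearman screen reproduces hand-computed rank correlations and BH", {
  df <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3),
                   z = c(1, 2, 3, 4))
  res <- spearman_bh(df, "x", c("y", "z"))
  expect_equal(res$rho[res$y == "y"], 0.6)
  expect_equal(res$rho[res$y == "z"], 1)

  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))

  df$c <- 5
  expect_warning(res2 <- spearman_bh(df, "x", "c"), "constant")
  expect_true(is.na(res2$rho))
  df2 <- df[1:3, ]
  expect_warning(spearman_bh(df2, "x", "y"), "complete pairs")
})

test_that("group power on reference VDP parameters is high", {
  ov <- reference_cohort_summaries("overall")
  vdp <- ov[ov$outcome == "vdp_pct", ]
  hits <- 0L
  for (r in 1:200) {
    set.seed(r)
    y <- unlist(mapply(function(m, s, n) rnorm(n, m, s), vdp$mean, vdp$sd,
                       vdp$n, SIMPLIFY = FALSE))
    df <- data.frame(group = rep(vdp$group, vdp$n), y = y)
    if (one_way_anova(df, "y")$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.90)
})
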