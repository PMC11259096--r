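test_that("assumption gates flag normal and non-normal data correctly", {
  set.seed(20)
  d_norm <- group_df(rnorm(50), rnorm(50), rnorm(50))
  g <- gate_assumptions(d_norm)
  expect_true(g$normal)
  expect_true(g$homoscedastic)
  expect_equal(g$variance_test$test, "bartlett")

  # Shapiro-Wilk has essentially full power against exponential at n = 50
  set.seed(21)
  d_exp <- group_df(rexp(50), rnorm(50), rnorm(50))
  g2 <- gate_assumptions(d_exp)
  expect_false(g2$normal)
  expect_equal(g2$variance_test$test, "levene_median")

  # identical values in every group: trivially homoscedastic
  d_same <- group_df(c(1, 5, 3, 2, 4, 6), c(1, 5, 3, 2, 4, 6), c(1, 5, 3, 2, 4, 6))
  expect_true(gate_assumptions(d_same, quiet = TRUE)$homoscedastic)

  expect_error(gate_assumptions(group_df(1:2, 3:4)), "at least 3")
  expect_warning(gate_assumptions(group_df(c(1, 2, 3.5), c(2, 3, 4.5))), "little power")
})

test_that("gate verdicts agree with the reference implementations", {
  set.seed(22)
  d <- group_df(rnorm(30), rnorm(30, 0, 3), rnorm(30))
  g <- gate_assumptions(d)
  sw_ref <- vapply(split(d$value, d$group), function(x) shapiro.test(x)$p.value, numeric(1))
  expect_equal(sort(g$shapiro$p), sort(unname(sw_ref)))
  if (g$normal) {
    expect_equal(g$variance_test$p, bartlett.test(value ~ group, d)$p.value)
  }
})

test_that("Kruskal-Wallis exact p matches brute-force enumeration in the no-tie case", {
  d <- group_df(c(1, 2, 3), c(2.1, 3.1, 4), c(10, 11, 12))
  kw <- kruskal_wallis(d)
  expect_equal(kw$method, "exact_enumeration")
  # independent oracle: enumerate all 1680 assignments with combn and the
  # stock kruskal.test statistic
  vals <- d$value
  gfac <- factor(rep(1:3, each = 3))
  hobs <- unname(kruskal.test(d$value, factor(d$group))$statistic)
  cnt <- 0
  ge <- 0
  c1 <- combn(9, 3)
  for (i in seq_len(ncol(c1))) {
    rest <- setdiff(1:9, c1[, i])
    c2 <- combn(rest, 3)
    for (j in seq_len(ncol(c2))) {
      v <- c(vals[c1[, i]], vals[c2[, j]], vals[setdiff(rest, c2[, j])])
      h <- unname(kruskal.test(v, gfac)$statistic)
      cnt <- cnt + 1
      if (h >= hobs - 1e-9) ge <- ge + 1
    }
  }
  expect_lt(abs(kw$p - ge / cnt), 1e-6)
  # large samples fall back to the chi-squared approximation
  set.seed(23)
  big <- group_df(rnorm(20), rnorm(20), rnorm(20))
  kw_big <- kruskal_wallis(big)
  expect_equal(kw_big$method, "chi_squared")
  expect_equal(kw_big$p, kruskal.test(value ~ group, big)$p.value)
})

test_that("two-group Welch ANOVA equals the Welch t-test", {
  set.seed(24)
  d <- group_df(rnorm(8), rnorm(8, 1, 3))
  fit <- route_and_test(d, force_route = "welch_games_howell", quiet = TRUE)
  tt <- t.test(value ~ group, d)
  expect_lt(abs(fit$omnibus$p - tt$p.value), 1e-10)
  expect_lt(abs(fit$omnibus$statistic - tt$statistic^2), 1e-8)
})

test_that("Games-Howell matches an independent reimplementation exactly", {
  set.seed(25)
  d <- group_df(rnorm(12), rnorm(15, 1, 2), rnorm(9, -1, 0.5), rnorm(11, 0.5, 3))
  gh <- games_howell(d)
  orc <- games_howell_oracle(split(d$value, d$group))
  expect_lt(max(abs(gh$p - orc$p)), 1e-10)
  expect_lt(max(abs(gh$statistic - orc$t)), 1e-10)
  expect_lt(max(abs(gh$df - orc$df)), 1e-10)
})

test_that("Games-Howell limits: equal groups give p near 1; equal variances approach Tukey", {
  d_eq <- group_df(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(games_howell(d_eq)$p[1], 0.999)
  set.seed(26)
  d <- group_df(rnorm(30), rnorm(30), rnorm(30))
  gh <- games_howell(d)
  tk <- tukey_posthoc(d)
  expect_lt(max(abs(gh$p - tk$p) / tk$p), 0.05)
  # zero variance in both members of a pair is an explicit error
  expect_error(games_howell(group_df(c(1, 1, 1), c(2, 2, 2))), "zero variance")
})

test_that("Tukey table reproduces stats::TukeyHSD", {
  set.seed(27)
  d <- group_df(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  tk <- tukey_posthoc(d)
  ref <- TukeyHSD(aov(value ~ group, d))$group
  expect_equal(sort(tk$p), sort(unname(ref[, "p adj"])), tolerance = 1e-10)
})

test_that("trimmed Welch F reduces to Welch ANOVA at trim 0 and resists outliers", {
  set.seed(28)
  d <- group_df(rnorm(15), rnorm(15, 0.5), rnorm(15, 1, 2))
  tw0 <- trimmed_welch_f(d, trim = 0)
  ow <- oneway.test(value ~ group, d, var.equal = FALSE)
  expect_equal(tw0$statistic, unname(ow$statistic))
  expect_equal(tw0$p, ow$p.value)
  expect_equal(tw0$df2, unname(ow$parameter[2]))

  # frozen dual-implementation oracle: the same statistic computed by an
  # independent implementation of the trimmed/Winsorized heteroscedastic F
  d_fix <- group_df(
    c(1, 2, 3, 4, 5, 6, 7, 8, 100),
    c(2, 3, 4, 5, 6, 7, 8, 9, 10),
    c(5, 6, 7, 8, 9, 10, 11, 12, 13)
  )
  tw_fix <- trimmed_welch_f(d_fix, trim = 0.2)
  expect_equal(tw_fix$statistic, 3.7482837528604116, tolerance = 1e-10)
  expect_equal(tw_fix$df2, 12, tolerance = 1e-10)
  expect_equal(tw_fix$p, 0.054367395640732785, tolerance = 1e-9)

  # symmetric clean data, large n: trimmed and untrimmed agree in decision
  set.seed(280)
  d_big <- group_df(rnorm(100), rnorm(100, 0.4), rnorm(100, 0.8, 1.5))
  tw_big <- trimmed_welch_f(d_big, trim = 0.2)
  ow_big <- oneway.test(value ~ group, d_big, var.equal = FALSE)
  expect_lt(abs(tw_big$p - ow_big$p.value), 0.05)
  expect_identical(tw_big$p < 0.05, ow_big$p.value < 0.05)

  # one gross outlier: trimmed p barely moves, untrimmed p shifts
  tw <- trimmed_welch_f(d, trim = 0.2)
  d_out <- d
  d_out$value[1] <- 100
  tw_out <- trimmed_welch_f(d_out, trim = 0.2)
  ow_out <- oneway.test(value ~ group, d_out, var.equal = FALSE)
  expect_lt(
    abs(tw_out$p - tw$p),
    abs(ow_out$p.value - ow$p.value)
  )
  expect_error(trimmed_welch_f(group_df(1:3, 1:3), trim = 0.4), "Over-trimming")
})

test_that("Dunn's test handles ties, identical groups, and adjustment dominance", {
  d_same <- group_df(c(1, 2, 3, 4), c(1, 2, 3, 4))
  dn <- dunn_posthoc(d_same)
  expect_equal(dn$statistic, 0)
  expect_equal(dn$p, 1)

  set.seed(29)
  d <- group_df(rnorm(10), rnorm(10), rnorm(10, 8))
  dn2 <- dunn_posthoc(d, adjust = "holm")
  shifted <- dn2$group1 == "c" | dn2$group2 == "c"
  expect_true(all(dn2$p_adj[shifted] < 0.05))
  expect_gt(dn2$p_adj[!shifted], 0.05)

  raw <- dunn_posthoc(d, adjust = "none")
  holm <- dunn_posthoc(d, adjust = "holm")
  bonf <- dunn_posthoc(d, adjust = "bonferroni")
  expect_true(all(bonf$p_adj >= holm$p_adj - 1e-12))
  expect_true(all(holm$p_adj >= raw$p_adj - 1e-12))
  expect_error(dunn_posthoc(group_df(c(1, 1, 1), c(1, 1, 1))), "identical")
})

test_that("routing selects the omnibus/post-hoc pair the gates dictate", {
  set.seed(30)
  d_nh <- group_df(rnorm(40), rnorm(40), rnorm(40)) # normal, homoscedastic
  fit <- route_and_test(d_nh)
  expect_equal(fit$route, "anova_tukey")
  expect_equal(fit$omnibus$test, "one_way_anova")

  set.seed(30)
  d_het <- group_df(rnorm(40, 0, 0.5), rnorm(40, 0, 0.5), rnorm(40, 0, 6))
  fit2 <- route_and_test(d_het)
  expect_equal(fit2$route, "welch_games_howell")

  d_nn <- group_df(rexp(40), rexp(40), rexp(40))
  fit3 <- route_and_test(d_nn)
  expect_false(fit3$gate$normal)
  expect_true(fit3$route %in% c("kruskal_dunn", "trimmed_welch_games_howell"))

  # forcing a route overrides the gates
  fit4 <- route_and_test(d_nh, force_route = "kruskal_dunn")
  expect_match(fit4$omnibus$test, "kruskal")
  expect_named(fit4$posthoc, c("group1", "group2", "statistic", "p", "p_adj"))

  # three groups with identical composition: no route rejects
  d_same <- group_df(1:6, 1:6, 1:6)
  for (r in c("anova_tukey", "welch_games_howell", "kruskal_dunn")) {
    f <- route_and_test(d_same, force_route = r, quiet = TRUE)
    expect_gt(f$omnibus$p, 0.05)
  }
  expect_error(route_and_test(group_df(rnorm(5))), "two groups")
})

test_that("omnibus tests are shift-invariant and rank tests monotone-invariant", {
  set.seed(31)
  d <- group_df(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  d_shift <- d
  d_shift$value <- d$value + 1000
  for (r in c("anova_tukey", "welch_games_howell", "trimmed_welch_games_howell")) {
    f1 <- route_and_test(d, force_route = r, posthoc = FALSE)
    f2 <- route_and_test(d_shift, force_route = r, posthoc = FALSE)
    expect_equal(f1$omnibus$p, f2$omnibus$p, tolerance = 1e-9)
  }
  d_pos <- d
  d_pos$value <- d$value - min(d$value) + 1
  d_mono <- d_pos
  d_mono$value <- log(d_pos$value) # strictly increasing transform
  k1 <- kruskal_wallis(d_pos)
  k2 <- kruskal_wallis(d_mono)
  expect_equal(k1$p, k2$p)
  expect_equal(dunn_posthoc(d_pos)$p, dunn_posthoc(d_mono)$p)
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(32)
  d <- group_df(rnorm(10), rnorm(10, 2), rnorm(10))
  fit <- route_and_test(d)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("group1", "group2", "p", "p_adj") %in% names(td)))
  expect_true(all(td$p_adj >= td$p - 1e-12))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$route, fit$route)
  expect_identical(gl$significant, gl$p < gl$alpha)
})
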