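#' @section Statistical routing:
#' Group comparisons are routed through a 2x2 decision tree. Normality is
#' gated per group by Shapiro-Wilk and equality of variances by Bartlett
#' (when normal) or median-centred Levene / Brown-Forsythe (when not,
#' matching Bartlett's own normality assumption):
#'
#' | normal | homoscedastic | omnibus                       | post hoc      |
#' |--------|---------------|-------------------------------|---------------|
#' | yes    | yes           | one-way ANOVA                 | Tukey HSD     |
#' | yes    | no            | Welch ANOVA                   | Games-Howell  |
#' | no     | yes           | Kruskal-Wallis                | Dunn          |
#' | no     | no            | trimmed/Winsorized Welch F    | Games-Howell  |
#' @noRd
NULL

split_groups <- function(data, value, group) {
  vals <- dplyr::pull(data, {{ value }})
  grps <- dplyr::pull(data, {{ group }})
  ok <- is.finite(vals) & !is.na(grps)
  vals <- vals[ok]
  grps <- factor(grps[ok])
  if (nlevels(grps) < 2) abort("At least two groups are required.")
  split(vals, grps)
}

#' Assumption gates: per-group normality and homoscedasticity
#'
#' Shapiro-Wilk is applied to every group separately (the conservative
#' reading for the small per-group n typical of hydrogel experiments);
#' the data are called normal when every group's p exceeds `alpha`.
#' Variance homogeneity uses Bartlett's test when normal and the
#' median-centred Levene (Brown-Forsythe) test otherwise. Groups of
#' fewer than 8 observations trigger a low-power warning — Shapiro-Wilk
#' cannot reliably detect non-normality at n = 3-6 — but are still
#' gated rather than refused.
#'
#' @param data data frame in long format.
#' @param value,group bare column names of the measurement and the group
#'   label (defaults `value`, `group`).
#' @param alpha gate significance level.
#' @param quiet suppress the low-power warning.
#' @return List: `normal`, `homoscedastic` (logicals), `shapiro` tibble
#'   (per-group W and p), `variance_test` (name, statistic, p), `alpha`.
#' @export
gate_assumptions <- function(data, value = value, group = group,
                             alpha = 0.05, quiet = FALSE) {
  groups <- split_groups(data, {{ value }}, {{ group }})
  ns <- lengths(groups)
  if (any(ns < 3)) {
    abort("Every group needs at least 3 observations for Shapiro-Wilk.")
  }
  if (!quiet && any(ns < 8)) {
    warn("Groups with n < 8: the Shapiro-Wilk normality gate has little power.")
  }
  sw <- purrr::imap(groups, function(x, nm) {
    fit <- shapiro.test(x)
    tibble(group = nm, n = length(x), w = unname(fit$statistic), p = fit$p.value)
  }) |> purrr::list_rbind()
  normal <- all(sw$p > alpha)
  df_long <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ns))
  )
  if (normal) {
    bt <- bartlett.test(value ~ group, data = df_long)
    vt <- list(test = "bartlett", statistic = unname(bt$statistic), p = bt$p.value)
  } else {
    lv <- car::leveneTest(value ~ group, data = df_long, center = median)
    vt <- list(
      test = "levene_median", statistic = lv$`F value`[1], p = lv$`Pr(>F)`[1]
    )
  }
  list(
    normal = normal, homoscedastic = vt$p > alpha,
    shapiro = sw, variance_test = vt, alpha = alpha
  )
}

n_arrangements <- function(ns) {
  exp(lgamma(sum(ns) + 1) - sum(lgamma(ns + 1)))
}

kw_statistic <- function(values, sizes) {
  # values pooled in group blocks of the given sizes; H with tie correction
  n <- length(values)
  r <- rank(values)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(sizes), function(j) {
      sum(r[starts[j]:ends[j]])^2 / sizes[j]
    }, numeric(1))) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h / corr else h
}

kw_exact_p <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  h_obs <- kw_statistic(pooled, sizes)
  r <- rank(pooled)
  n <- length(pooled)
  # enumerate assignments of ranks to groups (choose n1, then n2, ...)
  count <- 0
  ge <- 0
  recurse <- function(avail, remaining_sizes, acc) {
    if (length(remaining_sizes) == 1L) {
      h <- kw_statistic_ranked(c(acc, avail), sizes, n)
      count <<- count + 1
      if (h >= h_obs - 1e-9) ge <<- ge + 1
      return(invisible())
    }
    k <- remaining_sizes[1]
    cmb <- utils::combn(length(avail), k)
    for (ci in seq_len(ncol(cmb))) {
      pick <- cmb[, ci]
      recurse(avail[-pick], remaining_sizes[-1], c(acc, avail[pick]))
    }
  }
  kw_statistic_ranked <- function(rnk, sizes, n) {
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1
    h <- 12 / (n * (n + 1)) *
      sum(vapply(seq_along(sizes), function(j) {
        sum(rnk[starts[j]:ends[j]])^2 / sizes[j]
      }, numeric(1))) - 3 * (n + 1)
    ties <- table(rnk)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (corr > 0) h / corr else h
  }
  recurse(r, sizes, numeric(0))
  ge / count
}

#' Kruskal-Wallis test, exact by enumeration for small untied samples
#'
#' For small samples without ties (at most `exact_limit` distinct
#' assignments of observations to groups) the p-value is computed by
#' exhaustive enumeration of the permutation distribution of the H
#' statistic; otherwise the usual chi-squared approximation
#' ([stats::kruskal.test()]) is used. The `method` field records which.
#'
#' @param data,value,group long-format data as in [gate_assumptions()].
#' @param exact_limit maximum number of arrangements to enumerate.
#' @return List: `statistic` (H), `df`, `p`, `method`.
#' @export
kruskal_wallis <- function(data, value = value, group = group,
                           exact_limit = 100000) {
  groups <- split_groups(data, {{ value }}, {{ group }})
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  h <- kw_statistic(pooled, sizes)
  no_ties <- !any(duplicated(pooled))
  if (no_ties && n_arrangements(sizes) <= exact_limit) {
    p <- kw_exact_p(groups)
    method <- "exact_enumeration"
  } else {
    p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
    method <- "chi_squared"
  }
  list(statistic = h, df = length(groups) - 1, p = p, method = method)
}

winsorize <- function(x, g) {
  if (g == 0) return(x)
  s <- sort(x)
  lo <- s[g + 1]
  hi <- s[length(x) - g]
  pmin(pmax(x, lo), hi)
}

#' Welch-type heteroscedastic F test on trimmed means
#'
#' Welch's ANOVA computed on `trim`-trimmed group means with Winsorized
#' variances and the correspondingly reduced effective sample sizes —
#' the robust omnibus for data that are both non-normal and
#' heteroscedastic. With `trim = 0` the statistic reduces exactly to
#' Welch's ANOVA ([stats::oneway.test()] with `var.equal = FALSE`).
#'
#' @param data,value,group long-format data as in [gate_assumptions()].
#' @param trim fraction trimmed from each tail of each group (default
#'   0.2, the conventional choice); `floor(trim * n)` observations per
#'   tail.
#' @return List: `statistic` (F), `df1`, `df2`, `p`, `trim`.
#' @export
trimmed_welch_f <- function(data, value = value, group = group, trim = 0.2) {
  groups <- split_groups(data, {{ value }}, {{ group }})
  if (trim < 0 || trim >= 0.5) abort("`trim` must be in [0, 0.5).")
  k <- length(groups)
  ns <- lengths(groups)
  gs <- floor(trim * ns)
  hs <- ns - 2 * gs
  if (any(hs < 2)) abort("Over-trimming: fewer than 2 observations would remain in a group.")
  tmeans <- vapply(seq_len(k), function(j) {
    s <- sort(groups[[j]])
    mean(s[(gs[j] + 1):(ns[j] - gs[j])])
  }, numeric(1))
  wvars <- vapply(seq_len(k), function(j) {
    var(winsorize(groups[[j]], gs[j]))
  }, numeric(1))
  d <- (ns - 1) * wvars / (hs * (hs - 1))
  if (any(d <= 0)) abort("A group has zero Winsorized variance.")
  w <- 1 / d
  u <- sum(w)
  xbar <- sum(w * tmeans) / u
  a <- sum(w * (tmeans - xbar)^2) / (k - 1)
  s <- sum((1 - w / u)^2 / (hs - 1))
  b <- 2 * (k - 2) / (k^2 - 1) * s
  f <- a / (1 + b)
  df2 <- 1 / (3 / (k^2 - 1) * s)
  list(
    statistic = f, df1 = k - 1, df2 = df2,
    p = pf(f, k - 1, df2, lower.tail = FALSE), trim = trim
  )
}

pair_labels <- function(n1, n2) paste(n1, "-", n2)

#' Games-Howell pairwise comparisons
#'
#' For each pair of groups the Welch t statistic (unpooled variances,
#' Welch-Satterthwaite degrees of freedom) is referred to the
#' studentized-range distribution with `q = t * sqrt(2)` and the number
#' of groups as the number of means — the standard unequal-variance
#' analogue of Tukey's HSD. The studentized-range p-value is already
#' family-wise adjusted, so `p_adj = p`.
#'
#' @param data,value,group long-format data as in [gate_assumptions()].
#' @return Tibble: `group1`, `group2`, `diff`, `se`, `statistic` (t),
#'   `df`, `p`, `p_adj`.
#' @export
games_howell <- function(data, value = value, group = group) {
  groups <- split_groups(data, {{ value }}, {{ group }})
  k <- length(groups)
  if (any(lengths(groups) < 2)) abort("Every group needs n >= 2.")
  nm <- names(groups)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, var, numeric(1))
  ns <- lengths(groups)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(ci) {
    i <- pairs[1, ci]
    j <- pairs[2, ci]
    vi <- vars[i] / ns[i]
    vj <- vars[j] / ns[j]
    if (vi + vj == 0) {
      abort(sprintf("Groups '%s' and '%s' both have zero variance.", nm[i], nm[j]))
    }
    se <- unname(sqrt(vi + vj))
    t <- unname((means[i] - means[j]) / se)
    df <- unname((vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1)))
    p <- ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    tibble(
      group1 = nm[i], group2 = nm[j], diff = unname(means[i] - means[j]),
      se = se, statistic = t, df = df, p = p, p_adj = p
    )
  })
  purrr::list_rbind(rows)
}

#' Tukey HSD pairwise comparisons
#'
#' Tukey-Kramer studentized-range comparisons on the pooled ANOVA error
#' (matches [stats::TukeyHSD()]); `p_adj = p` since the studentized
#' range is family-wise by construction.
#'
#' @param data,value,group long-format data as in [gate_assumptions()].
#' @return Tibble as in [games_howell()].
#' @export
tukey_posthoc <- function(data, value = value, group = group) {
  groups <- split_groups(data, {{ value }}, {{ group }})
  k <- length(groups)
  nm <- names(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  n <- sum(ns)
  mse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / (n - k)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(ci) {
    i <- pairs[1, ci]
    j <- pairs[2, ci]
    se <- unname(sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j])))
    q <- unname(abs(means[i] - means[j]) / se)
    p <- ptukey(q, nmeans = k, df = n - k, lower.tail = FALSE)
    tibble(
      group1 = nm[i], group2 = nm[j], diff = unname(means[i] - means[j]),
      se = se * sqrt(2), statistic = unname((means[i] - means[j]) / (se * sqrt(2))),
      df = n - k, p = p, p_adj = p
    )
  })
  purrr::list_rbind(rows)
}

#' Dunn's rank-based pairwise comparisons
#'
#' Pairwise z statistics on the pooled Kruskal-Wallis ranks with the tie
#' correction, adjusted for multiplicity by Holm (default), Bonferroni,
#' or left raw.
#'
#' @param data,value,group long-format data as in [gate_assumptions()].
#' @param adjust `"holm"`, `"bonferroni"` or `"none"`.
#' @return Tibble: `group1`, `group2`, `statistic` (z), `p`, `p_adj`.
#' @export
dunn_posthoc <- function(data, value = value, group = group,
                         adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- split_groups(data, {{ value }}, {{ group }})
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    abort("All observations are identical; ranks are fully tied.")
  }
  n <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  rbar <- vapply(seq_along(groups), function(j) mean(r[starts[j]:ends[j]]), numeric(1))
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  nm <- names(groups)
  pairs <- utils::combn(length(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(ci) {
    i <- pairs[1, ci]
    j <- pairs[2, ci]
    se <- unname(sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[i] + 1 / sizes[j])))
    z <- unname((rbar[i] - rbar[j]) / se)
    tibble(
      group1 = nm[i], group2 = nm[j], statistic = z,
      p = 2 * pnorm(abs(z), lower.tail = FALSE)
    )
  })
  out <- purrr::list_rbind(rows)
  out$p_adj <- p.adjust(out$p, method = adjust)
  out
}

#' Route a group comparison through the assumption-gated battery
#'
#' Evaluates the normality and homoscedasticity gates, then runs exactly
#' one omnibus test and its matching post-hoc per the 2x2 routing table:
#' ANOVA + Tukey (normal, homoscedastic), Welch ANOVA + Games-Howell
#' (normal, heteroscedastic), Kruskal-Wallis + Dunn (non-normal,
#' homoscedastic), trimmed/Winsorized Welch F + Games-Howell (non-normal,
#' heteroscedastic). All intermediate statistics are retained in the
#' result. A route can be forced (e.g. to reproduce a published figure's
#' stated test) with `force_route`.
#'
#' @param data,value,group long-format data as in [gate_assumptions()].
#' @param alpha significance level for the gates and for flagging.
#' @param force_route `NULL`, or one of `"anova_tukey"`,
#'   `"welch_games_howell"`, `"kruskal_dunn"`,
#'   `"trimmed_welch_games_howell"`.
#' @param posthoc compute the post-hoc table (set `FALSE` in large
#'   simulations where only the omnibus decision is needed).
#' @param trim trim fraction for the robust route.
#' @param dunn_adjust multiplicity adjustment for Dunn's test.
#' @param quiet suppress the small-n gate warning.
#' @return An object of class `stat_routing_result`; see [tidy()] /
#'   [glance()] methods.
#' @examples
#' d <- data.frame(
#'   group = rep(c("a", "b", "c"), each = 6),
#'   value = c(rnorm(6), rnorm(6), rnorm(6, 2))
#' )
#' fit <- route_and_test(d, quiet = TRUE)
#' glance(fit)
#' @export
route_and_test <- function(data, value = value, group = group, alpha = 0.05,
                           force_route = NULL, posthoc = TRUE, trim = 0.2,
                           dunn_adjust = "holm", quiet = FALSE) {
  gate <- gate_assumptions(data, {{ value }}, {{ group }}, alpha = alpha, quiet = quiet)
  routes <- c("anova_tukey", "welch_games_howell", "kruskal_dunn",
              "trimmed_welch_games_howell")
  route <- if (!is.null(force_route)) {
    match.arg(force_route, routes)
  } else if (gate$normal && gate$homoscedastic) {
    "anova_tukey"
  } else if (gate$normal && !gate$homoscedastic) {
    "welch_games_howell"
  } else if (!gate$normal && gate$homoscedastic) {
    "kruskal_dunn"
  } else {
    "trimmed_welch_games_howell"
  }
  df_long <- data.frame(
    value = dplyr::pull(data, {{ value }}),
    group = factor(dplyr::pull(data, {{ group }}))
  )
  omnibus <- switch(route,
    anova_tukey = {
      ow <- oneway.test(value ~ group, data = df_long, var.equal = TRUE)
      list(
        test = "one_way_anova", statistic = unname(ow$statistic),
        df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
        p = ow$p.value
      )
    },
    welch_games_howell = {
      ow <- oneway.test(value ~ group, data = df_long, var.equal = FALSE)
      list(
        test = "welch_anova", statistic = unname(ow$statistic),
        df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]),
        p = ow$p.value
      )
    },
    kruskal_dunn = {
      kw <- kruskal_wallis(df_long)
      list(
        test = paste0("kruskal_wallis_", kw$method), statistic = kw$statistic,
        df1 = kw$df, df2 = NA_real_, p = kw$p
      )
    },
    trimmed_welch_games_howell = {
      tw <- trimmed_welch_f(df_long, trim = trim)
      list(
        test = "trimmed_welch_f", statistic = tw$statistic,
        df1 = tw$df1, df2 = tw$df2, p = tw$p
      )
    }
  )
  ph <- NULL
  if (posthoc) {
    ph <- switch(route,
      anova_tukey = tukey_posthoc(df_long),
      welch_games_howell = games_howell(df_long),
      kruskal_dunn = dunn_posthoc(df_long, adjust = dunn_adjust),
      trimmed_welch_games_howell = games_howell(df_long)
    )
  }
  structure(
    list(
      gate = gate, route = route, omnibus = omnibus, posthoc = ph,
      alpha = alpha, group_sizes = table(df_long$group)
    ),
    class = "stat_routing_result"
  )
}

#' @export
print.stat_routing_result <- function(x, ...) {
  cat(sprintf(
    "<stat_routing_result> route: %s (normal=%s, homoscedastic=%s)\n",
    x$route, x$gate$normal, x$gate$homoscedastic
  ))
  cat(sprintf(
    "  omnibus %s: statistic = %.4g, p = %.4g (alpha = %g)\n",
    x$omnibus$test, x$omnibus$statistic, x$omnibus$p, x$alpha
  ))
  if (!is.null(x$posthoc)) {
    cat(sprintf(
      "  post hoc: %d pairwise comparisons, %d with p_adj < alpha\n",
      nrow(x$posthoc), sum(x$posthoc$p_adj < x$alpha)
    ))
  }
  invisible(x)
}

#' @rdname route_and_test
#' @param x a `stat_routing_result`.
#' @param ... unused.
#' @export
tidy.stat_routing_result <- function(x, ...) {
  if (is.null(x$posthoc)) {
    return(tibble(
      group1 = character(0), group2 = character(0),
      statistic = numeric(0), p = numeric(0), p_adj = numeric(0)
    ))
  }
  x$posthoc
}

#' @rdname route_and_test
#' @export
glance.stat_routing_result <- function(x, ...) {
  tibble(
    route = x$route,
    normal = x$gate$normal,
    homoscedastic = x$gate$homoscedastic,
    variance_test = x$gate$variance_test$test,
    omnibus = x$omnibus$test,
    statistic = x$omnibus$statistic,
    df1 = x$omnibus$df1,
    df2 = x$omnibus$df2,
    p = x$omnibus$p,
    alpha = x$alpha,
    significant = x$omnibus$p < x$alpha
  )
}

#' Empirical type-I error of the routed procedure under the null
#'
#' Simulates `n_sims` experiments of `k` standard-normal groups of size
#' `n` and reports the fraction in which the routed omnibus rejects at
#' `alpha`. A correctly calibrated battery stays near `alpha`.
#'
#' @param n_sims number of simulated experiments.
#' @param k number of groups.
#' @param n observations per group.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return Rejection rate (scalar).
#' @export
simulate_null_rejection_rate <- function(n_sims = 2000, k = 3, n = 6,
                                         alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    rej <- logical(n_sims)
    g <- factor(rep(seq_len(k), each = n))
    for (s in seq_len(n_sims)) {
      d <- data.frame(value = rnorm(k * n), group = g)
      fit <- route_and_test(d, alpha = alpha, posthoc = FALSE, quiet = TRUE)
      rej[s] <- fit$omnibus$p < alpha
    }
    mean(rej)
  })
}
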