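#' Group summary table
#'
#' Per-group mean, SD and n for one outcome, as printed in cohort
#' summary tables. Serves as the summary-mode input to the ANOVA and
#' post-hoc routines, so published group summaries can be analysed
#' without subject-level data.
#'
#' @param group character vector of group labels.
#' @param mean,sd numeric vectors of group means and standard deviations.
#' @param n integer vector of group sizes (each >= 2).
#' @return object of class `group_summary` (a data frame).
#' @export
group_summary <- function(group, mean, sd, n) {
  if (any(n < 2)) stop("every group needs n >= 2 (variance undefined)")
  if (any(sd < 0)) stop("standard deviations must be non-negative")
  if (anyDuplicated(group)) stop("duplicate group labels")
  structure(data.frame(group = as.character(group), mean = mean, sd = sd,
                       n = as.integer(n), stringsAsFactors = FALSE),
            class = c("group_summary", "data.frame"))
}

#' Summarize a cohort table outcome by group
#'
#' Complete-case per-outcome summary (subjects missing the outcome are
#' dropped for that outcome only).
#'
#' @param table cohort data frame with a `group` column.
#' @param outcome outcome column name.
#' @return a [group_summary()].
#' @export
summarize_groups <- function(table, outcome) {
  stopifnot(outcome %in% names(table), "group" %in% names(table))
  ok <- !is.na(table[[outcome]])
  sp <- split(table[[outcome]][ok], as.character(table$group[ok]))
  if (any(lengths(sp) < 2))
    stop(sprintf("outcome '%s': every group needs n >= 2", outcome))
  group_summary(names(sp), vapply(sp, mean, 0), vapply(sp, sd, 0),
                lengths(sp))
}

#' One-way between-group ANOVA
#'
#' From raw per-subject values (via [stats::aov()]) or, equivalently,
#' from printed group summaries via the pooled within-group sum of
#' squares. The two input modes yield identical F statistics.
#'
#' @param data a cohort data frame with a `group` column, or a
#'   [group_summary()].
#' @param outcome outcome column name (raw mode only).
#' @return list with `F`, `df` (numerator, denominator) and `p`.
#' @export
one_way_anova <- function(data, outcome = NULL) {
  if (inherits(data, "group_summary")) {
    k <- nrow(data)
    if (k < 2) stop("need at least 2 groups")
    if (any(data$n < 2)) stop("every group needs n >= 2")
    n_tot <- sum(data$n)
    grand <- sum(data$n * data$mean) / n_tot
    ssb <- sum(data$n * (data$mean - grand)^2)
    ssw <- sum((data$n - 1) * data$sd^2)
    f <- (ssb / (k - 1)) / (ssw / (n_tot - k))
    return(list(F = f, df = c(k - 1, n_tot - k),
                p = pf(f, k - 1, n_tot - k, lower.tail = FALSE)))
  }
  stopifnot(!is.null(outcome))
  ok <- !is.na(data[[outcome]])
  y <- data[[outcome]][ok]
  g <- factor(as.character(data$group[ok]))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  fit <- summary(aov(y ~ g))[[1]]
  list(F = fit$`F value`[1], df = c(fit$Df[1], fit$Df[2]),
       p = fit$`Pr(>F)`[1])
}

posthoc_result <- function(pair, diff, ci, p, method) {
  data.frame(group1 = pair[1], group2 = pair[2], mean_difference = diff,
             ci_low = ci[1], ci_high = ci[2], p_adjusted = min(1, p),
             method = method, stringsAsFactors = FALSE)
}

#' Post-hoc contrast from group summaries
#'
#' Pairwise contrast of a one-way design computed from group means, SDs
#' and sizes alone. `mean_difference` is `mean(group2) - mean(group1)`.
#' Tukey-Kramer uses the studentized-range quantile with the mean square
#' error pooled over all `k` groups; Games-Howell uses per-pair variances
#' with Welch degrees of freedom (for unequal group variances).
#'
#' @param summary a [group_summary()] covering all groups of the design.
#' @param pair character pair `c(group1, group2)`.
#' @param method `"tukey_kramer"` or `"games_howell"`.
#' @param conf_level simultaneous confidence level (default 0.95).
#' @return one-row data frame: pair, `mean_difference`, adjusted
#'   `ci_low`/`ci_high`, `p_adjusted`, `method`.
#' @export
posthoc_from_summary <- function(summary, pair,
                                 method = c("tukey_kramer", "games_howell"),
                                 conf_level = 0.95) {
  if (length(method) == 1 && !method %in% c("tukey_kramer", "games_howell"))
    stop(sprintf("unknown post-hoc method '%s'", method))
  method <- match.arg(method)
  stopifnot(inherits(summary, "group_summary"))
  i <- match(pair, summary$group)
  if (anyNA(i)) stop("pair contains a group absent from the summary")
  k <- nrow(summary)
  m <- summary$mean[i]; s <- summary$sd[i]; n <- summary$n[i]
  diff <- m[2] - m[1]
  if (method == "tukey_kramer") {
    mse <- sum((summary$n - 1) * summary$sd^2) / (sum(summary$n) - k)
    se <- sqrt(mse / 2 * (1 / n[1] + 1 / n[2]))
    df <- sum(summary$n) - k
  } else {
    v <- s^2 / n
    se <- sqrt(sum(v) / 2)
    df <- sum(v)^2 / (v[1]^2 / (n[1] - 1) + v[2]^2 / (n[2] - 1))
  }
  qcrit <- qtukey(conf_level, k, df)
  p <- ptukey(abs(diff) / se, k, df, lower.tail = FALSE)
  posthoc_result(pair, diff, diff + c(-1, 1) * qcrit * se, p, method)
}

welch_pair <- function(m, s, n, conf_level) {
  v <- s^2 / n
  se <- sqrt(sum(v))
  df <- sum(v)^2 / (v[1]^2 / (n[1] - 1) + v[2]^2 / (n[2] - 1))
  diff <- m[2] - m[1]
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  list(diff = diff, ci = diff + c(-1, 1) * tcrit * se,
       p = 2 * pt(abs(diff) / se, df, lower.tail = FALSE))
}

#' All pairwise post-hoc contrasts of a one-way design
#'
#' Convenience wrapper over [posthoc_from_summary()] for every group
#' pair. `method = "bh"` runs Welch t tests per pair and applies the
#' Benjamini-Hochberg step-up adjustment across the pairs (confidence
#' intervals stay per-pair Welch intervals).
#'
#' @param summary a [group_summary()].
#' @param method `"tukey_kramer"`, `"games_howell"` or `"bh"`.
#' @param conf_level confidence level.
#' @return data frame with one row per pair.
#' @export
posthoc_all_pairs <- function(summary, method = "tukey_kramer",
                              conf_level = 0.95) {
  stopifnot(inherits(summary, "group_summary"))
  pairs <- utils::combn(summary$group, 2, simplify = FALSE)
  if (method == "bh") {
    rows <- lapply(pairs, function(p) {
      i <- match(p, summary$group)
      w <- welch_pair(summary$mean[i], summary$sd[i], summary$n[i],
                      conf_level)
      posthoc_result(p, w$diff, w$ci, w$p, "bh")
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- p.adjust(out$p_adjusted, method = "BH")
    return(out)
  }
  do.call(rbind, lapply(pairs, function(p)
    posthoc_from_summary(summary, p, method, conf_level)))
}

side_cols <- function(outcome) paste0(outcome, c("_nonaff", "_aff"))

#' Mixed (split-plot) ANOVA: group by lung side
#'
#' Two-way repeated-measures ANOVA with a between-subject factor (group)
#' and a within-subject factor (lung side, affected vs non-affected),
#' including their interaction. Subjects missing either side value are
#' dropped with a message. Sums of squares follow the standard
#' mixed-design partitioning (between-subject error for the group effect,
#' within-subject error for side and interaction).
#'
#' @param table cohort data frame with columns `id`, `group` and
#'   `<outcome>_aff` / `<outcome>_nonaff`.
#' @param outcome base name of the per-side outcome (e.g. `"vdp"`).
#' @return data frame with rows `group`, `side`, `group:side` and columns
#'   `F`, `df1`, `df2`, `p`.
#' @export
mixed_anova_group_side <- function(table, outcome) {
  sc <- side_cols(outcome)
  stopifnot(all(sc %in% names(table)))
  ok <- complete.cases(table[, sc])
  if (any(!ok))
    message(sprintf("%d subjects dropped (missing a side value)", sum(!ok)))
  tab <- table[ok, , drop = FALSE]
  orig_groups <- unique(as.character(table$group))
  counts <- table(factor(as.character(tab$group), levels = orig_groups))
  if (any(counts < 2))
    stop("fewer than 2 complete subjects in a group")
  long <- data.frame(
    id = factor(rep(tab$id, 2L)),
    group = factor(rep(as.character(tab$group), 2L)),
    side = factor(rep(c("non_affected", "affected"), each = nrow(tab)),
                  levels = c("non_affected", "affected")),
    value = c(tab[[sc[1]]], tab[[sc[2]]]))
  fit <- aov(value ~ group * side + Error(id), data = long)
  sm <- summary(fit)
  between <- sm[["Error: id"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  total_ss <- sum(between$`Sum Sq`) + sum(within$`Sum Sq`)
  eff <- function(stratum, row) {
    i <- match(row, trimws(rownames(stratum)))
    r <- match("Residuals", trimws(rownames(stratum)))
    f <- stratum$`F value`[i]
    p <- stratum$`Pr(>F)`[i]
    # a numerically null effect (e.g. identical side values) is reported
    # as F = 0 rather than as a 0/0 ratio of round-off sums of squares
    if (stratum$`Sum Sq`[i] <= 1e-12 * max(total_ss, 1)) {
      f <- 0; p <- 1
    }
    data.frame(effect = row, F = f, df1 = stratum$Df[i],
               df2 = stratum$Df[r], p = p, stringsAsFactors = FALSE)
  }
  rbind(eff(between, "group"), eff(within, "side"),
        eff(within, "group:side"))
}

#' Bonferroni-adjusted side contrasts per group
#'
#' Paired t-based difference (affected minus non-affected) within each
#' group, with the confidence level and p value Bonferroni-adjusted for
#' the number of groups tested. Groups with fewer than 2 complete pairs
#' are skipped with a warning. A group with zero within-pair variance is
#' reported with a degenerate interval.
#'
#' @param table cohort data frame (see [mixed_anova_group_side()]).
#' @param outcome base name of the per-side outcome.
#' @param alpha nominal family significance level (default 0.05).
#' @return data frame with one row per group: `mean_difference`, adjusted
#'   `ci_low`/`ci_high`, `p_adjusted`, `n`.
#' @export
bonferroni_side_posthoc <- function(table, outcome, alpha = 0.05) {
  sc <- side_cols(outcome)
  stopifnot(all(sc %in% names(table)))
  sp <- split(table[, sc], as.character(table$group))
  sp <- lapply(sp, function(d) d[complete.cases(d), , drop = FALSE])
  usable <- vapply(sp, nrow, 0L) >= 2L
  if (any(!usable))
    warning(sprintf("groups skipped (< 2 complete pairs): %s",
                    paste(names(sp)[!usable], collapse = ", ")))
  sp <- sp[usable]
  k <- length(sp)
  if (k == 0L) stop("no group with >= 2 complete pairs")
  rows <- lapply(names(sp), function(g) {
    d <- sp[[g]][[sc[2]]] - sp[[g]][[sc[1]]]
    n <- length(d)
    m <- mean(d); s <- sd(d)
    if (s == 0) {
      ci <- c(m, m)
      p_raw <- if (m == 0) 1 else 0
    } else {
      se <- s / sqrt(n)
      tcrit <- qt(1 - alpha / k / 2, n - 1)
      ci <- m + c(-1, 1) * tcrit * se
      p_raw <- 2 * pt(abs(m) / se, n - 1, lower.tail = FALSE)
    }
    data.frame(group = g, mean_difference = m, ci_low = ci[1],
               ci_high = ci[2], p_adjusted = min(1, k * p_raw), n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation screen with Benjamini-Hochberg adjustment
#'
#' Rank correlations (mid-ranks for ties) between every `x` and `y`
#' outcome pair, complete-case per pair, with the Benjamini-Hochberg
#' step-up procedure applied over the full matrix of tests. Pairs with a
#' constant column or fewer than `min_n` complete observations are
#' reported as missing with a warning.
#'
#' @param table cohort data frame.
#' @param x_outcomes,y_outcomes column names to correlate.
#' @param min_n minimum complete pairs per cell (default 4).
#' @return data frame with columns `x`, `y`, `n`, `rho`, `p`,
#'   `p_adjusted`.
#' @export
spearman_bh <- function(table, x_outcomes, y_outcomes, min_n = 4) {
  stopifnot(all(c(x_outcomes, y_outcomes) %in% names(table)))
  grid <- expand.grid(x = x_outcomes, y = y_outcomes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- table[[grid$x[i]]]; y <- table[[grid$y[i]]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_n) {
      warning(sprintf("'%s' vs '%s': fewer than %d complete pairs",
                      grid$x[i], grid$y[i], min_n))
      return(data.frame(x = grid$x[i], y = grid$y[i], n = length(x),
                        rho = NA_real_, p = NA_real_))
    }
    if (sd(x) == 0 || sd(y) == 0) {
      warning(sprintf("'%s' vs '%s': constant column, rho undefined",
                      grid$x[i], grid$y[i]))
      return(data.frame(x = grid$x[i], y = grid$y[i], n = length(x),
                        rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    data.frame(x = grid$x[i], y = grid$y[i], n = length(x),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p)
  out$p_adjusted[ok] <- p.adjust(out$p[ok], method = "BH")
  out
}

#' Default post-hoc method per outcome
#'
#' Mapping used by [run_cohort()]: Tukey-Kramer for most lung-function
#' and imaging outcomes, Games-Howell for the outcomes with markedly
#' unequal group variances (FEV1/FVC ratio, VDP), Benjamini-Hochberg
#' Welch contrasts for the defect distribution indices. Overridable.
#'
#' @return named character vector keyed by outcome column.
#' @export
default_posthoc_methods <- function() {
  c(fev1_z = "tukey_kramer", fvc_z = "tukey_kramer",
    fev1_fvc_pct = "games_howell", tlc_z = "tukey_kramer",
    rv_tlc_pct = "tukey_kramer", lci2_5_TO = "tukey_kramer",
    vdp_pct = "games_howell", qdp_pct = "tukey_kramer",
    vqd_pct = "tukey_kramer", ddi_v = "bh", ddi_q = "bh")
}
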