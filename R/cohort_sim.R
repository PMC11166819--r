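#' Reference cohort summary statistics
#'
#' Published group summaries (mean, SD, n per group) of lung function and
#' functional-MRI outcomes for school-aged children after congenital
#' diaphragmatic hernia repair (small and large initial defect) and
#' age/sex-matched healthy controls. `"overall"` gives whole-lung
#' outcomes; `"side"` gives the per-lung-side imaging outcomes (affected
#' vs non-affected side; left vs right in controls). These tables serve
#' both as summary-mode statistics input and as default parameters for
#' [generate_cohort_table()].
#'
#' @param type `"overall"` or `"side"`.
#' @return data frame.
#' @export
reference_cohort_summaries <- function(type = c("overall", "side")) {
  type <- match.arg(type)
  file <- if (type == "overall") "cohort_reference_summaries.csv"
  else "cohort_reference_side_summaries.csv"
  read.csv(system.file("extdata", file, package = "mplung",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Cohort simulation configuration
#'
#' @param overall data frame `(group, outcome, mean, sd, n)` of whole-lung
#'   outcome parameters; defaults to
#'   `reference_cohort_summaries("overall")`.
#' @param side data frame `(group, outcome, side, mean, sd, n)` of
#'   per-side outcome parameters; defaults to
#'   `reference_cohort_summaries("side")`.
#' @param n named integer vector of group sizes (each >= 2); defaults to
#'   the sizes carried by `overall`.
#' @param side_corr within-subject correlation between the two side
#'   values, in `[-1, 1]`.
#' @param seed integer seed.
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(overall = reference_cohort_summaries("overall"),
                              side = reference_cohort_summaries("side"),
                              n = NULL, side_corr = 0.3, seed = 1L) {
  if (any(overall$sd < 0) || any(side$sd < 0))
    stop_config("sd", "standard deviations must be non-negative")
  if (is.null(n)) {
    n <- tapply(overall$n, overall$group, max)
    n <- setNames(as.integer(n), names(n))
  }
  if (any(n < 2)) stop_config("n", "need n >= 2 per group")
  if (!is.numeric(side_corr) || abs(side_corr) > 1)
    stop_config("side_corr", "must lie in [-1, 1]")
  structure(list(overall = overall, side = side, n = n,
                 side_corr = side_corr, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a cohort table
#'
#' Draws per-subject outcomes from group-specific normal distributions
#' (whole-lung outcomes independently; the two side values of each
#' per-side outcome from a bivariate normal with the configured
#' within-subject correlation). Group labels are control / small_CDH /
#' large_CDH; within each patient group one subject gets a right-sided
#' hernia and the rest left-sided (the predominant pattern in this
#' population); controls carry no hernia side. Deterministic for a fixed
#' seed.
#'
#' @param config a [cohort_sim_config()].
#' @return cohort data frame, one row per subject: `id`, `group`,
#'   `hernia_side`, whole-lung outcome columns, and `<outcome>_nonaff` /
#'   `<outcome>_aff` side columns.
#' @export
generate_cohort_table <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    groups <- names(config$n)
    rows <- list()
    for (g in groups) {
      ng <- config$n[[g]]
      df <- data.frame(id = sprintf("%s_%02d", g, seq_len(ng)),
                       group = g, stringsAsFactors = FALSE)
      df$hernia_side <- if (g == "control") NA_character_
      else c("right", rep("left", ng - 1L))
      ov <- config$overall[config$overall$group == g, , drop = FALSE]
      for (i in seq_len(nrow(ov)))
        df[[ov$outcome[i]]] <- rnorm(ng, ov$mean[i], ov$sd[i])
      sd_tab <- config$side[config$side$group == g, , drop = FALSE]
      for (oc in unique(sd_tab$outcome)) {
        p_non <- sd_tab[sd_tab$outcome == oc & sd_tab$side == "nonaff", ]
        p_aff <- sd_tab[sd_tab$outcome == oc & sd_tab$side == "aff", ]
        z1 <- rnorm(ng)
        z2 <- config$side_corr * z1 +
          sqrt(1 - config$side_corr^2) * rnorm(ng)
        df[[paste0(oc, "_nonaff")]] <- p_non$mean + p_non$sd * z1
        df[[paste0(oc, "_aff")]] <- p_aff$mean + p_aff$sd * z2
      }
      rows[[g]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
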