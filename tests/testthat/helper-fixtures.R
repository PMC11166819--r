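# Small phantom configurations used across tests: quarter-size grid and a
# short series keep per-test runtime low while preserving every signal
# feature (two lung sides, heart region, smooth amplitude fields).
small_phantom_config <- function(...) {
  args <- list(grid = c(48, 48), n_slices = 4, n_frames = 100)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

# Dice overlap of two logical masks
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Raw per-group samples with exact mean and SD, for summary/raw
# cross-checks against stats:: reference implementations.
exact_group_data <- function(means, sds, ns, groups = names(means)) {
  do.call(rbind, lapply(seq_along(means), function(i) {
    z <- scale(rnorm(ns[i]))  # mean 0, sd 1 exactly
    data.frame(group = groups[i], y = means[i] + sds[i] * as.numeric(z))
  }))
}

# Group summary for one outcome of the bundled reference table
reference_summary_for <- function(outcome) {
  ov <- reference_cohort_summaries("overall")
  s <- ov[ov$outcome == outcome, ]
  group_summary(s$group, s$mean, s$sd, s$n)
}
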