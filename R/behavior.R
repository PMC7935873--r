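# Behavioural statistics: performance indices from per-frame occupancy
# counts, estimation statistics (BCa bootstrap effect sizes with
# Mann-Whitney p-values) and precision/power planning.

#' Half performance index from one occupancy trace
#'
#' Per frame f in the final `window_seconds` of the trace,
#' `s_f = 0.5 * (n_uncond - n_cond) / (n_uncond + n_cond)` (frames with no
#' flies in either zone are skipped); the half PI is the mean of the
#' retained frames and lies in \[-0.5, +0.5\].
#'
#' @param trace data.frame for a single unit/trial with columns `frame`,
#'   `n_conditioned_side`, `n_unconditioned_side`.
#' @param fps video frames per second.
#' @param window_seconds scored window at the end of the trace.
#' @return half PI.
#' @export
halfPI <- function(trace, fps, window_seconds = 30) {
  nf <- as.integer(round(fps * window_seconds))
  trace <- trace[order(trace$frame), , drop = FALSE]
  if (nrow(trace) < nf) stop("trace shorter than the scoring window")
  win <- trace[(nrow(trace) - nf + 1L):nrow(trace), , drop = FALSE]
  tot <- win$n_unconditioned_side + win$n_conditioned_side
  keep <- tot > 0
  if (!any(keep)) stop("no frames with flies in the scoring window")
  s <- 0.5 * (win$n_unconditioned_side[keep] - win$n_conditioned_side[keep]) /
    tot[keep]
  mean(s)
}

#' Full performance index
#'
#' The sum of the two reciprocal half PIs (OCT- and MCH-conditioned),
#' so unconditioned odor bias cancels; range \[-1, +1\].
#'
#' @param half_oct,half_mch half PIs of the reciprocal trials.
#' @return full PI.
#' @export
fullPI <- function(half_oct, half_mch) half_oct + half_mch

#' Performance indices for every unit in a trace table
#'
#' @param traces occupancy table (columns unit, trial_odor, frame,
#'   n_conditioned_side, n_unconditioned_side), e.g. from
#'   [simulateBehavior()].
#' @param fps frames per second.
#' @param window_seconds scored window.
#' @return data.frame: unit, half_pi_oct, half_pi_mch, full_pi.
#' @export
performanceIndices <- function(traces, fps, window_seconds = 30) {
  units <- sort(unique(traces$unit))
  res <- lapply(units, function(u) {
    oct <- traces[traces$unit == u & traces$trial_odor == "OCT", ]
    mch <- traces[traces$unit == u & traces$trial_odor == "MCH", ]
    ho <- halfPI(oct, fps, window_seconds)
    hm <- halfPI(mch, fps, window_seconds)
    data.frame(unit = u, half_pi_oct = ho, half_pi_mch = hm,
               full_pi = fullPI(ho, hm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Two-tailed Mann-Whitney p-value
#'
#' Exact (no ties, both groups of size at most 8) or continuity-corrected
#' normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return two-tailed p-value.
#' @export
mannWhitneyP <- function(x, y) {
  exact <- length(x) <= 8L && length(y) <= 8L &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

#' Estimation-statistics effect size for two PI groups
#'
#' Mean difference (test minus control) with a seeded bootstrap 95%
#' confidence interval — bias-corrected and accelerated (BCa) by default,
#' percentile by flag — and a two-tailed Mann-Whitney p-value reported
#' alongside.
#'
#' @param test_pis,control_pis full-PI vectors (each of length at least 2).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level.
#' @param method `"bca"` or `"percentile"`.
#' @return data.frame: delta_pi, ci_low, ci_high, p_mw, n_test, n_control.
#' @export
effectSize <- function(test_pis, control_pis, n_boot = 5000L, seed = 1L,
                       conf = 0.95, method = c("bca", "percentile")) {
  method <- match.arg(method)
  nt <- length(test_pis); nc <- length(control_pis)
  if (nt < 2L || nc < 2L) stop("both groups need at least 2 values")
  delta <- mean(test_pis) - mean(control_pis)
  boot <- withr::with_seed(seed, {
    bt <- matrix(sample(test_pis, nt * n_boot, replace = TRUE), ncol = n_boot)
    bc <- matrix(sample(control_pis, nc * n_boot, replace = TRUE),
                 ncol = n_boot)
    colMeans(bt) - colMeans(bc)
  })
  alpha <- (1 - conf) / 2
  if (method == "percentile") {
    ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  } else {
    # BCa: bias correction from the bootstrap distribution, acceleration
    # from a leave-one-out jackknife over all observations
    prop <- mean(boot < delta)
    prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
    z0 <- qnorm(prop)
    jack <- c(
      vapply(seq_len(nt), function(i)
        mean(test_pis[-i]) - mean(control_pis), numeric(1)),
      vapply(seq_len(nc), function(i)
        mean(test_pis) - mean(control_pis[-i]), numeric(1)))
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * sum((jm - jack)^2)^1.5
    a <- if (den == 0) 0 else num / den
    zl <- qnorm(alpha); zh <- qnorm(1 - alpha)
    p1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    p2 <- pnorm(z0 + (z0 + zh) / (1 - a * (z0 + zh)))
    ci <- unname(quantile(boot, c(p1, p2), type = 7))
  }
  data.frame(delta_pi = delta, ci_low = ci[1], ci_high = ci[2],
             p_mw = mannWhitneyP(test_pis, control_pis),
             n_test = nt, n_control = nc, stringsAsFactors = FALSE)
}

#' Margin of error for a standardized two-group mean difference
#'
#' Large-sample half-width of the `1 - alpha` confidence interval of a
#' standardized mean difference at equal group sizes:
#' `z_{1-alpha/2} * sqrt(2/n)`.
#'
#' @param n per-group sample size.
#' @param alpha significance level.
#' @return margin of error in SD units.
#' @export
marginOfError <- function(n, alpha = 0.05) {
  if (n < 2L) stop("n must be at least 2")
  qnorm(1 - alpha / 2) * sqrt(2 / n)
}

#' Power of a two-sided two-group comparison
#'
#' Analytic: the large-sample normal approximation including both
#' rejection tails, `Phi(d*sqrt(n/2) - z) + Phi(-d*sqrt(n/2) - z)` with
#' `z = z_{1-alpha/2}`, so the power at `d = 0` equals the level exactly.
#' Simulated: the fraction of seeded replicates of two Normal groups
#' shifted by `d` SD that reject at `alpha` with the chosen test.
#'
#' @param n per-group sample size.
#' @param d standardized effect size (difference in SD units).
#' @param alpha significance level.
#' @param method `"analytic"` or `"simulate"`.
#' @param test test used in simulation: pooled two-sample t or
#'   Mann-Whitney.
#' @param n_sims simulation replicates.
#' @param seed integer seed.
#' @return power in \[0, 1\].
#' @export
powerTwoGroup <- function(n, d, alpha = 0.05,
                          method = c("analytic", "simulate"),
                          test = c("t", "mann_whitney"),
                          n_sims = 10000L, seed = 1L) {
  method <- match.arg(method)
  test <- match.arg(test)
  if (method == "analytic") {
    z <- qnorm(1 - alpha / 2)
    shift <- d * sqrt(n / 2)
    return(pnorm(shift - z) + pnorm(-shift - z))
  }
  withr::with_seed(seed, {
    if (test == "t") {
      x <- matrix(rnorm(n * n_sims), nrow = n)
      y <- matrix(rnorm(n * n_sims, mean = d), nrow = n)
      mx <- colMeans(x); my <- colMeans(y)
      vx <- colSums((x - rep(mx, each = n))^2) / (n - 1)
      vy <- colSums((y - rep(my, each = n))^2) / (n - 1)
      tstat <- (my - mx) / sqrt((vx + vy) / n)
      crit <- qt(1 - alpha / 2, df = 2 * n - 2)
      mean(abs(tstat) > crit)
    } else {
      rej <- vapply(seq_len(n_sims), function(i) {
        x <- rnorm(n); y <- rnorm(n, mean = d)
        mannWhitneyP(y, x) < alpha
      }, logical(1))
      mean(rej)
    }
  })
}
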