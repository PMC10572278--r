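# Shared result-row builder: every method reports the Tables-style columns
# (method, #SNPs, beta, se, p) plus the odds-ratio scale via effect_transform.
.mr_result_row <- function(method, n_snps, beta, se, p, model = NA_character_,
                           intercept = NA_real_, intercept_se = NA_real_,
                           intercept_p = NA_real_) {
  es <- if (is.finite(se) && se > 0) effect_transform(beta, se) else
    tibble(odds_ratio = exp(beta), ci_low = NA_real_, ci_high = NA_real_)
  tibble(
    method = method, n_snps = as.integer(n_snps),
    beta = beta, se = se, p = p,
    odds_ratio = es$odds_ratio, ci_low = es$ci_low, ci_high = es$ci_high,
    model = model,
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = intercept_p
  )
}

.check_instruments <- function(instruments, min_n, method, hint = NULL) {
  n <- nrow(instruments)
  if (n < min_n) {
    stop_degenerate("%s requires at least %d instruments (got %d)%s",
                    method, min_n, n,
                    if (is.null(hint)) "" else paste0("; ", hint))
  }
  if (any(instruments$se_Gamma <= 0) || any(instruments$se_gamma <= 0)) {
    stop_domain("instrument standard errors must be positive")
  }
  invisible(n)
}

#' Per-variant Wald ratio estimates
#'
#' The per-instrument causal estimate is the ratio of the outcome to the
#' exposure effect, `beta_j = Gamma_j / gamma_j`, with first-order
#' delta-method standard error `se_j = se_Gamma_j / |gamma_j|` and a
#' two-sided normal p-value. Instruments with a zero exposure effect are
#' dropped with a diagnostic.
#'
#' @param instruments Harmonized-instrument tibble.
#' @param second_order When `TRUE`, use the second-order delta variance
#'   `se_Gamma^2/gamma^2 + Gamma^2 se_gamma^2 / gamma^4`.
#' @return A tibble with `variant_id`, `ratio`, `se`, `p`.
#' @export
wald_ratios <- function(instruments, second_order = FALSE) {
  zero <- instruments$gamma == 0
  if (any(zero)) {
    warn(sprintf("dropping %d instrument(s) with zero exposure effect: %s",
                 sum(zero),
                 paste(instruments$variant_id[zero], collapse = ", ")))
    instruments <- instruments[!zero, , drop = FALSE]
  }
  ratio <- instruments$Gamma / instruments$gamma
  v <- instruments$se_Gamma^2 / instruments$gamma^2
  if (second_order) {
    v <- v + instruments$Gamma^2 * instruments$se_gamma^2 / instruments$gamma^4
  }
  se <- sqrt(v)
  tibble(
    variant_id = instruments$variant_id,
    ratio = ratio, se = se,
    p = 2 * pnorm(-abs(ratio / se))
  )
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of the outcome effects on the exposure effects
#' through the origin, with weights `1/se_Gamma^2` — equivalently the
#' inverse-variance weighted meta-analysis of the per-variant Wald ratios.
#' Under the fixed-effect model the standard error is
#' `1/sqrt(sum(gamma^2 * w))`; the multiplicative random-effects model
#' (default) scales it by the residual standard deviation when that
#' exceeds 1 (inflation only, never deflation), which absorbs balanced
#' pleiotropy in excess of the sampling variance.
#'
#' @param instruments Harmonized-instrument tibble (at least 2 rows).
#' @param model `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return A one-row MR-result tibble; see [mr_run_all()].
#' @export
mr_ivw <- function(instruments, model = c("mre", "fixed")) {
  model <- match.arg(model)
  n <- .check_instruments(instruments, 2, "IVW",
                          "use the Wald ratio for a single instrument")
  g <- instruments$gamma
  G <- instruments$Gamma
  w <- 1 / instruments$se_Gamma^2
  beta <- sum(w * g * G) / sum(w * g^2)
  se_fixed <- 1 / sqrt(sum(w * g^2))
  sigma <- sqrt(sum(w * (G - beta * g)^2) / (n - 1))
  se <- if (model == "mre") se_fixed * max(1, sigma) else se_fixed
  p <- 2 * pnorm(-abs(beta / se))
  .mr_result_row("IVW", n, beta, se, p,
                 model = if (model == "mre")
                   "multiplicative-random-effects" else "fixed")
}

# Weighted least squares of G on g with intercept after orienting every
# instrument to a positive exposure effect; returns the pieces Egger and
# the heterogeneity statistic share.
.egger_fit <- function(instruments) {
  s <- ifelse(instruments$gamma < 0, -1, 1)
  g <- s * instruments$gamma
  G <- s * instruments$Gamma
  w <- 1 / instruments$se_Gamma^2
  sw <- sum(w); swx <- sum(w * g); swy <- sum(w * G)
  swxx <- sum(w * g^2); swxy <- sum(w * g * G)
  den <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / den
  intercept <- (swxx * swy - swx * swxy) / den
  resid <- G - intercept - slope * g
  list(slope = slope, intercept = intercept,
       var_slope = sw / den, var_intercept = swxx / den,
       Q = sum(w * resid^2), n = length(g))
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome effects on the exposure effects with
#' an intercept, after orienting every instrument so the exposure effect is
#' positive (the estimate is not invariant to allele-coding sign). The
#' slope estimates the causal effect under the InSIDE assumption; the
#' intercept estimates the average directional pleiotropy, and its test
#' uses a t-distribution with n-2 degrees of freedom. Standard errors are
#' scaled by the residual standard deviation when it exceeds 1.
#'
#' @param instruments Harmonized-instrument tibble (at least 3 rows).
#' @return A one-row MR-result tibble including `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instruments) {
  n <- .check_instruments(instruments, 3, "MR-Egger")
  fit <- .egger_fit(instruments)
  scale <- max(1, sqrt(fit$Q / (n - 2)))
  se <- sqrt(fit$var_slope) * scale
  se_i <- sqrt(fit$var_intercept) * scale
  p <- 2 * pt(-abs(fit$slope / se), df = n - 2)
  p_i <- 2 * pt(-abs(fit$intercept / se_i), df = n - 2)
  .mr_result_row("MR-Egger", n, fit$slope, se, p,
                 model = "multiplicative-random-effects",
                 intercept = fit$intercept, intercept_se = se_i,
                 intercept_p = p_i)
}

# Interpolated weighted median of x with weights w (standardized cumulative
# positions (S_j - w_j/2)/S_n, linear interpolation at 1/2).
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  s <- cumsum(w)
  pos <- (s - w / 2) / s[length(s)]
  if (length(x) == 1) return(x)
  approx(pos, x, xout = 0.5, rule = 2, ties = "ordered")$y
}

.ratio_weights <- function(instruments, second_order = FALSE) {
  v <- instruments$se_Gamma^2 / instruments$gamma^2
  if (second_order) {
    v <- v + instruments$Gamma^2 * instruments$se_gamma^2 / instruments$gamma^4
  }
  w <- 1 / v
  w / sum(w)
}

# Parametric-bootstrap standard error shared by the median and mode
# estimators: resample (gamma, Gamma) from their normal sampling
# distributions and recompute the point estimate.
.bootstrap_se <- function(instruments, point_fun, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    inform(sprintf("no bootstrap seed supplied; drew seed %d", seed))
  }
  n <- nrow(instruments)
  withr::with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      boot <- instruments
      boot$gamma <- rnorm(n, instruments$gamma, instruments$se_gamma)
      boot$Gamma <- rnorm(n, instruments$Gamma, instruments$se_Gamma)
      point_fun(boot)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted-median estimate
#'
#' Orders the per-variant Wald ratios and takes the inverse-variance
#' weighted median by linear interpolation of the standardized cumulative
#' weights at 1/2. Consistent when at least half of the weight comes from
#' valid instruments. The standard error is the standard deviation of the
#' estimate over parametric-bootstrap resamples of the summary statistics.
#'
#' @param instruments Harmonized-instrument tibble (at least 2 rows).
#' @param n_boot Bootstrap replicates for the standard error; `0` skips the
#'   bootstrap (`se` and `p` are then `NA`).
#' @param seed Seed for the bootstrap; when `NULL` a seed is drawn from the
#'   session RNG and logged.
#' @param second_order Use second-order delta-method ratio variances.
#' @return A one-row MR-result tibble.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = NULL,
                               second_order = FALSE) {
  .check_instruments(instruments, 2, "weighted median")
  point <- function(inst) {
    .weighted_median(inst$Gamma / inst$gamma,
                     .ratio_weights(inst, second_order))
  }
  beta <- point(instruments)
  se <- .bootstrap_se(instruments, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(beta / se))
  .mr_result_row("weighted-median", nrow(instruments), beta, se, p)
}

# Weighted MAD about the weighted median, normal-consistent scale.
.weighted_mad <- function(x, w) {
  .weighted_median(abs(x - .weighted_median(x, w)), w)
}

.mode_point <- function(ratios, w, phi) {
  n <- length(ratios)
  wsd <- sqrt(sum(w * (ratios - sum(w * ratios))^2))
  wmad <- .weighted_mad(ratios, w) / 0.6745
  spread <- if (wmad > 0) min(wsd, wmad) else wsd
  h <- phi * 0.9 * spread * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # all ratios identical (or a degenerate spread): the mode is the
    # common/most-weighted value
    return(ratios[which.max(w)])
  }
  d <- density(ratios, weights = w, bw = h, kernel = "gaussian", n = 4096,
               from = min(ratios) - 4 * h, to = max(ratios) + 4 * h)
  d$x[which.max(d$y)]
}

#' Weighted-mode estimate
#'
#' The mode of the inverse-variance weighted kernel density of the
#' per-variant Wald ratios, with bandwidth
#' `h = phi * 0.9 * min(sd, mad/0.6745) * n^(-1/5)` (weighted sd and
#' weighted median absolute deviation). Consistent when the largest group
#' of instruments sharing a causal estimate is valid, even if they are a
#' minority of all instruments. Bootstrap standard error as for
#' [mr_weighted_median()].
#'
#' @param instruments Harmonized-instrument tibble (at least 2 rows).
#' @param phi Bandwidth multiplier.
#' @inheritParams mr_weighted_median
#' @return A one-row MR-result tibble.
#' @export
mr_weighted_mode <- function(instruments, phi = 1, n_boot = 1000,
                             seed = NULL, second_order = FALSE) {
  .check_instruments(instruments, 2, "weighted mode")
  point <- function(inst) {
    .mode_point(inst$Gamma / inst$gamma,
                .ratio_weights(inst, second_order), phi)
  }
  beta <- point(instruments)
  se <- .bootstrap_se(instruments, point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(beta / se))
  .mr_result_row("weighted-mode", nrow(instruments), beta, se, p)
}

#' Cochran's Q heterogeneity statistics
#'
#' Weighted sums of squared deviations of the per-variant estimates from
#' the fitted model, on the outcome-effect scale with weights
#' `1/se_Gamma^2` (algebraically identical to the ratio-scale Q with
#' first-order ratio weights): about the IVW fit (df = n-1) and about the
#' Egger fit (df = n-2, requires n >= 3). P-values are chi-square upper
#' tails.
#'
#' @param instruments Harmonized-instrument tibble (at least 2 rows).
#' @return A tibble with one row per method (`IVW`, `MR-Egger`):
#'   `Q`, `df`, `p`.
#' @export
mr_heterogeneity <- function(instruments) {
  n <- .check_instruments(instruments, 2, "heterogeneity")
  g <- instruments$gamma
  G <- instruments$Gamma
  w <- 1 / instruments$se_Gamma^2
  b <- sum(w * g * G) / sum(w * g^2)
  q_ivw <- sum(w * (G - b * g)^2)
  out <- tibble(method = "IVW", Q = q_ivw, df = n - 1L,
                p = pchisq(q_ivw, df = n - 1, lower.tail = FALSE))
  if (n >= 3) {
    fit <- .egger_fit(instruments)
    out <- dplyr::bind_rows(out, tibble(
      method = "MR-Egger", Q = fit$Q, df = n - 2L,
      p = pchisq(fit$Q, df = n - 2, lower.tail = FALSE)
    ))
  }
  out
}

#' Sensitivity tables: leave-one-out, single-variant, funnel, scatter
#'
#' Leave-one-out refits the IVW estimate excluding each instrument in turn
#' (falling back to the Wald ratio when only one instrument remains) and
#' appends an `"All"` row. The single-variant table lists every Wald ratio
#' plus overall IVW and MR-Egger rows. The funnel table pairs each ratio
#' with its precision `1/se`; the scatter table carries the per-variant
#' effect pairs with the fitted slope (and intercept) of each method that
#' can run.
#'
#' @param instruments Harmonized-instrument tibble (at least 2 rows).
#' @param model IVW model passed to [mr_ivw()].
#' @return A list with tibbles `leave_one_out`, `single_snp`, `funnel`,
#'   `scatter`, and `fits` (per-method slope/intercept for the scatter).
#' @export
mr_sensitivity <- function(instruments, model = c("mre", "fixed")) {
  model <- match.arg(model)
  n <- .check_instruments(instruments, 2, "sensitivity analysis")
  wr <- wald_ratios(instruments)

  loo_rows <- lapply(seq_len(n), function(j) {
    rest <- instruments[-j, , drop = FALSE]
    row <- if (nrow(rest) >= 2) {
      mr_ivw(rest, model = model)
    } else {
      w <- wald_ratios(rest)
      .mr_result_row("Wald-ratio", 1, w$ratio, w$se, w$p)
    }
    tibble(excluded = instruments$variant_id[j],
           n_snps = row$n_snps, beta = row$beta, se = row$se, p = row$p)
  })
  all_row <- mr_ivw(instruments, model = model)
  leave_one_out <- dplyr::bind_rows(
    dplyr::bind_rows(loo_rows),
    tibble(excluded = "All", n_snps = all_row$n_snps,
           beta = all_row$beta, se = all_row$se, p = all_row$p)
  )

  single <- tibble(variant_id = wr$variant_id, method = "Wald-ratio",
                   beta = wr$ratio, se = wr$se, p = wr$p)
  single <- dplyr::bind_rows(single, tibble(
    variant_id = "All", method = "IVW",
    beta = all_row$beta, se = all_row$se, p = all_row$p
  ))
  fits <- tibble(method = "IVW", slope = all_row$beta, intercept = 0)
  if (n >= 3) {
    eg <- mr_egger(instruments)
    single <- dplyr::bind_rows(single, tibble(
      variant_id = "All", method = "MR-Egger",
      beta = eg$beta, se = eg$se, p = eg$p
    ))
    fits <- dplyr::bind_rows(fits, tibble(
      method = "MR-Egger", slope = eg$beta, intercept = eg$intercept
    ))
  }

  list(
    leave_one_out = leave_one_out,
    single_snp = single,
    funnel = tibble(variant_id = wr$variant_id, ratio = wr$ratio,
                    precision = 1 / wr$se),
    scatter = tibble(variant_id = instruments$variant_id,
                     gamma = instruments$gamma,
                     se_gamma = instruments$se_gamma,
                     Gamma = instruments$Gamma,
                     se_Gamma = instruments$se_Gamma),
    fits = fits
  )
}

#' Run the four MR methods plus diagnostics
#'
#' Applies IVW, weighted median, weighted mode and MR-Egger to the same
#' harmonized, clumped instruments, and collects heterogeneity statistics,
#' the Egger intercept test, and the sensitivity tables. Methods whose
#' instrument-count requirement is not met are reported in `not_run` with
#' the reason instead of aborting the rest; a single instrument yields the
#' Wald ratio alone.
#'
#' @param instruments Harmonized-instrument tibble.
#' @param model IVW model (`"mre"` or `"fixed"`).
#' @param n_boot Bootstrap replicates for the median/mode standard errors.
#' @param seed Seed for all stochastic steps.
#' @param phi Weighted-mode bandwidth multiplier.
#' @return A list of class `mr_result_set`: `estimates` (one row per
#'   method), `heterogeneity`, `egger_intercept`, `sensitivity`,
#'   `not_run`, `n_snps`.
#' @export
mr_run_all <- function(instruments, model = c("mre", "fixed"),
                       n_boot = 1000, seed = NULL, phi = 1) {
  model <- match.arg(model)
  n <- nrow(instruments)
  if (n == 0) stop_empty("no instruments to analyse")
  not_run <- tibble(method = character(), reason = character())
  note <- function(method, e) {
    not_run <<- dplyr::bind_rows(not_run,
                                 tibble(method = method,
                                        reason = conditionMessage(e)))
    NULL
  }
  run <- function(method, expr) {
    tryCatch(expr, mrshare_degenerate_input = function(e) note(method, e))
  }

  rows <- list()
  if (n == 1) {
    wr <- wald_ratios(instruments)
    rows$wald <- .mr_result_row("Wald-ratio", 1, wr$ratio, wr$se, wr$p)
    for (m in c("IVW", "weighted-median", "weighted-mode", "MR-Egger")) {
      not_run <- dplyr::bind_rows(not_run, tibble(
        method = m, reason = "not applicable with a single instrument"
      ))
    }
  } else {
    rows$ivw <- run("IVW", mr_ivw(instruments, model = model))
    rows$wm <- run("weighted-median",
                   mr_weighted_median(instruments, n_boot = n_boot,
                                      seed = seed))
    rows$wmo <- run("weighted-mode",
                    mr_weighted_mode(instruments, phi = phi,
                                     n_boot = n_boot,
                                     seed = if (is.null(seed)) NULL else
                                       seed + 1L))
    rows$egger <- run("MR-Egger", mr_egger(instruments))
  }
  estimates <- dplyr::bind_rows(rows)

  heterogeneity <- if (n >= 2) mr_heterogeneity(instruments) else NULL
  egger_row <- estimates[estimates$method == "MR-Egger", , drop = FALSE]
  egger_intercept <- if (nrow(egger_row) == 1) {
    tibble(intercept = egger_row$intercept,
           se = egger_row$intercept_se,
           p = egger_row$intercept_p)
  } else NULL
  sensitivity <- if (n >= 2) mr_sensitivity(instruments, model = model) else NULL

  structure(list(
    estimates = estimates,
    heterogeneity = heterogeneity,
    egger_intercept = egger_intercept,
    sensitivity = sensitivity,
    not_run = not_run,
    n_snps = n
  ), class = "mr_result_set")
}

#' @export
print.mr_result_set <- function(x, ...) {
  cat(sprintf("<mr_result_set: %d instruments>\n", x$n_snps))
  est <- x$estimates
  if (!is.null(est) && nrow(est) > 0) {
    show <- est[, c("method", "n_snps", "beta", "se", "p")]
    show$beta <- signif(show$beta, 3)
    show$se <- signif(show$se, 3)
    show$p <- signif(show$p, 2)
    print(as.data.frame(show), row.names = FALSE)
  }
  if (nrow(x$not_run) > 0) {
    cat("not run:", paste(x$not_run$method, collapse = ", "), "\n")
  }
  invisible(x)
}
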