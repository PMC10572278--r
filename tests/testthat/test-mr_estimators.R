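test_that("Wald ratios apply the first-order delta method", {
  inst <- make_instruments(gamma = 0.25, Gamma = 0.5, se_Gamma = 0.1)
  wr <- wald_ratios(inst)
  expect_equal(wr$ratio, 2)
  expect_equal(wr$se, 0.4)

  null <- wald_ratios(make_instruments(gamma = 0.3, Gamma = 0))
  expect_equal(null$ratio, 0)

  neg <- wald_ratios(make_instruments(gamma = c(-0.3, 0.3),
                                      Gamma = c(0.15, -0.15)))
  expect_equal(neg$ratio, c(-0.5, -0.5))

  expect_warning(dropped <- wald_ratios(make_instruments(gamma = c(0, 0.3),
                                                         Gamma = c(0.1, 0.1))),
                 "zero exposure effect")
  expect_equal(nrow(dropped), 1)
})

test_that("IVW closed form matches the weighted-ratio identity and lm", {
  two <- make_instruments(gamma = c(0.25, 0.25), Gamma = c(0.5, 0.5),
                          se_Gamma = 0.1)
  fit <- mr_ivw(two, model = "fixed")
  expect_equal(fit$beta, 2)
  expect_equal(fit$se, 0.4 / sqrt(2), tolerance = 1e-12)

  set.seed(81)
  inst <- make_instruments(gamma = runif(15, 0.1, 0.5),
                           Gamma = rnorm(15, 0.1, 0.1),
                           se_Gamma = runif(15, 0.03, 0.1))
  fit2 <- mr_ivw(inst, model = "mre")
  # algebraic identity: IVW equals the inverse-variance weighted mean of
  # Wald ratios with weights w_j * gamma_j^2
  wr <- wald_ratios(inst)
  w <- inst$gamma^2 / inst$se_Gamma^2
  expect_equal(fit2$beta, sum(w * wr$ratio) / sum(w), tolerance = 1e-10)

  # independent route: weighted regression through the origin
  lm_fit <- lm(Gamma ~ 0 + gamma, data = inst, weights = 1 / se_Gamma^2)
  expect_equal(fit2$beta, unname(coef(lm_fit)), tolerance = 1e-12)
  sigma <- sqrt(sum((1 / inst$se_Gamma^2) *
                      residuals(lm_fit)^2) / (nrow(inst) - 1))
  if (sigma > 1) {
    expect_equal(fit2$se, unname(summary(lm_fit)$coefficients[1, 2]),
                 tolerance = 1e-10)
  }
  expect_error(mr_ivw(inst[1, ]), class = "mrshare_degenerate_input")
  expect_error(mr_ivw(inst[1, ]), "Wald ratio")
})

test_that("Egger recovers an exact affine relationship and matches lm", {
  inst <- make_instruments(gamma = c(0.1, 0.2, 0.4),
                           Gamma = 0.1 + 0.5 * c(0.1, 0.2, 0.4),
                           se_Gamma = c(0.1, 0.2, 0.15))
  fit <- mr_egger(inst)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  het <- mr_heterogeneity(inst)
  expect_equal(het$Q[het$method == "MR-Egger"], 0, tolerance = 1e-20)

  set.seed(91)
  inst2 <- make_instruments(gamma = runif(20, -0.5, 0.5),
                            Gamma = rnorm(20, 0.05, 0.15),
                            se_Gamma = runif(20, 0.03, 0.1))
  fit2 <- mr_egger(inst2)
  s <- ifelse(inst2$gamma < 0, -1, 1)
  lm_fit <- lm(I(s * Gamma) ~ I(s * gamma), data = inst2,
               weights = 1 / se_Gamma^2)
  expect_equal(fit2$beta, unname(coef(lm_fit)[2]), tolerance = 1e-10)
  expect_equal(fit2$intercept, unname(coef(lm_fit)[1]), tolerance = 1e-10)
  sm <- summary(lm_fit)$coefficients
  if (summary(lm_fit)$sigma > 1) {
    expect_equal(fit2$se, unname(sm[2, 2]), tolerance = 1e-10)
    expect_equal(fit2$intercept_p, unname(sm[1, 4]), tolerance = 1e-10)
  }
  expect_error(mr_egger(inst2[1:2, ]), class = "mrshare_degenerate_input")
})

test_that("weighted median interpolates the weighted ratio order statistics", {
  inst <- make_instruments(gamma = rep(1, 3), Gamma = c(1, 2, 9),
                           se_Gamma = 1)
  fit <- mr_weighted_median(inst, n_boot = 0)
  expect_equal(fit$beta, 2)

  # bootstrap with a fixed seed is reproducible
  fit_a <- mr_weighted_median(inst, n_boot = 50, seed = 7)
  fit_b <- mr_weighted_median(inst, n_boot = 50, seed = 7)
  expect_identical(fit_a$se, fit_b$se)
  expect_gt(fit_a$se, 0)
  expect_error(mr_weighted_median(inst[1, ]),
               class = "mrshare_degenerate_input")
})

test_that("weighted mode tracks the dominant ratio cluster", {
  inst <- make_instruments(gamma = rep(1, 4),
                           Gamma = c(0.48, 0.50, 0.52, 3.0), se_Gamma = 1)
  fit <- mr_weighted_mode(inst, n_boot = 0)
  expect_equal(fit$beta, 0.5, tolerance = 0.02)

  # independent dense-grid KDE oracle with the bandwidth worked by hand:
  # equal weights, weighted median 0.51, weighted MAD 0.02, weighted sd 1.083
  ratios <- inst$Gamma / inst$gamma
  w <- rep(0.25, 4)
  h <- 0.9 * min(1.0826, 0.02 / 0.6745) * 4^(-1 / 5)
  grid <- seq(min(ratios) - 1, max(ratios) + 1, length.out = 50000)
  kde <- vapply(grid, function(x) sum(w * dnorm(x, ratios, h)), numeric(1))
  expect_equal(fit$beta, grid[which.max(kde)], tolerance = 0.01)

  same <- make_instruments(gamma = rep(1, 3), Gamma = rep(0.7, 3))
  expect_equal(mr_weighted_mode(same, n_boot = 0)$beta, 0.7)

  # removing the outlier moves the estimate by less than the bandwidth scale
  no_out <- make_instruments(gamma = rep(1, 3), Gamma = c(0.48, 0.50, 0.52),
                             se_Gamma = 1)
  fit2 <- mr_weighted_mode(no_out, n_boot = 0)
  expect_lt(abs(fit2$beta - fit$beta), 0.05)
})

test_that("heterogeneity Q matches hand computation and Egger never exceeds IVW", {
  inst <- make_instruments(gamma = c(1, 1), Gamma = c(1, 3), se_Gamma = 1)
  het <- mr_heterogeneity(inst)
  expect_equal(het$Q[het$method == "IVW"], 2)
  expect_equal(het$df[het$method == "IVW"], 1)

  ident <- make_instruments(gamma = c(0.2, 0.4, 0.8),
                            Gamma = 0.5 * c(0.2, 0.4, 0.8), se_Gamma = 0.1)
  het2 <- mr_heterogeneity(ident)
  expect_equal(het2$Q, c(0, 0), tolerance = 1e-20)
  expect_equal(het2$p, c(1, 1))

  set.seed(101)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    inst3 <- make_instruments(gamma = runif(n, -0.5, 0.5),
                              Gamma = rnorm(n, 0, 0.2),
                              se_Gamma = runif(n, 0.02, 0.2))
    het3 <- mr_heterogeneity(inst3)
    expect_lte(het3$Q[2], het3$Q[1] + 1e-9)
  }
})

test_that("estimates are sign-equivariant and scale-equivariant", {
  set.seed(111)
  inst <- make_instruments(gamma = runif(12, 0.1, 0.5),
                           Gamma = rnorm(12, 0.2, 0.05),
                           se_Gamma = runif(12, 0.03, 0.08))
  neg <- inst
  neg$Gamma <- -neg$Gamma
  scaled <- inst
  scaled$gamma <- 2 * scaled$gamma
  scaled$se_gamma <- 2 * scaled$se_gamma

  for (f in list(function(x) mr_ivw(x)$beta,
                 function(x) mr_egger(x)$beta,
                 function(x) mr_weighted_median(x, n_boot = 0)$beta)) {
    expect_equal(f(neg), -f(inst), tolerance = 1e-9)
    expect_equal(f(scaled), f(inst) / 2, tolerance = 1e-9)
  }
  expect_equal(mr_weighted_mode(neg, n_boot = 0)$beta,
               -mr_weighted_mode(inst, n_boot = 0)$beta, tolerance = 1e-3)
  expect_equal(mr_weighted_mode(scaled, n_boot = 0)$beta,
               mr_weighted_mode(inst, n_boot = 0)$beta / 2, tolerance = 1e-3)
})

test_that("sensitivity tables have the documented shape and consistency", {
  set.seed(121)
  n <- 6
  inst <- make_instruments(gamma = runif(n, 0.2, 0.5),
                           Gamma = rnorm(n, 0.15, 0.05),
                           se_Gamma = runif(n, 0.03, 0.08))
  s <- mr_sensitivity(inst)
  expect_equal(nrow(s$leave_one_out), n + 1)
  expect_equal(s$leave_one_out$excluded[n + 1], "All")
  expect_equal(s$leave_one_out$n_snps[1:n], rep(n - 1L, n))

  all_ivw <- mr_ivw(inst)
  all_egger <- mr_egger(inst)
  overall <- s$single_snp[s$single_snp$variant_id == "All", ]
  expect_equal(overall$beta[overall$method == "IVW"], all_ivw$beta)
  expect_equal(overall$beta[overall$method == "MR-Egger"], all_egger$beta)
  expect_equal(nrow(s$funnel), n)
  expect_equal(s$funnel$precision, 1 / wald_ratios(inst)$se)

  # identical instruments: every leave-one-out estimate equals the overall
  copies <- make_instruments(gamma = rep(0.3, 5), Gamma = rep(0.15, 5))
  s2 <- mr_sensitivity(copies)
  expect_equal(unique(round(s2$leave_one_out$beta, 12)), 0.5)
})

test_that("the four-method suite degrades gracefully by instrument count", {
  set.seed(131)
  inst <- make_instruments(gamma = runif(4, 0.2, 0.5),
                           Gamma = rnorm(4, 0.15, 0.05))
  res <- mr_run_all(inst, n_boot = 50, seed = 3)
  expect_setequal(res$estimates$method,
                  c("IVW", "weighted-median", "weighted-mode", "MR-Egger"))
  expect_equal(unique(res$estimates$n_snps), 4L)
  expect_false(is.null(res$egger_intercept))
  expect_equal(nrow(res$not_run), 0)

  one <- mr_run_all(inst[1, ], n_boot = 0)
  expect_equal(one$estimates$method, "Wald-ratio")
  expect_equal(nrow(one$not_run), 4)

  two <- mr_run_all(inst[1:2, ], n_boot = 0)
  expect_true("IVW" %in% two$estimates$method)
  expect_true("MR-Egger" %in% two$not_run$method)

  expect_error(mr_run_all(inst[0, ]), class = "mrshare_empty_input")
})

test_that("simulated causal effects are recovered within sampling error", {
  cfg <- simulation_config(n_instruments = 30, theta = 0.5, seed = 141,
                           se_gamma = 0.02, se_Gamma = 0.05,
                           selection_threshold = 1)
  sim <- simulate_two_sample(cfg)
  h <- harmonize_dataset(sim$exposure, sim$outcome)
  fit <- mr_ivw(h$retained)
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)

  res <- mr_run_all(h$retained, n_boot = 100, seed = 5)
  est <- res$estimates
  for (m in est$method) {
    row <- est[est$method == m, ]
    expect_lt(abs(row$beta - 0.5), 4 * row$se)
  }
})
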