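#' Configuration for the two-sample summary-statistic simulator
#'
#' The generator emulates a pair of non-overlapping case-control GWAS: true
#' per-variant exposure effects (log-odds scale), a true causal effect
#' `theta` carrying them into the outcome, optional pleiotropic direct
#' effects, and independent sampling noise in each sample. Directional
#' pleiotropy is expressed relative to the exposure-increasing allele, the
#' orientation MR-Egger regresses in. Instrument selection at the
#' genome-wide threshold is modelled by rejection sampling of the observed
#' exposure association (inducing winner's curse); set
#' `selection_threshold = 1` to disable selection.
#'
#' @param n_instruments Number of instruments J.
#' @param theta True causal effect of the exposure on the outcome.
#' @param gamma_sd Standard deviation of the true exposure effects
#'   (log-odds per allele).
#' @param se_gamma,se_Gamma Sampling standard errors for the exposure and
#'   outcome effects; a scalar, or a length-2 range drawn uniformly per
#'   variant.
#' @param mu_alpha,sd_alpha Mean and standard deviation of the pleiotropic
#'   direct effects (directional when `mu_alpha != 0`, balanced when 0).
#' @param pleiotropy_fraction Fraction of instruments receiving a
#'   pleiotropic effect (the rest are valid).
#' @param inside_corr Correlation between pleiotropic effects and
#'   instrument strength; 0 means the InSIDE assumption holds.
#' @param confounder_effect Weight in [0, 1) of a shared confounded
#'   component entering both the exposure effect and the outcome directly
#'   (correlated pleiotropy).
#' @param palindromic_fraction Fraction of variants given A/T or C/G
#'   alleles.
#' @param palindromic_eaf_spread Half-width of the effect-allele-frequency
#'   band around 0.5 for palindromic variants.
#' @param strand_flip_fraction Fraction of (non-palindromic) outcome rows
#'   emitted on the opposite strand.
#' @param allele_swap_fraction Fraction of (non-palindromic) outcome rows
#'   emitted with effect/other alleles swapped (and the effect negated).
#' @param selection_threshold Exposure p-value an instrument must pass.
#' @param max_attempts Rejection-sampling budget per instrument.
#' @param seed Seed; when `NULL` one is drawn and logged at simulation
#'   time.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_instruments = 30, theta = 0.5,
                              gamma_sd = 0.25, se_gamma = 0.03,
                              se_Gamma = 0.05, mu_alpha = 0, sd_alpha = 0,
                              pleiotropy_fraction = 1, inside_corr = 0,
                              confounder_effect = 0,
                              palindromic_fraction = 0.2,
                              palindromic_eaf_spread = 0.15,
                              strand_flip_fraction = 0.1,
                              allele_swap_fraction = 0.2,
                              selection_threshold = 5e-8,
                              max_attempts = 10000, seed = NULL) {
  frac <- c(pleiotropy_fraction, palindromic_fraction,
            strand_flip_fraction, allele_swap_fraction)
  if (any(frac < 0) || any(frac > 1)) {
    stop_config("fractions must lie in [0, 1]")
  }
  if (gamma_sd < 0 || sd_alpha < 0) stop_config("sd parameters must be >= 0")
  if (abs(inside_corr) > 1) stop_config("inside_corr must lie in [-1, 1]")
  if (confounder_effect < 0 || confounder_effect >= 1) {
    stop_config("confounder_effect must lie in [0, 1)")
  }
  if (selection_threshold <= 0 || selection_threshold > 1) {
    stop_config("selection_threshold must lie in (0, 1]")
  }
  if (n_instruments < 1) stop_config("n_instruments must be >= 1")
  structure(list(
    n_instruments = as.integer(n_instruments), theta = theta,
    gamma_sd = gamma_sd, se_gamma = se_gamma, se_Gamma = se_Gamma,
    mu_alpha = mu_alpha, sd_alpha = sd_alpha,
    pleiotropy_fraction = pleiotropy_fraction,
    inside_corr = inside_corr, confounder_effect = confounder_effect,
    palindromic_fraction = palindromic_fraction,
    palindromic_eaf_spread = palindromic_eaf_spread,
    strand_flip_fraction = strand_flip_fraction,
    allele_swap_fraction = allele_swap_fraction,
    selection_threshold = selection_threshold,
    max_attempts = as.integer(max_attempts), seed = seed
  ), class = "simulation_config")
}

.draw_se <- function(spec, n) {
  if (length(spec) == 1) return(rep(spec, n))
  if (length(spec) == 2) return(runif(n, min(spec), max(spec)))
  stop_config("se specification must be a scalar or a length-2 range")
}

.nonpal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                          "G", "A", "G", "T", "T", "C", "T", "G"),
                        ncol = 2, byrow = TRUE)
.pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                     ncol = 2, byrow = TRUE)

#' Simulate a two-sample GWAS summary-statistic pair with known truth
#'
#' Draws true exposure effects, applies the causal effect and the
#' configured pleiotropy/confounding to form true outcome effects, adds
#' independent sampling noise in each sample, and dresses the variants
#' with allele pairs, frequencies, and strand/swap presentation so the
#' harmonization stage is exercised. Every latent quantity is stored in
#' the truth record.
#'
#' @param config A [simulation_config()].
#' @return A list with `exposure` and `outcome` association tibbles (the
#'   dialects [read_associations()] reads) and `truth`, a list holding the
#'   per-variant latent values and the configuration.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    inform(sprintf("no seed supplied; drew seed %d", seed))
  }
  withr::with_seed(seed, .simulate_two_sample_impl(config, seed))
}

.simulate_two_sample_impl <- function(config, seed) {
  J <- config$n_instruments
  se_g <- .draw_se(config$se_gamma, J)
  se_G <- .draw_se(config$se_Gamma, J)
  lam <- config$confounder_effect

  gamma_true <- numeric(J)
  u_conf <- numeric(J)
  gamma_hat <- numeric(J)
  select_on <- config$selection_threshold < 1
  for (j in seq_len(J)) {
    accepted <- FALSE
    for (attempt in seq_len(config$max_attempts)) {
      u <- rnorm(1, 0, config$gamma_sd)
      g <- sqrt(1 - lam^2) * rnorm(1, 0, config$gamma_sd) + lam * u
      gh <- g + rnorm(1, 0, se_g[j])
      if (!select_on ||
          2 * pnorm(-abs(gh / se_g[j])) < config$selection_threshold) {
        gamma_true[j] <- g
        u_conf[j] <- u
        gamma_hat[j] <- gh
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      stop_domain(paste0(
        "selection threshold %g unreachable at se_gamma %g within %d ",
        "attempts (instrument %d)"),
        config$selection_threshold, se_g[j], config$max_attempts, j)
    }
  }

  n_invalid <- round(config$pleiotropy_fraction * J)
  invalid <- rep(FALSE, J)
  if (n_invalid > 0) invalid[sample.int(J, n_invalid)] <- TRUE
  alpha <- numeric(J)
  if (n_invalid > 0 && (config$mu_alpha != 0 || config$sd_alpha > 0)) {
    z_ind <- rnorm(n_invalid)
    rho <- config$inside_corr
    strength <- abs(gamma_true[invalid])
    z_str <- if (n_invalid >= 2 && sd(strength) > 0) {
      as.numeric(scale(strength))
    } else {
      rep(0, n_invalid)
    }
    z <- rho * z_str + sqrt(1 - rho^2) * z_ind
    alpha[invalid] <- config$mu_alpha + config$sd_alpha * z
  }

  Gamma_true <- config$theta * gamma_true +
    sign(gamma_true) * alpha + lam * u_conf
  Gamma_hat <- Gamma_true + rnorm(J, 0, se_G)

  # variant dressing: ids, map positions, alleles, frequencies
  variant_id <- sprintf("rs%07d", sample.int(9999999, J))
  chrom <- as.character(sample.int(22, J, replace = TRUE))
  pos <- sample.int(240000000, J)
  n_pal <- round(config$palindromic_fraction * J)
  pal <- rep(FALSE, J)
  if (n_pal > 0) pal[sample.int(J, n_pal)] <- TRUE
  ea <- oa <- character(J)
  np_pick <- sample.int(nrow(.nonpal_pairs), J, replace = TRUE)
  p_pick <- sample.int(nrow(.pal_pairs), J, replace = TRUE)
  ea[!pal] <- .nonpal_pairs[np_pick[!pal], 1]
  oa[!pal] <- .nonpal_pairs[np_pick[!pal], 2]
  ea[pal] <- .pal_pairs[p_pick[pal], 1]
  oa[pal] <- .pal_pairs[p_pick[pal], 2]
  eaf <- numeric(J)
  eaf[!pal] <- runif(sum(!pal), 0.05, 0.95)
  spread <- config$palindromic_eaf_spread
  eaf[pal] <- pmin(0.98, pmax(0.02, runif(sum(pal), 0.5 - spread,
                                          0.5 + spread)))
  eaf_out <- pmin(0.99, pmax(0.01, eaf + rnorm(J, 0, 0.01)))

  exposure <- tibble(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = gamma_hat, se = se_g,
    pval = 2 * pnorm(-abs(gamma_hat / se_g)),
    trait = "exposure_sim", ancestry = "SIM"
  )

  # Presentation of the outcome rows: strand flips and allele swaps on
  # non-palindromic variants only (a flipped palindrome is indistinguishable
  # from a swap, which would muddy the truth record).
  candidates <- which(!pal)
  pick_frac <- function(frac) {
    n <- round(frac * J)
    if (n == 0 || length(candidates) == 0) return(integer(0))
    sample(candidates, min(n, length(candidates)))
  }
  flip_idx <- pick_frac(config$strand_flip_fraction)
  swap_idx <- pick_frac(config$allele_swap_fraction)

  ea_y <- ea; oa_y <- oa
  beta_y <- Gamma_hat
  eaf_y <- eaf_out
  if (length(swap_idx) > 0) {
    tmp <- ea_y[swap_idx]
    ea_y[swap_idx] <- oa_y[swap_idx]
    oa_y[swap_idx] <- tmp
    beta_y[swap_idx] <- -beta_y[swap_idx]
    eaf_y[swap_idx] <- 1 - eaf_y[swap_idx]
  }
  if (length(flip_idx) > 0) {
    ea_y[flip_idx] <- .complement_allele(ea_y[flip_idx])
    oa_y[flip_idx] <- .complement_allele(oa_y[flip_idx])
  }

  outcome <- tibble(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = ea_y, other_allele = oa_y, eaf = eaf_y,
    beta = beta_y, se = se_G,
    pval = 2 * pnorm(-abs(beta_y / se_G)),
    trait = "outcome_sim", ancestry = "SIM"
  )

  truth <- list(
    theta = config$theta,
    seed = seed,
    config = config,
    variants = tibble(
      variant_id = variant_id,
      gamma_true = gamma_true, gamma_hat = gamma_hat,
      u_conf = u_conf, alpha = alpha, invalid = invalid,
      Gamma_true = Gamma_true, Gamma_hat = Gamma_hat,
      se_gamma = se_g, se_Gamma = se_G,
      palindromic = pal,
      presented_flipped = seq_len(J) %in% flip_idx,
      presented_swapped = seq_len(J) %in% swap_idx
    )
  )
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate two gene lists with a known overlap
#'
#' Draws `n_query + n_subject - k_true` distinct symbols from a synthetic
#' background universe and arranges them so the two lists share exactly
#' `k_true` symbols.
#'
#' @param n_query,n_subject List sizes.
#' @param n_background Background universe size.
#' @param k_true Exact number of shared symbols.
#' @param seed Seed.
#' @return A list with `query` and `subject` [gene_list()] objects.
#' @export
simulate_overlap_lists <- function(n_query, n_subject, n_background = 19303,
                                   k_true, seed = 1) {
  if (k_true > min(n_query, n_subject)) {
    stop_domain("k_true must not exceed min(n_query, n_subject)")
  }
  if (n_query + n_subject - k_true > n_background) {
    stop_domain("background too small for the requested list sizes")
  }
  withr::with_seed(seed, {
    pool <- sample.int(n_background, n_query + n_subject - k_true)
    sym <- sprintf("G%05d", pool)
    shared <- sym[seq_len(k_true)]
    q_only <- sym[k_true + seq_len(n_query - k_true)]
    s_only <- sym[n_query + seq_len(n_subject - k_true)]
    list(
      query = gene_list("query_sim", sample(c(shared, q_only))),
      subject = gene_list("subject_sim", sample(c(shared, s_only)))
    )
  })
}

#' Simulate two locus tables with a known number of window overlaps
#'
#' Places lead variants on a grid of well-separated genomic slots so that
#' exactly `k_true` query windows intersect a subject window (each shared
#' slot holds a query lead and a subject lead offset by less than the
#' window size; all other slots are isolated).
#'
#' @param n_query,n_subject Number of loci per table.
#' @param k_true Exact number of overlapping query windows.
#' @param window_size Window width the downstream analysis will use.
#' @param offset Center-to-center distance of an overlapping pair; must be
#'   smaller than `window_size`.
#' @param seed Seed.
#' @return A list with `query` and `subject` association tibbles (one
#'   variant per locus, suitable for [build_loci()]).
#' @export
simulate_overlap_loci <- function(n_query, n_subject, k_true,
                                  window_size = 500000, offset = 200000,
                                  seed = 1) {
  if (k_true > min(n_query, n_subject)) {
    stop_domain("k_true must not exceed min(n_query, n_subject)")
  }
  if (offset >= window_size) {
    stop_domain("offset must be smaller than window_size for pairs to overlap")
  }
  n_slots <- n_query + n_subject - k_true
  spacing <- 4 * window_size + offset
  withr::with_seed(seed, {
    slot <- sample.int(n_slots)
    slot_chrom <- as.character(((slot - 1) %% 22) + 1)
    slot_base <- 10000000 + ((slot - 1) %/% 22) * spacing
    mk <- function(idx, prefix, shift) {
      tibble(
        variant_id = sprintf("%s_%03d", prefix, seq_along(idx)),
        chrom = slot_chrom[idx],
        pos = as.integer(slot_base[idx] + shift),
        effect_allele = "A", other_allele = "G",
        eaf = runif(length(idx), 0.1, 0.9),
        beta = 0.3, se = 0.05,
        pval = 10^-runif(length(idx), 8.5, 30),
        trait = paste0(prefix, "_sim"), ancestry = "SIM"
      )
    }
    query_slots <- seq_len(n_query)                 # slots 1..k are shared
    subject_slots <- c(seq_len(k_true),
                       n_query + seq_len(n_subject - k_true))
    list(
      query = mk(query_slots, "qlocus", 0),
      subject = mk(subject_slots, "slocus", offset)
    )
  })
}
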