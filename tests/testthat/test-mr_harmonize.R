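test_that("palindromic classification follows the strand-complement rule", {
  expect_true(classify_palindromic("A", "T"))
  expect_true(classify_palindromic("C", "G"))
  expect_false(classify_palindromic("A", "G"))
  expect_warning(expect_false(classify_palindromic("AT", "A")), "multi-base")
})

test_that("align_pair resolves swaps, strand flips and palindrome policies", {
  ex <- make_assoc("rs1", effect_allele = "A", other_allele = "G",
                   beta = 0.2, eaf = 0.3)
  swap <- make_assoc("rs1", effect_allele = "G", other_allele = "A",
                     beta = -0.15, eaf = 0.7)
  h <- align_pair(ex, swap)
  expect_equal(h$Gamma, 0.15)
  expect_true(h$swapped)
  expect_equal(h$eaf_outcome, 0.3)

  flip <- make_assoc("rs1", effect_allele = "T", other_allele = "C",
                     beta = -0.15, eaf = 0.3)
  h2 <- align_pair(ex, flip)
  expect_true(h2$strand_flipped)
  expect_false(h2$swapped)
  expect_equal(h2$Gamma, -0.15) # complementation alone never changes sign

  flip_swap <- make_assoc("rs1", effect_allele = "C", other_allele = "T",
                          beta = -0.15, eaf = 0.7)
  h3 <- align_pair(ex, flip_swap)
  expect_true(h3$strand_flipped && h3$swapped)
  expect_equal(h3$Gamma, 0.15)

  pal_ex <- make_assoc("rs2", effect_allele = "A", other_allele = "T",
                       eaf = 0.45)
  pal_out <- make_assoc("rs2", effect_allele = "A", other_allele = "T",
                        beta = 0.1, eaf = 0.44)
  expect_equal(align_pair(pal_ex, pal_out)$dropped_reason, "palindromic")

  pal_rare_ex <- make_assoc("rs3", effect_allele = "A", other_allele = "T",
                            eaf = 0.10)
  pal_rare_out <- make_assoc("rs3", effect_allele = "A", other_allele = "T",
                             beta = 0.1, eaf = 0.12)
  h4 <- align_pair(pal_rare_ex, pal_rare_out, policy = "infer")
  expect_true(is.na(h4$dropped_reason))
  expect_true(h4$inferred_by_maf)

  # common palindrome stays ambiguous even under the infer policy
  h5 <- align_pair(pal_ex, pal_out, policy = "infer")
  expect_equal(h5$dropped_reason, "palindromic_ambiguous")

  expect_error(align_pair(ex, make_assoc("rsX")), class = "mrshare_config_error")
})

test_that("alignment never changes effect magnitudes or standard errors", {
  set.seed(51)
  cfg <- simulation_config(n_instruments = 40, seed = 52,
                           palindromic_fraction = 0)
  sim <- simulate_two_sample(cfg)
  h <- harmonize_dataset(sim$exposure, sim$outcome)
  m <- match(h$retained$variant_id, sim$outcome$variant_id)
  expect_equal(abs(h$retained$Gamma), abs(sim$outcome$beta[m]))
  expect_equal(h$retained$se_Gamma, sim$outcome$se[m])
  # every presented swap/flip is undone: aligned Gamma equals the latent draw
  t <- sim$truth$variants
  mt <- match(h$retained$variant_id, t$variant_id)
  expect_equal(h$retained$Gamma, t$Gamma_hat[mt])
})

test_that("harmonization is idempotent and reports drops by reason", {
  cfg <- simulation_config(n_instruments = 30, seed = 61)
  sim <- simulate_two_sample(cfg)
  h <- harmonize_dataset(sim$exposure, sim$outcome)
  expect_equal(h$report$n_matched, 30)
  expect_gt(h$report$n_swapped + h$report$n_strand_flipped, 0)
  expect_true(all(h$report$dropped$reason == "palindromic"))

  # feed the harmonized set back through as exposure/outcome tables
  as_assoc <- function(x, beta, se) {
    make_assoc(x$variant_id, chrom = x$chrom, pos = x$pos,
               effect_allele = x$effect_allele, other_allele = x$other_allele,
               eaf = x$eaf_exposure, beta = beta, se = se)
  }
  r <- h$retained
  h2 <- harmonize_dataset(as_assoc(r, r$gamma, r$se_gamma),
                          as_assoc(r, r$Gamma, r$se_Gamma))
  expect_equal(h2$retained$Gamma, r$Gamma)
  expect_equal(h2$retained$gamma, r$gamma)
  expect_false(any(h2$retained$swapped | h2$retained$strand_flipped))

  # all-palindromic matches under the drop policy leave nothing
  pal_ex <- make_assoc(c("p1", "p2"), effect_allele = "A", other_allele = "T",
                       eaf = 0.5)
  expect_error(harmonize_dataset(pal_ex, pal_ex),
               class = "mrshare_empty_input")
  expect_error(harmonize_dataset(make_assoc("a1"), make_assoc("b1")),
               class = "mrshare_empty_input")
})

test_that("strict mode drops matched ids at different positions", {
  ex <- make_assoc("rs1", pos = 100)
  out <- make_assoc("rs1", pos = 999)
  out2 <- make_assoc(c("rs1", "rs2"), pos = c(999, 2e6))
  ex2 <- make_assoc(c("rs1", "rs2"), pos = c(100, 2e6))
  h <- harmonize_dataset(ex2, out2, strict = TRUE)
  expect_equal(h$instruments$dropped_reason[h$instruments$variant_id == "rs1"],
               "position_mismatch")
  expect_equal(h$retained$variant_id, "rs2")
  expect_true(is.na(harmonize_dataset(ex, out)$retained$dropped_reason))
})

test_that("greedy clumping keeps the most significant variant per LD clique", {
  inst <- make_instruments(gamma = c(0.30, 0.28), Gamma = c(0.15, 0.14),
                           pos = c(1e6, 1.5e6))
  inst$pval_exposure <- c(1e-10, 1e-9)
  ld <- tibble::tibble(id1 = "rs001", id2 = "rs002", r2 = 0.9)
  kept <- ld_clump(inst, ld)
  expect_equal(kept$variant_id, "rs001")
  expect_equal(attr(kept, "removed")$index_id, "rs001")

  ld_low <- tibble::tibble(id1 = "rs001", id2 = "rs002", r2 = 0.0005)
  expect_equal(nrow(ld_clump(inst, ld_low)), 2)

  # a four-variant clique at r2 = 1 leaves exactly one survivor, the one
  # every removal order leaves: the smallest p-value
  clique <- make_instruments(gamma = c(0.3, 0.31, 0.29, 0.32),
                             Gamma = rep(0.15, 4), pos = c(1, 2, 3, 4) * 1e5)
  clique$pval_exposure <- c(1e-9, 1e-12, 1e-8, 1e-10)
  ids <- clique$variant_id
  ld_full <- tidyr::expand_grid(id1 = ids, id2 = ids) |>
    dplyr::filter(id1 < id2) |>
    dplyr::mutate(r2 = 1)
  expect_equal(ld_clump(clique, ld_full)$variant_id, "rs002")
})

test_that("clumping is order-invariant and the retained set is LD-pruned", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 12
    inst <- make_instruments(gamma = runif(n, 0.1, 0.5),
                             Gamma = runif(n, 0, 0.3),
                             chrom = sample(c("1", "2"), n, TRUE),
                             pos = sample.int(5e7, n))
    inst$pval_exposure <- 10^-runif(n, 8, 15)
    cluster <- sample(1:4, n, TRUE)
    pairs <- t(utils::combn(n, 2))
    ld <- tibble::tibble(
      id1 = inst$variant_id[pairs[, 1]],
      id2 = inst$variant_id[pairs[, 2]],
      r2 = ifelse(cluster[pairs[, 1]] == cluster[pairs[, 2]],
                  runif(nrow(pairs), 0.5, 1),
                  runif(nrow(pairs), 0, 0.0005))
    )
    kept <- ld_clump(inst, ld)
    perm <- sample.int(n)
    kept_perm <- ld_clump(inst[perm, ], ld)
    expect_setequal(kept$variant_id, kept_perm$variant_id)

    # post-hoc: all retained same-chromosome pairs within the window have
    # r2 below the threshold
    ids <- kept$variant_id
    if (length(ids) >= 2) {
      for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
        same <- kept$chrom[i] == kept$chrom[j] &&
          abs(kept$pos[i] - kept$pos[j]) <= 1e7
        if (same) {
          r2 <- ld$r2[(ld$id1 == ids[i] & ld$id2 == ids[j]) |
                        (ld$id1 == ids[j] & ld$id2 == ids[i])]
          expect_lt(max(r2, 0), 0.001)
        }
      }
    }
  }
})

test_that("LD sources validate and missing pairs warn as unlinked", {
  inst <- make_instruments(gamma = c(0.3, 0.28), Gamma = c(0.1, 0.1),
                           pos = c(1e6, 2e6))
  expect_error(ld_clump(inst, tibble::tibble(x = 1)),
               class = "mrshare_config_error")
  expect_error(ld_clump(inst, tibble::tibble(id1 = "a", id2 = "b", r2 = 2)),
               class = "mrshare_config_error")
  partial <- tibble::tibble(id1 = "rs001", id2 = "rs999", r2 = 0.5)
  expect_warning(kept <- ld_clump(inst, partial), "treating r2 as 0")
  expect_equal(nrow(kept), 2)

  m <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
              dimnames = list(inst$variant_id, inst$variant_id))
  expect_equal(nrow(ld_clump(inst, m)), 1)
  expect_error(ld_clump(inst, matrix(1, 2, 2)), class = "mrshare_config_error")
})
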