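# Small in-code fixtures shared across test files.

make_assoc <- function(variant_id, chrom = "1", pos = seq_along(variant_id) * 1e6,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.2, se = 0.02,
                       pval = 2 * pnorm(-abs(beta / se)),
                       trait = "trait", ancestry = "EUR") {
  tibble::tibble(
    variant_id = variant_id, chrom = as.character(chrom), pos = as.integer(pos),
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval,
    trait = trait, ancestry = ancestry
  )
}

make_instruments <- function(gamma, Gamma, se_gamma = 0.02,
                             se_Gamma = 0.05,
                             ids = sprintf("rs%03d", seq_along(gamma)),
                             chrom = "1",
                             pos = seq_along(gamma) * 1e6) {
  n <- length(gamma)
  tibble::tibble(
    variant_id = ids, chrom = rep_len(as.character(chrom), n),
    pos = as.integer(rep_len(pos, n)),
    effect_allele = "A", other_allele = "G",
    gamma = gamma, se_gamma = rep_len(se_gamma, n),
    pval_exposure = 2 * pnorm(-abs(gamma / rep_len(se_gamma, n))),
    Gamma = Gamma, se_Gamma = rep_len(se_Gamma, n),
    eaf_exposure = 0.3, eaf_outcome = 0.3,
    swapped = FALSE, strand_flipped = FALSE, palindromic = FALSE,
    inferred_by_maf = FALSE, dropped_reason = NA_character_
  )
}

# Write an association tibble to a temp TSV (plain dialect) and return the path.
write_assoc_tsv <- function(x, path = withr::local_tempfile(fileext = ".tsv",
                                                            .local_envir = parent.frame())) {
  readr::write_tsv(x, path, progress = FALSE)
  path
}

# Exact hypergeometric upper tail via exact binomial coefficients
# (linear-space rational arithmetic; independent of the log-space path).
hyper_tail_oracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Literal draw enumeration for tiny N: all C(N, n) subsets of a background
# with K marked elements, counting draws with at least k marked.
hyper_tail_enumerate <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the marked ones
  mean(hits >= k)
}
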