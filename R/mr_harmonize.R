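.complement_allele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

#' Is an allele pair palindromic?
#'
#' A single-base variant is palindromic when its two alleles are strand
#' complements of each other ({A,T} or {C,G}), so the reporting strand
#' cannot be resolved from allele labels alone. Multi-base alleles are
#' never classed palindromic (a warning is raised for them).
#'
#' @param effect_allele,other_allele Allele strings.
#' @return Logical vector.
#' @export
classify_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  multi <- nchar(ea) > 1 | nchar(oa) > 1
  if (any(multi)) {
    warn(sprintf("%d multi-base allele pair(s) classed non-palindromic",
                 sum(multi)))
  }
  !multi & ea == .complement_allele(oa)
}

# Core single-variant alignment decision. Returns the orientation action
# and flags; the caller applies sign/eaf changes.
.align_one <- function(ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y,
                       policy, maf_cutoff) {
  res <- list(swap = FALSE, flip = FALSE, palindromic = FALSE,
              inferred = FALSE, reason = NA_character_)
  indel <- nchar(ea_x) > 1 || nchar(oa_x) > 1 ||
    nchar(ea_y) > 1 || nchar(oa_y) > 1
  pal <- !indel && ea_x == .complement_allele(oa_x)
  res$palindromic <- pal

  if (pal) {
    # Complementation maps a palindromic pair onto its own swap, so allele
    # labels alone cannot fix the orientation.
    if (ea_y == ea_x && oa_y == oa_x) {
      res$swap <- FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      res$swap <- TRUE
    } else {
      res$reason <- "incompatible_alleles"
      return(res)
    }
    if (policy == "drop") {
      res$reason <- "palindromic"
      return(res)
    }
    # infer-by-MAF: trust the labels only when both frequencies sit firmly
    # on the same side of the cutoff after label alignment.
    if (is.na(eaf_x) || is.na(eaf_y)) {
      res$reason <- "palindromic_no_eaf"
      return(res)
    }
    eaf_y_aligned <- if (res$swap) 1 - eaf_y else eaf_y
    same_side <- (eaf_x < maf_cutoff && eaf_y_aligned < maf_cutoff) ||
      (eaf_x > 1 - maf_cutoff && eaf_y_aligned > 1 - maf_cutoff)
    if (!same_side) {
      res$reason <- "palindromic_ambiguous"
      return(res)
    }
    res$inferred <- TRUE
    return(res)
  }

  if (ea_y == ea_x && oa_y == oa_x) {
    return(res)
  }
  if (ea_y == oa_x && oa_y == ea_x) {
    res$swap <- TRUE
    return(res)
  }
  if (!indel) {
    cea <- .complement_allele(ea_y)
    coa <- .complement_allele(oa_y)
    if (cea == ea_x && coa == oa_x) {
      res$flip <- TRUE
      return(res)
    }
    if (cea == oa_x && coa == ea_x) {
      res$flip <- TRUE
      res$swap <- TRUE
      return(res)
    }
  }
  res$reason <- "incompatible_alleles"
  res
}

#' Align one exposure/outcome association pair to a common effect allele
#'
#' The exposure record defines the reference orientation. Outcome alleles
#' equal to the exposure's are kept as-is; swapped alleles negate the
#' outcome effect and reflect its frequency; alleles matching only after
#' strand complementation are flagged `strand_flipped` (with the swap rule
#' applied after complementing). Palindromic variants are dropped under the
#' default policy, or retained under `"infer"` only when both effect-allele
#' frequencies fall on the same side of the MAF cutoff. Alignment never
#' changes effect magnitudes or standard errors — only signs and labels.
#'
#' @param exposure,outcome One-row association tibbles sharing `variant_id`.
#' @param policy `"drop"` (default) or `"infer"` for palindromic variants.
#' @param maf_cutoff Minor-allele-frequency cutoff for the infer policy.
#' @return A one-row harmonized-instrument tibble with the exposure effect
#'   (`gamma`, `se_gamma`), the aligned outcome effect (`Gamma`,
#'   `se_Gamma`), frequencies, and flags (`swapped`, `strand_flipped`,
#'   `palindromic`, `inferred_by_maf`, `dropped_reason`).
#' @export
align_pair <- function(exposure, outcome, policy = c("drop", "infer"),
                       maf_cutoff = 0.3) {
  policy <- match.arg(policy)
  if (exposure$variant_id != outcome$variant_id) {
    stop_config("variant ids differ: %s vs %s",
                exposure$variant_id, outcome$variant_id)
  }
  a <- .align_one(toupper(exposure$effect_allele),
                  toupper(exposure$other_allele),
                  toupper(outcome$effect_allele),
                  toupper(outcome$other_allele),
                  exposure$eaf, outcome$eaf, policy, maf_cutoff)
  Gamma <- if (a$swap) -outcome$beta else outcome$beta
  eaf_out <- if (a$swap) 1 - outcome$eaf else outcome$eaf
  tibble(
    variant_id = exposure$variant_id,
    chrom = norm_chrom(exposure$chrom),
    pos = exposure$pos,
    effect_allele = toupper(exposure$effect_allele),
    other_allele = toupper(exposure$other_allele),
    gamma = exposure$beta,
    se_gamma = exposure$se,
    pval_exposure = exposure$pval,
    Gamma = Gamma,
    se_Gamma = outcome$se,
    eaf_exposure = exposure$eaf,
    eaf_outcome = eaf_out,
    swapped = a$swap,
    strand_flipped = a$flip,
    palindromic = a$palindromic,
    inferred_by_maf = a$inferred,
    dropped_reason = a$reason
  )
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two tables on `variant_id`, aligns each matched pair
#' with [align_pair()], and returns the harmonized instruments (retained
#' and dropped, the latter carrying a `dropped_reason`) together with a
#' harmonization report. Output order is deterministic (chromosome,
#' position, id).
#'
#' @param exposure,outcome Association tibbles.
#' @param policy Palindrome policy; see [align_pair()].
#' @param maf_cutoff MAF cutoff for the infer policy.
#' @param strict When `TRUE`, matched pairs must also agree on chromosome
#'   and position; disagreeing pairs are dropped with reason
#'   `"position_mismatch"`.
#' @return A list of class `harmonized_set`: `instruments` (all matched
#'   rows), `retained` (rows entering estimation), and `report` (counts of
#'   kept/swapped/flipped and drops by reason).
#' @export
harmonize_dataset <- function(exposure, outcome, policy = c("drop", "infer"),
                              maf_cutoff = 0.3, strict = FALSE) {
  policy <- match.arg(policy)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) {
    stop_empty("no shared variant ids between exposure and outcome")
  }
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  rows <- lapply(seq_along(shared), function(i) {
    row <- align_pair(ex[i, ], ou[i, ], policy = policy,
                      maf_cutoff = maf_cutoff)
    if (strict && is.na(row$dropped_reason)) {
      same_place <- identical(norm_chrom(ex$chrom[i]), norm_chrom(ou$chrom[i])) &&
        isTRUE(ex$pos[i] == ou$pos[i])
      if (!same_place) row$dropped_reason <- "position_mismatch"
    }
    row
  })
  inst <- dplyr::bind_rows(rows)
  inst <- inst[order(inst$chrom, inst$pos, inst$variant_id), , drop = FALSE]
  retained <- inst[is.na(inst$dropped_reason), , drop = FALSE]
  if (nrow(retained) == 0) {
    stop_empty("no instruments retained after harmonization (drops: %s)",
               paste(unique(inst$dropped_reason), collapse = ", "))
  }
  drop_tab <- table(inst$dropped_reason[!is.na(inst$dropped_reason)])
  report <- list(
    n_exposure = nrow(exposure),
    n_outcome = nrow(outcome),
    n_matched = nrow(inst),
    n_retained = nrow(retained),
    n_swapped = sum(retained$swapped),
    n_strand_flipped = sum(retained$strand_flipped),
    n_inferred_by_maf = sum(retained$inferred_by_maf),
    dropped = tibble(reason = names(drop_tab),
                     n = as.integer(drop_tab)),
    policy = policy,
    maf_cutoff = maf_cutoff
  )
  structure(list(instruments = inst, retained = retained, report = report),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  r <- x$report
  cat(sprintf("<harmonized_set: %d matched, %d retained (%d swapped, %d strand-flipped)>\n",
              r$n_matched, r$n_retained, r$n_swapped, r$n_strand_flipped))
  if (nrow(r$dropped) > 0) {
    cat("  dropped:", paste(sprintf("%s=%d", r$dropped$reason, r$dropped$n),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Clumping configuration
#'
#' @param r2_threshold Pairwise r-squared at or above which a variant is
#'   clumped away by a more significant index variant.
#' @param window Physical window in base pairs around an index variant.
#' @param rank Ranking statistic; only `"pval"` (exposure p-value) is
#'   supported.
#' @return A list of class `clump_config`.
#' @export
clump_config <- function(r2_threshold = 0.001, window = 1e7, rank = "pval") {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop_config("r2_threshold must lie in (0, 1]")
  }
  if (window <= 0) stop_config("window must be positive")
  rank <- match.arg(rank, "pval")
  structure(list(r2_threshold = r2_threshold, window = window, rank = rank),
            class = "clump_config")
}

# Build an r2 lookup function from a square matrix (dimnames = ids) or a
# long table (id1, id2, r2). Missing pairs are treated as r2 = 0.
.ld_lookup <- function(ld, ids) {
  missing_warned <- FALSE
  warn_missing <- function() {
    if (!missing_warned) {
      warn("LD unavailable for some same-chromosome pair(s); treating r2 as 0")
      missing_warned <<- TRUE
    }
  }
  if (is.null(ld)) {
    return(function(i, j) 0)
  }
  if (is.matrix(ld)) {
    if (is.null(rownames(ld)) || is.null(colnames(ld))) {
      stop_config("LD matrix must carry variant ids as dimnames")
    }
    return(function(i, j) {
      if (i %in% rownames(ld) && j %in% colnames(ld)) {
        as.numeric(ld[i, j])
      } else {
        warn_missing()
        0
      }
    })
  }
  if (is.data.frame(ld)) {
    need <- c("id1", "id2", "r2")
    if (!all(need %in% names(ld))) {
      stop_config("long LD table must have columns id1, id2, r2")
    }
    if (any(is.na(ld$r2)) || any(ld$r2 < 0) || any(ld$r2 > 1)) {
      stop_config("LD r2 values must lie in [0, 1]")
    }
    key <- c(paste(ld$id1, ld$id2, sep = "\r"),
             paste(ld$id2, ld$id1, sep = "\r"))
    val <- c(ld$r2, ld$r2)
    lut <- setNames(val, key)
    return(function(i, j) {
      v <- lut[paste(i, j, sep = "\r")]
      if (is.na(v)) {
        warn_missing()
        0
      } else {
        as.numeric(v)
      }
    })
  }
  stop_config("LD must be NULL, a square matrix with id dimnames, or a long table")
}

#' Greedy LD clumping of harmonized instruments
#'
#' Repeatedly takes the unclumped variant with the smallest exposure
#' p-value as the index (ties broken by chromosome, position, id) and
#' removes every unclumped same-chromosome variant within the physical
#' window whose r-squared with the index reaches the threshold. Pairs with
#' no LD information are treated as unlinked (r2 = 0) with a warning.
#'
#' @param instruments Harmonized-instrument tibble (needs `variant_id`,
#'   `chrom`, `pos`, `gamma`, `se_gamma`; `pval_exposure` is computed from
#'   `gamma/se_gamma` when absent).
#' @param ld Pairwise r-squared source: a square matrix with variant-id
#'   dimnames, a long tibble (`id1`, `id2`, `r2`), or `NULL` (no LD — all
#'   variants retained).
#' @param config A [clump_config()].
#' @return The retained instruments, with the removals (variant, index
#'   variant, r2) attached as the `"removed"` attribute.
#' @export
ld_clump <- function(instruments, ld = NULL, config = clump_config()) {
  stopifnot(inherits(config, "clump_config"))
  n <- nrow(instruments)
  if (n == 0) return(instruments)
  p <- instruments$pval_exposure
  if (is.null(p) || all(is.na(p))) {
    p <- 2 * pnorm(-abs(instruments$gamma / instruments$se_gamma))
  }
  r2 <- .ld_lookup(ld, instruments$variant_id)
  ord <- order(p, norm_chrom(instruments$chrom), instruments$pos,
               instruments$variant_id)
  alive <- rep(TRUE, n)
  keep <- rep(FALSE, n)
  removed <- list()
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive &
                    norm_chrom(instruments$chrom) == norm_chrom(instruments$chrom[i]) &
                    abs(instruments$pos - instruments$pos[i]) <= config$window)
    for (j in near) {
      rr <- r2(instruments$variant_id[i], instruments$variant_id[j])
      if (rr >= config$r2_threshold) {
        alive[j] <- FALSE
        removed[[length(removed) + 1]] <- tibble(
          variant_id = instruments$variant_id[j],
          index_id = instruments$variant_id[i],
          r2 = rr
        )
      }
    }
  }
  out <- instruments[keep, , drop = FALSE]
  attr(out, "removed") <- if (length(removed)) dplyr::bind_rows(removed) else
    tibble(variant_id = character(), index_id = character(), r2 = double())
  out
}
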