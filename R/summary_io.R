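#' Column dialects for summary-statistic tables
#'
#' A dialect maps the canonical field names used throughout the package to
#' the column names of a particular tab-delimited export. Two dialects are
#' built in: `"plain"` (beta/se scale, canonical names) and `"or_ci"`
#' (odds-ratio scale with a 95% confidence interval, as many GWAS-catalog
#' style exports report). A custom dialect is a named list mapping canonical
#' names to file column names; `or`/`ci_low`/`ci_high` entries mark an
#' odds-ratio-scale input.
#'
#' @param name `"plain"`, `"or_ci"`, or a named list as described above.
#' @return A named list mapping canonical field names to file columns.
#' @export
association_dialect <- function(name = "plain") {
  if (is.list(name)) {
    if (is.null(names(name)) || any(!nzchar(names(name)))) {
      stop_config("a custom dialect must be a fully named list")
    }
    return(name)
  }
  builtin <- list(
    plain = list(
      variant_id = "variant_id", chrom = "chrom", pos = "pos",
      effect_allele = "effect_allele", other_allele = "other_allele",
      eaf = "eaf", beta = "beta", se = "se", pval = "pval",
      trait = "trait", ancestry = "ancestry"
    ),
    or_ci = list(
      variant_id = "variant_id", chrom = "chrom", pos = "pos",
      effect_allele = "effect_allele", other_allele = "other_allele",
      eaf = "eaf", or = "odds_ratio", ci_low = "ci_lower",
      ci_high = "ci_upper", pval = "pval",
      trait = "trait", ancestry = "ancestry"
    )
  )
  if (!name %in% names(builtin)) {
    stop_config("unknown dialect '%s' (built-in: %s)",
                name, paste(names(builtin), collapse = ", "))
  }
  builtin[[name]]
}

#' Load a column dialect from a YAML file
#'
#' @param path Path to a YAML file whose top level maps canonical field
#'   names to file column names.
#' @return A dialect list as for [association_dialect()].
#' @export
read_dialect_yaml <- function(path) {
  if (!file.exists(path)) stop_config("dialect file not found: %s", path)
  association_dialect(yaml::read_yaml(path))
}

.canonical_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pval",
                     "trait", "ancestry")

.valid_allele <- function(a) {
  grepl("^[ACGT]+$", toupper(a))
}

#' Read GWAS variant associations from a tab-delimited file
#'
#' Reads one association record per data row. Odds-ratio-scale inputs are
#' converted to the log-odds (beta) scale: `beta = ln(OR)` and
#' `se = (ln(upper) - ln(lower)) / (2 * 1.96)` from the 95% CI; when only an
#' OR and a p-value are available the fallback `se = |ln(OR)| / |qnorm(p/2)|`
#' is used. Rows with unparseable alleles, identical effect/other alleles,
#' non-positive standard errors, or out-of-range p-values are rejected with
#' a row-numbered warning and excluded from the result.
#'
#' @param path Path to a tab-delimited file with a header row. Lines
#'   starting with `#` are treated as comments.
#' @param dialect Column dialect; see [association_dialect()].
#' @param strict_consistency When `TRUE`, additionally reject rows whose
#'   reported p-value disagrees with `2 * pnorm(-|beta/se|)` by more than
#'   a factor of 10 (published tables round, so this is off by default).
#' @return A tibble of validated associations on the beta scale with
#'   canonical columns (`variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `trait`, `ancestry`).
#'   Rejected rows are attached as the `"rejected"` attribute.
#' @export
read_associations <- function(path, dialect = "plain",
                              strict_consistency = FALSE) {
  if (!file.exists(path)) stop_config("association file not found: %s", path)
  map <- association_dialect(dialect)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) stop_empty("no data rows in %s", path)

  or_scale <- "or" %in% names(map)
  mandatory <- c("variant_id", "effect_allele", "other_allele",
                 if (or_scale) "or" else c("beta", "se"))
  missing_cols <- vapply(mandatory, function(f) {
    is.null(map[[f]]) || !(map[[f]] %in% names(raw))
  }, logical(1))
  if (any(missing_cols)) {
    stop_config("mandatory column(s) missing from %s: %s", path,
                paste(unlist(map[mandatory[missing_cols]]), collapse = ", "))
  }

  pick <- function(field) {
    col <- map[[field]]
    if (is.null(col) || !(col %in% names(raw))) {
      return(rep(NA_character_, nrow(raw)))
    }
    raw[[col]]
  }
  num <- function(field) suppressWarnings(as.numeric(pick(field)))

  out <- tibble(
    variant_id = pick("variant_id"),
    chrom = norm_chrom(pick("chrom")),
    pos = suppressWarnings(as.integer(num("pos"))),
    effect_allele = toupper(pick("effect_allele")),
    other_allele = toupper(pick("other_allele")),
    eaf = num("eaf"),
    pval = num("pval"),
    trait = pick("trait"),
    ancestry = pick("ancestry")
  )

  if (or_scale) {
    or <- num("or")
    lo <- num("ci_low")
    hi <- num("ci_high")
    out$beta <- log(or)
    out$se <- ifelse(
      !is.na(lo) & !is.na(hi),
      (log(hi) - log(lo)) / (2 * 1.96),
      abs(log(or)) / abs(qnorm(out$pval / 2))
    )
  } else {
    out$beta <- num("beta")
    out$se <- num("se")
  }
  out <- out[, .canonical_cols]

  reasons <- character(nrow(out))
  flag <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }
  flag(is.na(out$variant_id) | !nzchar(out$variant_id), "missing variant id")
  flag(!.valid_allele(out$effect_allele) | !.valid_allele(out$other_allele),
       "unparseable allele")
  flag(out$effect_allele == out$other_allele,
       "effect allele equals other allele")
  flag(is.na(out$beta), "missing or unparseable effect")
  flag(is.na(out$se) | out$se <= 0, "missing or non-positive se")
  flag(!is.na(out$pos) & out$pos < 1, "position < 1")
  flag(!is.na(out$pval) & (out$pval <= 0 | out$pval > 1), "p-value outside (0,1]")
  flag(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1), "eaf outside [0,1]")
  if (strict_consistency) {
    implied <- 2 * pnorm(-abs(out$beta / out$se))
    off <- !is.na(out$pval) & !is.na(implied) & implied > 0 &
      abs(log10(out$pval) - log10(implied)) > 1
    flag(off, "p-value inconsistent with beta/se")
  }

  bad <- nzchar(reasons)
  if (any(bad)) {
    for (i in which(bad)) {
      warn(sprintf("row %d rejected: %s", i, reasons[i]))
    }
  }
  kept <- out[!bad, , drop = FALSE]
  attr(kept, "rejected") <- tibble(row = which(bad), reason = reasons[bad])
  kept
}

#' Write associations to a tab-delimited file
#'
#' Writes the canonical columns with a commented provenance header line so
#' that [read_associations()] round-trips the table exactly.
#'
#' @param x Association tibble with canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(x, path) {
  header <- sprintf("# mrshare %s | associations | written %s",
                    as.character(utils::packageVersion("mrshare")),
                    format(Sys.time(), "%Y-%m-%d"))
  writeLines(header, path)
  readr::write_tsv(x[, .canonical_cols], path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Convert a log-odds effect to the odds-ratio scale
#'
#' Given an effect on the log-odds scale and its standard error, computes
#' the Z score `z = beta/se`, the two-sided p-value `p = 2 * pnorm(-|z|)`,
#' the odds ratio `exp(beta)` and its Wald 95% confidence interval
#' `exp(beta -/+ 1.96 * se)`. The log of the p-value is carried alongside so
#' that p-values below double-precision underflow remain usable; see
#' [format_pval()].
#'
#' @param beta Log odds ratio(s).
#' @param se Standard error(s) of `beta`; must be positive.
#' @return A tibble with columns `beta`, `se`, `z`, `p`, `log_p`,
#'   `odds_ratio`, `ci_low`, `ci_high`.
#' @examples
#' effect_transform(0.94, 0.13) # OR 2.56, 95% CI 1.98-3.30
#' @export
effect_transform <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_domain("se must be positive and finite")
  }
  z <- beta / se
  log_p <- pnorm(-abs(z), log.p = TRUE) + log(2)
  tibble(
    beta = beta, se = se, z = z,
    p = exp(log_p), log_p = log_p,
    odds_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se)
  )
}

#' Invert the odds-ratio scale back to beta/se
#'
#' @param odds_ratio Odds ratio(s).
#' @param ci_low,ci_high Limits of the 95% confidence interval of the OR.
#' @return A tibble with columns `beta` and `se`.
#' @export
effect_from_or <- function(odds_ratio, ci_low, ci_high) {
  if (any(odds_ratio <= 0) || any(ci_low <= 0) || any(ci_high <= 0)) {
    stop_domain("odds ratios and CI limits must be positive")
  }
  tibble(beta = log(odds_ratio),
         se = (log(ci_high) - log(ci_low)) / (2 * 1.96))
}

#' Format a p-value for display
#'
#' Values whose log is below `log(1e-300)` print as `"<1e-300"`; otherwise
#' the value prints with 2 significant figures.
#'
#' @param p P-value(s).
#' @param log_p Optional natural-log p-values (used when `p` underflows).
#' @return Character vector.
#' @export
format_pval <- function(p, log_p = log(p)) {
  ifelse(log_p < log(1e-300), "<1e-300",
         format(signif(exp(log_p), 2), scientific = TRUE))
}

#' Keep genome-wide significant associations
#'
#' Retains records with `pval` strictly below the threshold (the
#' conventional genome-wide significance cutoff of 5.0e-8 by default),
#' preserving input order. Records with missing p-values are dropped.
#'
#' @param records Association tibble.
#' @param threshold Significance threshold in (0, 1).
#' @return Filtered tibble.
#' @export
filter_genome_wide <- function(records, threshold = 5.0e-8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_config("threshold must lie in (0, 1)")
  }
  keep <- !is.na(records$pval) & records$pval < threshold
  records[keep, , drop = FALSE]
}

#' Remove variants on an explicit exclusion list
#'
#' A mechanical replacement for manual regional-plot QC: variants judged to
#' violate the relevance condition are listed by id and removed, with one
#' log line per removal stating the supplied reason.
#'
#' @param records Association tibble.
#' @param excluded_ids Character vector of variant ids to drop.
#' @param reason Reason label recorded with each removal.
#' @return The records with excluded ids removed; the removals are attached
#'   as the `"excluded"` attribute.
#' @export
apply_exclusion_list <- function(records, excluded_ids,
                                 reason = "manual exclusion") {
  excluded_ids <- unique(as.character(excluded_ids))
  hit <- records$variant_id %in% excluded_ids
  for (id in records$variant_id[hit]) {
    inform(sprintf("excluding %s: %s", id, reason))
  }
  absent <- setdiff(excluded_ids, records$variant_id)
  if (length(absent) > 0) {
    warn(sprintf("exclusion id(s) not present in records: %s",
                 paste(absent, collapse = ", ")))
  }
  out <- records[!hit, , drop = FALSE]
  attr(out, "excluded") <- tibble(variant_id = records$variant_id[hit],
                                  reason = reason)
  out
}

#' Construct a gene list
#'
#' Symbols are case-normalized to upper case and de-duplicated, preserving
#' first-occurrence order.
#'
#' @param name Label for the list.
#' @param symbols Character vector of gene symbols.
#' @return An object of class `gene_list` with fields `name` and `symbols`.
#' @export
gene_list <- function(name, symbols) {
  symbols <- toupper(as.character(symbols))
  symbols <- symbols[nzchar(symbols)]
  dup <- duplicated(symbols)
  if (any(dup)) {
    warn(sprintf("%d duplicate symbol(s) dropped from '%s'", sum(dup), name))
  }
  structure(list(name = name, symbols = symbols[!dup]),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list '%s': %d symbols>\n", x$name, length(x$symbols)))
  cat(" ", paste(head(x$symbols, 8), collapse = ", "),
      if (length(x$symbols) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a gene list from a plain-text file
#'
#' One symbol per line; blank lines and `#` comments are skipped.
#'
#' @param path Path to the file.
#' @param name List label; defaults to the file name.
#' @return A [gene_list()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop_config("gene-list file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop_empty("no symbols in %s", path)
  gene_list(name, lines)
}
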