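# TSV writer with a commented provenance header (tool version, config
# hash, seed) so every output file is self-describing.
.write_report_tsv <- function(x, path, manifest) {
  writeLines(sprintf("# mrshare %s | config_hash=%s | seed=%s",
                     manifest$version, manifest$config_hash,
                     manifest$seed %||% "NA"), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

.manifest <- function(settings, seed) {
  list(
    version = as.character(utils::packageVersion("mrshare")),
    seed = seed,
    config_hash = rlang::hash(settings),
    settings = settings
  )
}

#' Gene-list overlap report
#'
#' Runs [enrich_gene_lists()] and formats a display row (expected overlap,
#' fold enrichment, upper-tail hypergeometric p); optionally writes the
#' row as TSV and the full result as JSON.
#'
#' @param query,subject Gene lists (objects or character vectors).
#' @param background_size Background gene count.
#' @param label Row label.
#' @param out_dir Optional output directory.
#' @return A list with `result`, `shared`, `table` (display row), and
#'   `manifest`.
#' @export
run_overlap_report <- function(query, subject, background_size = 19303,
                               label = "gene_overlap", out_dir = NULL) {
  enr <- enrich_gene_lists(query, subject, background_size)
  table <- format_enrichment(enr$result, label)
  manifest <- .manifest(list(background_size = background_size,
                             label = label), seed = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_report_tsv(table, file.path(out_dir, "overlap_genes.tsv"), manifest)
    jsonlite::write_json(
      list(manifest = manifest[c("version", "seed", "config_hash", "settings")],
           result = enr$result, shared = enr$shared),
      file.path(out_dir, "overlap_genes.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(result = enr$result, shared = enr$shared, table = table,
       manifest = manifest)
}

#' Genomic risk-interval overlap report
#'
#' Builds proximity-merged loci for both variant sets, forms lead-variant
#' windows, counts query windows overlapping any subject window, and tests
#' the count against the genome-block hypergeometric background.
#'
#' @param query_records,subject_records Association tibbles.
#' @param merge_gap Locus merge gap in bp.
#' @param window_size Window width in bp.
#' @param genome_length Genome length used for the block background.
#' @param label Row label.
#' @param out_dir Optional output directory.
#' @return A list with the loci, windows, overlap pairs, enrichment
#'   result, display `table`, and `manifest`.
#' @export
run_locus_overlap_report <- function(query_records, subject_records,
                                     merge_gap = 250000,
                                     window_size = 500000,
                                     genome_length = 3298912062,
                                     label = "locus_overlap",
                                     out_dir = NULL) {
  qloci <- build_loci(query_records, merge_gap = merge_gap)
  sloci <- build_loci(subject_records, merge_gap = merge_gap)
  qwin <- make_windows(qloci, window_size = window_size)
  swin <- make_windows(sloci, window_size = window_size)
  ov <- count_window_overlaps(qwin, swin)
  N <- genome_block_count(genome_length, window_size)
  res <- hypergeom_enrichment(ov$k, nrow(qwin), nrow(swin), N)
  table <- format_enrichment(res, label)
  settings <- list(merge_gap = merge_gap, window_size = window_size,
                   genome_length = genome_length, label = label)
  manifest <- .manifest(settings, seed = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_report_tsv(table, file.path(out_dir, "overlap_loci.tsv"), manifest)
    loci_to_bed(qwin, file.path(out_dir, "query_windows.bed"))
    loci_to_bed(swin, file.path(out_dir, "subject_windows.bed"))
    jsonlite::write_json(
      list(manifest = manifest[c("version", "seed", "config_hash", "settings")],
           result = res, k = ov$k,
           n_query_windows = nrow(qwin), n_subject_windows = nrow(swin)),
      file.path(out_dir, "overlap_loci.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(query_loci = qloci, subject_loci = sloci,
       query_windows = qwin, subject_windows = swin,
       overlap = ov, result = res, table = table, manifest = manifest)
}

#' Full two-sample MR pipeline report
#'
#' Composes the analysis stages exactly as calling them individually:
#' genome-wide filtering of the exposure, explicit instrument exclusions,
#' harmonization to a common effect allele, LD clumping, then the
#' four-method MR suite with heterogeneity, intercept, and sensitivity
#' tables. When an output directory is given, every table is written as
#' TSV with a provenance header plus a JSON manifest listing all settings,
#' the seed, and every dropped variant with its reason.
#'
#' @param exposure,outcome Association tibbles.
#' @param ld Optional pairwise r-squared source for [ld_clump()].
#' @param exclude Character vector of variant ids to exclude (relevance-QC
#'   list).
#' @param sig_threshold Exposure significance threshold.
#' @param palindrome_policy `"drop"` or `"infer"`.
#' @param maf_cutoff MAF cutoff for the infer policy.
#' @param clump A [clump_config()].
#' @param model IVW model.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Seed for all stochastic steps.
#' @param out_dir Optional output directory.
#' @return A list with `results` (an `mr_result_set`), `harmonization`,
#'   `instruments` (post-clump), `clump_removed`, and `manifest`.
#' @export
run_mr_report <- function(exposure, outcome, ld = NULL, exclude = NULL,
                          sig_threshold = 5e-8,
                          palindrome_policy = c("drop", "infer"),
                          maf_cutoff = 0.3, clump = clump_config(),
                          model = c("mre", "fixed"), n_boot = 1000,
                          seed = NULL, out_dir = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  model <- match.arg(model)

  sig <- filter_genome_wide(exposure, threshold = sig_threshold)
  if (nrow(sig) == 0) stop_empty("no exposure variants pass %g", sig_threshold)
  if (!is.null(exclude) && length(exclude) > 0) {
    sig <- apply_exclusion_list(sig, exclude, reason = "relevance QC")
  }
  harm <- harmonize_dataset(sig, outcome, policy = palindrome_policy,
                            maf_cutoff = maf_cutoff)
  inst <- ld_clump(harm$retained, ld = ld, config = clump)
  results <- mr_run_all(inst, model = model, n_boot = n_boot, seed = seed)

  dropped <- harm$instruments[!is.na(harm$instruments$dropped_reason),
                              c("variant_id", "dropped_reason")]
  excluded <- attr(sig, "excluded") %||%
    tibble(variant_id = character(), reason = character())
  clump_removed <- attr(inst, "removed")

  settings <- list(
    sig_threshold = sig_threshold, palindrome_policy = palindrome_policy,
    maf_cutoff = maf_cutoff, clump_r2 = clump$r2_threshold,
    clump_window = clump$window, model = model, n_boot = n_boot
  )
  manifest <- .manifest(settings, seed)
  manifest$dropped <- dplyr::bind_rows(
    tibble(variant_id = excluded$variant_id, stage = "exclusion_list",
           reason = excluded$reason),
    tibble(variant_id = dropped$variant_id, stage = "harmonization",
           reason = dropped$dropped_reason),
    tibble(variant_id = clump_removed$variant_id, stage = "clumping",
           reason = sprintf("clumped by %s (r2=%.3g)",
                            clump_removed$index_id, clump_removed$r2))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_report_tsv(results$estimates,
                      file.path(out_dir, "mr_methods.tsv"), manifest)
    if (!is.null(results$heterogeneity)) {
      .write_report_tsv(results$heterogeneity,
                        file.path(out_dir, "heterogeneity.tsv"), manifest)
    }
    if (!is.null(results$egger_intercept)) {
      .write_report_tsv(results$egger_intercept,
                        file.path(out_dir, "egger_intercept.tsv"), manifest)
    }
    if (!is.null(results$sensitivity)) {
      s <- results$sensitivity
      .write_report_tsv(s$leave_one_out,
                        file.path(out_dir, "leave_one_out.tsv"), manifest)
      .write_report_tsv(s$single_snp,
                        file.path(out_dir, "single_snp.tsv"), manifest)
      .write_report_tsv(s$funnel, file.path(out_dir, "funnel.tsv"), manifest)
      .write_report_tsv(s$scatter, file.path(out_dir, "scatter.tsv"),
                        manifest)
      .write_report_tsv(s$fits, file.path(out_dir, "scatter_fits.tsv"),
                        manifest)
    }
    .write_report_tsv(
      tibble(metric = c("n_exposure", "n_outcome", "n_matched", "n_retained",
                        "n_swapped", "n_strand_flipped", "n_inferred_by_maf",
                        "n_clumped_away", "n_analysed"),
             value = c(harm$report$n_exposure, harm$report$n_outcome,
                       harm$report$n_matched, harm$report$n_retained,
                       harm$report$n_swapped, harm$report$n_strand_flipped,
                       harm$report$n_inferred_by_maf,
                       nrow(clump_removed), nrow(inst))),
      file.path(out_dir, "harmonization_report.tsv"), manifest)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(results = results, harmonization = harm, instruments = inst,
       clump_removed = clump_removed, manifest = manifest)
}
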