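#!/usr/bin/env Rscript

# Run the full two-sample MR pipeline on each simulated dataset written by
# 02_simulate_gwas.R: genome-wide filtering, harmonization (palindromes
# dropped), LD clumping (no LD table here, so all independent), and the
# four-method suite with heterogeneity, Egger intercept, and sensitivity
# tables. Reports land under results/mr/<scenario>/.

suppressPackageStartupMessages(library(mrshare))

sim_dir <- "results/sim"
if (!file.exists(file.path(sim_dir, "analysis1_exposure.tsv"))) {
  stop("run analysis/02_simulate_gwas.R first", call. = FALSE)
}

for (name in c("analysis1", "analysis2", "analysis3", "analysis4")) {
  exposure <- read_associations(file.path(sim_dir, paste0(name, "_exposure.tsv")))
  outcome <- read_associations(file.path(sim_dir, paste0(name, "_outcome.tsv")))
  out_dir <- file.path("results/mr", name)
  rep <- suppressMessages(run_mr_report(exposure, outcome,
                                        n_boot = 1000, seed = 42,
                                        out_dir = out_dir))
  truth <- jsonlite::read_json(file.path(sim_dir, paste0(name, "_truth.json")))

  message(sprintf("\n== %s (true effect %.2f, %d instruments analysed) ==",
                  name, truth$theta, rep$results$n_snps))
  print(rep$results)
  if (!is.null(rep$results$egger_intercept)) {
    ic <- rep$results$egger_intercept
    message(sprintf("Egger intercept %.3f (se %.3f, p %.3g)",
                    ic$intercept, ic$se, ic$p))
  }
  het <- rep$results$heterogeneity
  if (!is.null(het)) {
    message(sprintf("Cochran's Q (IVW): %.2f on %d df (p %.3g)",
                    het$Q[1], het$df[1], het$p[1]))
  }
}

message("\nWrote MR reports under results/mr/")
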