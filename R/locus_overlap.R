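#' Merge associated variants into loci by proximity
#'
#' Records are sorted by (chromosome, position); adjacent records on the
#' same chromosome whose positions differ by at most `merge_gap` base pairs
#' are merged transitively into one locus ("any sequence of adjacent
#' associated variants" within the gap). Each locus reports its lead
#' variant, the member with the smallest p-value (ties broken by position,
#' then id).
#'
#' @param records Association tibble with at least `variant_id`, `chrom`,
#'   `pos`; `pval` is used to pick the lead (missing p-values rank last).
#' @param merge_gap Maximum gap in base pairs between adjacent members;
#'   the comparison is inclusive (a gap of exactly `merge_gap` merges).
#' @return A tibble of loci with columns `chrom`, `start`, `end` (1-based,
#'   closed), `lead_id`, `lead_pos`, `lead_pval`, `n_members`, and a
#'   `member_ids` list-column.
#' @export
build_loci <- function(records, merge_gap = 250000) {
  if (merge_gap < 0) stop_config("merge_gap must be non-negative")
  bad <- is.na(records$pos) | is.na(records$chrom) | !nzchar(records$chrom)
  if (any(bad)) {
    for (i in which(bad)) {
      warn(sprintf("record %d (%s) rejected: missing chromosome or position",
                   i, records$variant_id[i] %||% "?"))
    }
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  lead_id = character(), lead_pos = integer(),
                  lead_pval = double(), n_members = integer(),
                  member_ids = list()))
  }
  records$chrom <- norm_chrom(records$chrom)
  ord <- order(records$chrom, records$pos, records$variant_id)
  records <- records[ord, , drop = FALSE]
  new_locus <- c(TRUE, records$chrom[-1] != records$chrom[-nrow(records)] |
                   diff(records$pos) > merge_gap)
  grp <- cumsum(new_locus)
  pv <- records$pval
  if (is.null(pv)) pv <- rep(NA_real_, nrow(records))
  pieces <- lapply(split(seq_len(nrow(records)), grp), function(idx) {
    m <- records[idx, , drop = FALSE]
    p <- pv[idx]
    rank_p <- ifelse(is.na(p), Inf, p)
    lead <- idx[order(rank_p, m$pos, m$variant_id)][1] - idx[1] + 1
    tibble(
      chrom = m$chrom[1],
      start = min(m$pos), end = max(m$pos),
      lead_id = m$variant_id[lead],
      lead_pos = m$pos[lead],
      lead_pval = p[lead],
      n_members = nrow(m),
      member_ids = list(m$variant_id)
    )
  })
  dplyr::bind_rows(pieces)
}

#' Build fixed-width windows centered on locus lead variants
#'
#' One half-open window `[start, end)` per locus, centered on the lead
#' variant position and clipped at zero on the left (so a lead close to the
#' chromosome start yields a shorter window; the right edge is always
#' `center + window_size/2`).
#'
#' @param loci Locus tibble from [build_loci()], or any tibble with
#'   `chrom` and `lead_pos` columns.
#' @param window_size Window width in base pairs; must be positive and even.
#' @return A tibble of windows with columns `chrom`, `start`, `end`
#'   (0-based half-open), `center`, `lead_id`.
#' @export
make_windows <- function(loci, window_size = 500000) {
  if (window_size <= 0 || window_size %% 2 != 0) {
    stop_config("window_size must be positive and even")
  }
  half <- window_size / 2
  tibble(
    chrom = norm_chrom(loci$chrom),
    start = pmax(0, loci$lead_pos - half),
    end = loci$lead_pos + half,
    center = loci$lead_pos,
    lead_id = if ("lead_id" %in% names(loci)) loci$lead_id else
      sprintf("window_%d", seq_len(nrow(loci)))
  )
}

#' Count query windows that overlap any subject window
#'
#' Windows are half-open intervals; two windows overlap iff they share a
#' chromosome and their intervals intersect (abutting windows do not
#' overlap). `k` counts windows in `a` that intersect at least one window
#' in `b` — the quantity drawn in the hypergeometric enrichment — and the
#' pair list enumerates every intersecting pair.
#'
#' @param a,b Window tibbles from [make_windows()].
#' @return A list with `k` (integer) and `pairs`, a tibble of
#'   (`a_index`, `b_index`, `a_lead`, `b_lead`) for every intersecting pair.
#' @export
count_window_overlaps <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(k = 0L, pairs = tibble(a_index = integer(),
                                       b_index = integer(),
                                       a_lead = character(),
                                       b_lead = character())))
  }
  ai <- tibble(a_index = seq_len(nrow(a)), chrom = norm_chrom(a$chrom),
               a_start = a$start, a_end = a$end, a_lead = a$lead_id)
  bi <- tibble(b_index = seq_len(nrow(b)), chrom = norm_chrom(b$chrom),
               b_start = b$start, b_end = b$end, b_lead = b$lead_id)
  joined <- dplyr::inner_join(ai, bi, by = "chrom",
                              relationship = "many-to-many")
  hit <- joined[joined$a_start < joined$b_end &
                  joined$b_start < joined$a_end, , drop = FALSE]
  pairs <- hit[order(hit$a_index, hit$b_index),
               c("a_index", "b_index", "a_lead", "b_lead")]
  list(k = length(unique(pairs$a_index)), pairs = as_tibble(pairs))
}

#' Number of fixed-width blocks in a genome
#'
#' Divides the genome length by the block size and rounds to the nearest
#' integer (halves away from zero). With the GRCh38.p14 total of
#' 3,298,912,062 bp and 500 kb blocks this gives the 6598-block background
#' used for locus-overlap enrichment.
#'
#' @param genome_length Total genome length in base pairs.
#' @param block Block width in base pairs.
#' @return Integer block count.
#' @examples
#' genome_block_count() # 6598
#' @export
genome_block_count <- function(genome_length = 3298912062, block = 500000) {
  if (genome_length <= 0 || block <= 0) {
    stop_domain("genome_length and block must be positive")
  }
  as.integer(round_half_away(genome_length / block))
}

#' Convert loci or windows to BED records
#'
#' Loci (1-based, closed) are shifted to the BED 0-based half-open
#' convention (`start - 1`); windows are already half-open and pass through
#' unchanged.
#'
#' @param x A locus tibble from [build_loci()] or a window tibble from
#'   [make_windows()].
#' @param path Optional output path; when given, a BED file with a comment
#'   header is written.
#' @return A tibble with BED3+name columns (`chrom`, `start`, `end`,
#'   `name`), invisibly when `path` is given.
#' @export
loci_to_bed <- function(x, path = NULL) {
  is_window <- "center" %in% names(x)
  if (nrow(x) == 0) {
    bed <- tibble(chrom = character(), start = integer(),
                  end = integer(), name = character())
  } else {
    bed <- tibble(
      chrom = paste0("chr", norm_chrom(x$chrom)),
      start = if (is_window) x$start else x$start - 1,
      end = x$end,
      name = x$lead_id %||% sprintf("region_%d", seq_len(nrow(x)))
    )
  }
  if (!is.null(path)) {
    writeLines(sprintf("# mrshare %s | BED 0-based half-open",
                       as.character(utils::packageVersion("mrshare"))), path)
    if (nrow(bed) > 0) {
      readr::write_tsv(bed, path, append = TRUE, col_names = FALSE,
                       progress = FALSE)
    }
    return(invisible(bed))
  }
  bed
}
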