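# Log upper-tail of the hypergeometric distribution, summed in log space
# via lchoose so tails down to ~1e-300 do not underflow.
.log_hyper_tail <- function(k, n, K, N) {
  if (k <= 0) return(0)
  i <- k:min(n, K)
  terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

#' Hypergeometric over-representation statistic
#'
#' For a background of `N` elements of which `K` are marked, and a query
#' draw of `n` elements of which `k` are observed marked, computes the
#' expected overlap `n*K/N`, the fold enrichment `k/expected`, and the
#' inclusive upper-tail probability `P(X >= k)` under
#' Hypergeometric(N, K, n). The tail is accumulated in log space with
#' log-binomial coefficients, so p-values remain exact down to the
#' double-precision floor.
#'
#' @param k Observed overlap count.
#' @param n Query set size.
#' @param K Subject (marked) set size.
#' @param N Background size.
#' @return A one-row tibble with `k`, `n`, `K`, `N`, `expected`, `fold`,
#'   `p_upper` and `log_p`.
#' @examples
#' hypergeom_enrichment(3, 23, 54, 19303) # p approx 3.6e-5
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != trunc(vals))) {
    stop_domain("k, n, K, N must be non-negative integers")
  }
  if (n > N || K > N) stop_domain("n and K must not exceed N")
  if (k > min(n, K)) stop_domain("k must not exceed min(n, K)")
  expected <- expected_overlap(n, K, N)
  log_p <- .log_hyper_tail(k, n, K, N)
  tibble(
    k = as.integer(k), n = as.integer(n),
    K = as.integer(K), N = as.integer(N),
    expected = expected,
    fold = if (expected > 0) k / expected else NA_real_,
    p_upper = min(1, exp(log_p)),
    log_p = min(0, log_p)
  )
}

#' Expected overlap under random draws
#'
#' @param n Query set size.
#' @param K Subject set size.
#' @param N Background size; must be positive.
#' @return `n * K / N`.
#' @examples
#' expected_overlap(23, 54, 19303) # 0.064..., displays as 0.06
#' @export
expected_overlap <- function(n, K, N) {
  if (N <= 0) stop_domain("background size N must be positive")
  if (n > N || K > N) stop_domain("n and K must not exceed N")
  n * K / N
}

#' Gene-list overlap enrichment
#'
#' Intersects two gene lists after case normalization and tests the overlap
#' against a hypergeometric background (by default the 19,303 genes of a
#' whole-proteome interaction network, the background the gene lists were
#' drawn from).
#'
#' @param query,subject [gene_list()] objects or character vectors.
#' @param background_size Background gene count; must be at least the size
#'   of the union of the two lists.
#' @return A list with `result` (the [hypergeom_enrichment()] row) and
#'   `shared` (the intersecting symbols).
#' @export
enrich_gene_lists <- function(query, subject, background_size = 19303) {
  qs <- if (inherits(query, "gene_list")) query$symbols else
    gene_list("query", query)$symbols
  ss <- if (inherits(subject, "gene_list")) subject$symbols else
    gene_list("subject", subject)$symbols
  if (background_size < length(union(qs, ss))) {
    stop_domain("background_size (%d) smaller than the union of the lists (%d)",
                background_size, length(union(qs, ss)))
  }
  shared <- intersect(qs, ss)
  list(
    result = hypergeom_enrichment(length(shared), length(qs), length(ss),
                                  background_size),
    shared = shared
  )
}

#' Format an enrichment result for display
#'
#' Fixed-point display convention: expected overlap to 2 decimals, fold to
#' the nearest integer-free 3 significant figures, p to 2 significant
#' figures.
#'
#' @param res A row from [hypergeom_enrichment()].
#' @param label Row label (e.g. the subject network name).
#' @return A one-row tibble with character columns `network`, `expected`,
#'   `fold`, `p`.
#' @export
format_enrichment <- function(res, label = "overlap") {
  tibble(
    network = label,
    expected = sprintf("%.2f", res$expected),
    fold = format(signif(res$fold, 3)),
    p = format_pval(res$p_upper, res$log_p)
  )
}
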