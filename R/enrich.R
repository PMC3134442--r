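#' Exact hypergeometric over/under-representation p-value
#'
#' Tail probability of drawing `k` annotated genes in a target of size `n`
#' from a background of `N` genes of which `K` are annotated, under
#' sampling without replacement. `direction = "over"` gives
#' `P(X >= k)`, `"under"` gives `P(X <= k)`, with
#' `X ~ Hypergeometric(N, K, n)`. The tail is an exact summation of density
#' terms accumulated in log space.
#'
#' @param k observed annotated genes in the target (vectorized).
#' @param K annotated genes in the background.
#' @param n target size.
#' @param N background size.
#' @param direction `"over"` (default) or `"under"`.
#' @return Numeric vector of p-values in (0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (any(K > N) || any(n > N) || any(K < 0) || any(n < 0) || any(N < 1)) {
    stop_invalid_input("require 0 <= K <= N, 0 <= n <= N, N >= 1")
  }
  args <- vctrs_recycle(k, K, n, N)
  if (any(args$k < 0) || any(args$k > pmin(args$n, args$K))) {
    stop_invalid_input("require 0 <= k <= min(n, K)")
  }
  purrr::pmap_dbl(args, function(k, K, n, N) {
    lo <- max(0, n - (N - K)) # smallest attainable overlap
    hi <- min(n, K)
    if (direction == "over" && k <= lo) {
      return(1)
    }
    if (direction == "under" && k < lo) {
      return(0)
    }
    j <- if (direction == "over") max(k, lo):hi else lo:k
    logs <- stats::dhyper(j, K, N - K, n, log = TRUE)
    mx <- max(logs)
    min(exp(mx + log(sum(exp(logs - mx)))), 1)
  })
}

# minimal common-length recycling for scalar-or-vector args
vctrs_recycle <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  list(
    k = rep_len(k, len), K = rep_len(K, len),
    n = rep_len(n, len), N = rep_len(N, len)
  )
}

#' Fold enrichment of an annotation in a target set
#'
#' Ratio of the annotation's frequency in the target set to its frequency
#' in the background: `(k/n) / (K/N)`.
#'
#' @inheritParams hypergeom_pvalue
#' @return Numeric vector of fold enrichments (>= 0).
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) {
    stop_invalid_input("`n`, `K` and `N` must be positive")
  }
  (k / n) / (K / N)
}

#' Annotation-term enrichment of a target set
#'
#' Tests every annotation term for over- (or under-) representation among
#' target genes relative to a background gene set, with the exact
#' hypergeometric test. The background is typically either the whole
#' genome or the translatome (the ribosomal-bait target set).
#'
#' @param annotations data frame with columns `gene_id` and `term` (one row
#'   per assignment); only assignments to background genes count.
#' @param targets target set (character vector), a subset of `background`.
#' @param background character vector of background gene ids.
#' @param alpha significance level on the (optionally adjusted) p-value
#'   (default 0.01, raw p).
#' @param direction `"over"` (default) or `"under"`.
#' @param p_adjust multiple-testing adjustment: `"none"` (default,
#'   matching the raw-p convention of classical GO term finders),
#'   `"bonferroni"` or `"BH"`.
#' @return Tibble with one row per term annotated in the background:
#'   `term`, `k`, `n`, `K`, `N`, `fold`, `p`, `p_adj`, `significant`,
#'   `direction`; sorted by ascending p (ties by term).
#' @export
enrich_terms <- function(annotations, targets, background, alpha = 0.01,
                         direction = c("over", "under"),
                         p_adjust = c("none", "bonferroni", "BH")) {
  direction <- match.arg(direction)
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(c("gene_id", "term") %in% names(annotations)))
  targets <- unique(as.character(targets))
  background <- unique(as.character(background))
  if (!all(targets %in% background)) {
    stop_consistency("`targets` must be a subset of `background`")
  }
  ann <- annotations %>%
    filter(.data$gene_id %in% background) %>%
    dplyr::distinct(.data$gene_id, .data$term)
  N <- length(background)
  n <- length(targets)
  out <- ann %>%
    group_by(.data$term) %>%
    summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% targets),
      .groups = "drop"
    ) %>%
    mutate(
      n = n, N = N,
      fold = fold_enrichment(.data$k, n, .data$K, N),
      p = hypergeom_pvalue(.data$k, .data$K, n, N, direction = direction),
      p_adj = stats::p.adjust(.data$p, method = p_adjust),
      significant = .data$p_adj < alpha,
      direction = direction
    ) %>%
    arrange(.data$p, .data$term) %>%
    select("term", "k", "n", "K", "N", "fold", "p", "p_adj", "significant", "direction")
  out
}
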