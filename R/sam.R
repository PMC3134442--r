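#' Spot-quality filtering of per-measurement log ratios
#'
#' Applies the measurement-level quality filter used for two-color array
#' spots: a measurement survives only if its print-tip regression
#' correlation strictly exceeds 0.6 and its signal-over-background strictly
#' exceeds 2.5. Failing measurements become missing; surviving values are
#' unchanged.
#'
#' @param spots long-format data frame with columns `gene_id`, `sample_id`,
#'   `value`, `regression_correlation`, `signal_over_background`.
#' @param min_correlation,min_signal_over_background strict lower bounds.
#' @return A wide ratio tibble (`gene_id` plus one column per sample, in
#'   first-appearance order), failing measurements set to `NA`.
#' @export
spot_quality_filter <- function(spots, min_correlation = 0.6,
                                min_signal_over_background = 2.5) {
  required <- c(
    "gene_id", "sample_id", "value",
    "regression_correlation", "signal_over_background"
  )
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf(
      "`spots` is missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  spots %>%
    mutate(
      value = ifelse(
        .data$regression_correlation > min_correlation &
          .data$signal_over_background > min_signal_over_background,
        .data$value, NA_real_
      ),
      gene_id = factor(.data$gene_id, levels = unique(.data$gene_id)),
      sample_id = factor(.data$sample_id, levels = unique(.data$sample_id))
    ) %>%
    select("gene_id", "sample_id", "value") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value") %>%
    mutate(gene_id = as.character(.data$gene_id))
}

#' Drop genes with too many missing replicate values
#'
#' Retains a gene only when its number of missing replicate values is at
#' most `max_missing` (default 1, i.e. features missing two or more values
#' are removed). Row order is preserved.
#'
#' @param ratios wide ratio tibble (`gene_id` + replicate columns).
#' @param max_missing maximum tolerated missing values per gene (>= 0).
#' @return The filtered tibble.
#' @export
filter_features <- function(ratios, max_missing = 1) {
  if (max_missing < 0) stop_invalid_config("`max_missing` must be >= 0")
  X <- ratio_matrix(ratios)
  keep <- rowSums(is.na(X)) <= max_missing
  ratios[keep, , drop = FALSE]
}

# Per-gene mean, scatter (standard error) and d = mean / (s + s0),
# computed over non-missing entries only.
sam_d_stats <- function(X, s0) {
  n_obs <- unname(rowSums(!is.na(X)))
  m <- unname(rowMeans(X, na.rm = TRUE))
  ss <- unname(rowSums((X - m)^2, na.rm = TRUE))
  s <- sqrt(ss / (n_obs - 1)) / sqrt(n_obs)
  list(n_obs = n_obs, mean = m, s = s, d = m / (s + s0))
}

# s0 selection: the candidate among the 0th-100th percentiles (step 5) of
# the per-gene scatter s that minimizes the coefficient of variation of the
# median |d| across s-quantile bins.
sam_pick_s0 <- function(m, s) {
  candidates <- unique(quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  nb <- max(2L, min(10L, floor(length(s) / 5)))
  bins <- cut(rank(s, ties.method = "first"), nb, labels = FALSE)
  cv <- vapply(candidates, function(s0) {
    d <- m / (s + s0)
    med <- tapply(abs(d), bins, median)
    mu <- mean(med)
    if (mu == 0) Inf else sd(med) / mu
  }, numeric(1))
  candidates[which.min(cv)]
}

# K-nearest-neighbour imputation of missing replicate values (the standard
# microarray preprocessing step preceding SAM). Neighbours are complete-case
# genes ranked by Euclidean distance over the target gene's observed
# columns; each missing cell takes the neighbours' mean in that column.
impute_knn <- function(X, k = 10) {
  incomplete <- which(rowSums(is.na(X)) > 0)
  if (length(incomplete) == 0L) {
    return(X)
  }
  complete <- which(rowSums(is.na(X)) == 0)
  if (length(complete) == 0L) {
    # fall back to row means: no donors available
    for (i in incomplete) {
      X[i, is.na(X[i, ])] <- mean(X[i, ], na.rm = TRUE)
    }
    return(X)
  }
  donors <- X[complete, , drop = FALSE]
  for (i in incomplete) {
    obs <- !is.na(X[i, ])
    dist2 <- colSums((t(donors[, obs, drop = FALSE]) - X[i, obs])^2)
    nn <- order(dist2)[seq_len(min(k, length(dist2)))]
    fill <- colMeans(donors[nn, !obs, drop = FALSE])
    X[i, !obs] <- fill
  }
  X
}

# count, for each threshold t, how many values in v satisfy v >= t
count_ge <- function(thresholds, v) {
  sv <- sort(v)
  length(sv) - findInterval(thresholds, sv, left.open = TRUE)
}

#' One-class SAM permutation test on replicated log ratios
#'
#' Tests, per gene, whether its mean log2(IP/reference) ratio differs from
#' zero, using the SAM moderated one-class t statistic
#' `d = mean / (s + s0)` with `s` the standard error over non-missing
#' replicates and `s0` an exchangeability fudge factor. The null
#' distribution comes from sign-flip permutations: one sign pattern per
#' permutation is applied to all genes (preserving gene-gene correlation).
#' All `2^R` patterns are enumerated exactly when `2^R <= n_permutations`;
#' otherwise `n_permutations` random patterns are drawn.
#'
#' The q-value of gene *i* is `100 * median_b(#{null |d| >= |d_i|}) /
#' #{observed |d| >= |d_i|}`, capped at 100 and made monotone
#' (non-increasing in `|d|`) by a cumulative minimum along the |d|-sorted
#' gene list; ties in `|d|` are ordered by gene id.
#'
#' @param ratios wide ratio tibble, already feature-filtered (every gene
#'   needs >= 2 non-missing values).
#' @param n_permutations permutation budget (default 800).
#' @param seed integer seed used when patterns are randomly sampled.
#' @param s0 fixed exchangeability constant; `NULL` (default) selects it by
#'   minimizing the coefficient of variation of median |d| across
#'   s-quantile bins.
#' @param center if `TRUE`, median-center each replicate column first
#'   (a global array normalization).
#' @param impute missing-value policy. `"knn"` (default) imputes remaining
#'   missing cells by 10-nearest-neighbour averaging before testing, the
#'   standard microarray preprocessing for SAM; without it, a gene with a
#'   missing replicate reproduces its observed d under every sign pattern
#'   that only flips its missing column, leaking true signal into the
#'   permutation null and inflating q-values near the calling threshold.
#'   `"none"` computes all statistics on non-missing entries only.
#' @param condition optional label stored in the fit.
#' @return An object of class `sam_fit`. Use [tidy()][generics::tidy] for
#'   the per-gene table (gene_id, n_obs, mean, s, d, q),
#'   [glance()][generics::glance] for a one-row fit summary, and
#'   [call_targets()] to extract a target set.
#' @export
sam_one_class <- function(ratios, n_permutations = 800, seed = 1L,
                          s0 = NULL, center = FALSE,
                          impute = c("knn", "none"), condition = NULL) {
  impute <- match.arg(impute)
  X <- ratio_matrix(ratios)
  R <- ncol(X)
  if (R < 2) stop_insufficient("at least 2 replicate columns are required")
  if (any(rowSums(!is.na(X)) < 2)) {
    stop_insufficient(
      "every gene needs >= 2 non-missing values; run filter_features() first"
    )
  }
  if (center) {
    X <- sweep(X, 2, apply(X, 2, median, na.rm = TRUE))
  }
  if (impute == "knn") {
    X <- impute_knn(X)
  }

  pre <- sam_d_stats(X, 0)
  if (is.null(s0)) s0 <- sam_pick_s0(pre$mean, pre$s)
  obs <- sam_d_stats(X, s0)
  abs_d <- abs(obs$d)

  exhaustive <- 2^R <= n_permutations
  if (exhaustive) {
    patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), R)))
  } else {
    patterns <- withr::with_seed(
      seed,
      matrix(sample(c(1, -1), R * n_permutations, replace = TRUE),
        ncol = R
      )
    )
  }
  B <- nrow(patterns)

  null_counts <- matrix(0L, nrow(X), B)
  for (b in seq_len(B)) {
    Xb <- sweep(X, 2, patterns[b, ], "*")
    db <- sam_d_stats(Xb, s0)$d
    null_counts[, b] <- count_ge(abs_d, abs(db))
  }
  med_null <- apply(null_counts, 1, median)
  obs_counts <- count_ge(abs_d, abs_d)
  q <- pmin(100 * med_null / obs_counts, 100)

  # monotonize: ascending |d| (ties by gene id), cumulative minimum
  ord <- order(abs_d, rownames(X))
  q[ord] <- cummin(q[ord])

  result <- tibble(
    gene_id = rownames(X),
    n_obs = obs$n_obs,
    mean = obs$mean,
    s = obs$s,
    d = obs$d,
    q = q
  )
  structure(
    list(
      result = result, s0 = s0,
      n_permutations = B, exhaustive = exhaustive,
      n_replicates = R, seed = seed, condition = condition
    ),
    class = "sam_fit"
  )
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf(
    "<sam_fit> %d genes x %d replicates, s0 = %.4g, %d %s permutations\n",
    nrow(x$result), x$n_replicates, x$s0, x$n_permutations,
    if (x$exhaustive) "exhaustive" else "random"
  ))
  print(utils::head(x$result))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-gene SAM results as a tibble
#'
#' @param x a `sam_fit`.
#' @param ... unused.
#' @return Tibble with columns gene_id, n_obs, mean, s, d, q.
#' @export
tidy.sam_fit <- function(x, ...) x$result

#' One-row summary of a SAM fit
#'
#' @param x a `sam_fit`.
#' @param ... unused.
#' @return One-row tibble: n_genes, n_replicates, s0, n_permutations,
#'   exhaustive, n_called (genes with q <= 1 and d > 0).
#' @export
glance.sam_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$result),
    n_replicates = x$n_replicates,
    s0 = x$s0,
    n_permutations = x$n_permutations,
    exhaustive = x$exhaustive,
    n_called = sum(x$result$q <= 1 & x$result$d > 0)
  )
}

#' Plot a SAM fit
#'
#' Observed d statistics against their rank, highlighting genes called at
#' the given q threshold.
#'
#' @param object a `sam_fit`.
#' @param q_threshold q-value cutoff (percent) used for highlighting.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sam_fit <- function(object, q_threshold = 1, ...) {
  df <- object$result %>%
    arrange(.data$d) %>%
    mutate(
      rank = dplyr::row_number(),
      called = .data$q <= q_threshold & .data$d > 0
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$d, colour = .data$called)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "rank of d", y = "SAM d statistic",
      colour = sprintf("q ≤ %g%%", q_threshold),
      title = object$condition
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Call the enriched target set from a SAM fit
#'
#' @param fit a `sam_fit`.
#' @param q_threshold q-value cutoff in percent (default 1, i.e. 1% FDR).
#' @param sign `"positive"` (default) restricts calls to enrichment
#'   (d > 0); `"both"` also admits depletion.
#' @return A `target_set`: character vector of gene ids with attributes
#'   `condition`, `q_threshold`, `s0` and `seed`.
#' @export
call_targets <- function(fit, q_threshold = 1, sign = c("positive", "both")) {
  sign <- match.arg(sign)
  if (q_threshold < 0) stop_invalid_config("`q_threshold` must be >= 0")
  res <- fit$result
  keep <- res$q <= q_threshold
  if (sign == "positive") keep <- keep & res$d > 0
  target_set(
    res$gene_id[keep],
    condition = fit$condition, q_threshold = q_threshold,
    s0 = fit$s0, seed = fit$seed
  )
}

#' Construct a target set
#'
#' A target set is the set of gene ids called significantly enriched for
#' one bait/condition, carrying the calling parameters as attributes.
#'
#' @param genes character vector of gene ids (de-duplicated, order kept).
#' @param condition,q_threshold,s0,seed provenance attributes.
#' @return A `target_set` object.
#' @export
target_set <- function(genes, condition = NULL, q_threshold = NA_real_,
                       s0 = NA_real_, seed = NA_integer_) {
  structure(
    unique(as.character(genes)),
    condition = condition, q_threshold = q_threshold,
    s0 = s0, seed = seed,
    class = "target_set"
  )
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf(
    "<target_set> %d genes (condition: %s, q <= %s%%)\n",
    length(x), attr(x, "condition") %||% "?", format(attr(x, "q_threshold"))
  ))
  print(utils::head(unclass(x), 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
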