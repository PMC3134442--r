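#' Pairwise Pearson correlation of samples or genes
#'
#' Pairwise-complete Pearson correlations between replicate columns
#' (`axis = "samples"`) or gene rows (`axis = "genes"`) of a ratio table.
#'
#' @param ratios wide ratio tibble (`gene_id` + replicate columns).
#' @param axis correlate `"samples"` (default) or `"genes"`.
#' @param min_overlap minimum shared non-missing positions per pair
#'   (default 3); less raises an insufficient-data error.
#' @return Symmetric correlation matrix of class `cor_matrix` with unit
#'   diagonal; [tidy()][generics::tidy] gives the long form.
#' @export
pearson_matrix <- function(ratios, axis = c("samples", "genes"),
                           min_overlap = 3) {
  axis <- match.arg(axis)
  X <- ratio_matrix(ratios)
  if (axis == "genes") X <- t(X)
  if (ncol(X) < 2) stop_insufficient_data("need at least 2 vectors to correlate")
  obs <- !is.na(X)
  overlap <- crossprod(obs)
  off <- overlap[upper.tri(overlap)]
  if (any(off < min_overlap)) {
    stop_insufficient_data(sprintf(
      "some pairs share fewer than %d non-missing observations", min_overlap
    ))
  }
  r <- stats::cor(X, use = "pairwise.complete.obs")
  diag(r) <- 1
  r <- (r + t(r)) / 2
  class(r) <- c("cor_matrix", class(r))
  r
}

#' @export
tidy.cor_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame.table(m, responseName = "r", stringsAsFactors = FALSE)) %>%
    rename(id1 = "Var1", id2 = "Var2")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("<cor_matrix> %d x %d\n", nrow(x), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Heat map of a correlation matrix
#'
#' @param object a `cor_matrix`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cor_matrix <- function(object, ...) {
  ggplot2::ggplot(
    tidy.cor_matrix(object),
    ggplot2::aes(x = .data$id1, y = .data$id2, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of samples or genes with distance
#' `1 - Pearson r` and the chosen linkage. Items are ordered by id before
#' clustering, so the tree is invariant to input-column permutation
#' (equal-distance merges are resolved by the lexicographically smallest
#' id pair).
#'
#' @inheritParams pearson_matrix
#' @param linkage agglomeration rule: `"average"` (default), `"complete"`
#'   or `"single"`.
#' @return An [stats::hclust] object.
#' @export
hcluster <- function(ratios, axis = c("samples", "genes"),
                     linkage = c("average", "complete", "single")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  r <- pearson_matrix(ratios, axis = axis)
  ids <- sort(colnames(r))
  d <- stats::as.dist(1 - unclass(r)[ids, ids])
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as Newick text
#'
#' @param hc an [stats::hclust] object.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_dendrogram <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}

#' Cumulative score fractions per gene group
#'
#' Empirical cumulative distribution of a per-gene score (typically the
#' mean log2 enrichment) within each group (typically subcellular
#' localization), the representation used to compare how strongly each
#' compartment's mRNAs are enriched.
#'
#' @param scores data frame with columns `gene_id` and `score`.
#' @param groups optional data frame with columns `gene_id` and `group`;
#'   when `NULL` all genes form one group.
#' @return Tibble with columns `group`, `score`, `fraction`: per group, one
#'   row per distinct score in ascending order, `fraction` the proportion
#'   of the group's genes with score <= that value (the last is 1).
#' @export
cumulative_fraction <- function(scores, groups = NULL) {
  stopifnot(all(c("gene_id", "score") %in% names(scores)))
  if (is.null(groups)) {
    groups <- tibble(gene_id = scores$gene_id, group = "all")
  }
  stopifnot(all(c("gene_id", "group") %in% names(groups)))
  joined <- dplyr::inner_join(groups, scores, by = "gene_id")
  empties <- setdiff(unique(groups$group), unique(joined$group))
  if (length(empties) > 0L) {
    stop_empty_class(sprintf(
      "group(s) with no scored genes: %s", paste(empties, collapse = ", ")
    ))
  }
  joined %>%
    group_by(.data$group) %>%
    arrange(.data$score, .by_group = TRUE) %>%
    mutate(fraction = dplyr::row_number() / dplyr::n()) %>%
    group_by(.data$group, .data$score) %>%
    summarise(fraction = max(.data$fraction), .groups = "drop") %>%
    arrange(.data$group, .data$score)
}

#' Step plot of cumulative fractions
#'
#' @param cf a tibble from [cumulative_fraction()].
#' @return A ggplot object.
#' @export
plot_cumulative_fraction <- function(cf) {
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$score, y = .data$fraction, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "score", y = "cumulative fraction of mRNAs") +
    ggplot2::theme_minimal()
}

#' Box-plot summary statistics
#'
#' Median and quartiles by linear interpolation of order statistics
#' (quantile type 7), with whiskers at the most extreme data points within
#' 1.5 interquartile ranges of the quartiles (Tukey's convention for
#' non-outlier extremes).
#'
#' @param values numeric vector (length >= 1, NAs dropped).
#' @return One-row tibble: `n`, `median`, `q25`, `q75`, `whisker_low`,
#'   `whisker_high`.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stop_invalid_input("`values` must contain data")
  qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo <- qs[1] - 1.5 * iqr
  hi <- qs[3] + 1.5 * iqr
  tibble(
    n = length(values),
    median = qs[2], q25 = qs[1], q75 = qs[3],
    whisker_low = min(values[values >= lo]),
    whisker_high = max(values[values <= hi])
  )
}
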