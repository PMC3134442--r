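quadrant_levels <- c("SRP+/Mem+", "SRP+/Mem-", "SRP-/Mem+", "SRP-/Mem-")
nac_levels <- c("NAC-independent", "NAC-dependent", "Off-target", "none")
dimer_levels <- c(
  "Egd1/Egd2", "Btt1/Egd2", "Egd2-homodimer", "Btt1-homodimer",
  "Egd1-only", "unassigned"
)

check_in_universe <- function(targets, universe, name) {
  extra <- setdiff(targets, universe)
  if (length(extra) > 0L) {
    stop_consistency(sprintf(
      "%d gene(s) in `%s` are outside the universe (e.g. %s)",
      length(extra), name, extra[[1]]
    ))
  }
}

#' Joint SRP / membrane quadrant classification
#'
#' Classifies every gene in the universe by joint membership in the
#' SRP-associated and membrane-associated target sets. The four quadrants
#' distinguish cotranslational ER-targeting routes: SRP-mediated
#' (SRP+/Mem+), SRP-independent membrane targeting (SRP-/Mem+), and
#' post-translational or cytosolic fates (SRP-/Mem-).
#'
#' @param universe data frame with a `gene_id` column, or a character
#'   vector: the gene universe (typically the translatome).
#' @param srp,mem target sets (character vectors or [target_set()]s),
#'   subsets of the universe.
#' @return Tibble with columns `gene_id`, `srp`, `mem` (logical) and
#'   `quadrant` (factor over the four quadrant labels); rows partition the
#'   universe.
#' @export
quadrant_classify <- function(universe, srp, mem) {
  universe <- as_gene_ids(universe, "universe")
  srp <- as.character(srp)
  mem <- as.character(mem)
  check_in_universe(srp, universe, "srp")
  check_in_universe(mem, universe, "mem")
  tibble(gene_id = universe) %>%
    mutate(
      srp = .data$gene_id %in% srp,
      mem = .data$gene_id %in% mem,
      quadrant = factor(
        dplyr::case_when(
          .data$srp & .data$mem ~ "SRP+/Mem+",
          .data$srp & !.data$mem ~ "SRP+/Mem-",
          !.data$srp & .data$mem ~ "SRP-/Mem+",
          TRUE ~ "SRP-/Mem-"
        ),
        levels = quadrant_levels
      )
    )
}

#' NAC-dependence classification of SRP targets
#'
#' Compares the SRP target sets obtained in wild-type and NAC-deletion
#' strains. Genes associated with SRP in both strains are NAC-independent;
#' genes lost upon NAC deletion are NAC-dependent; genes gained only in the
#' deletion strain are off-target SRP interactors.
#'
#' @inheritParams quadrant_classify
#' @param srp_wt,srp_dnac SRP target sets in wild-type and NAC-deletion
#'   cells, subsets of the universe.
#' @return Tibble with columns `gene_id` and `nac_class` (factor:
#'   NAC-independent, NAC-dependent, Off-target, none).
#' @export
nac_dependence <- function(universe, srp_wt, srp_dnac) {
  universe <- as_gene_ids(universe, "universe")
  srp_wt <- as.character(srp_wt)
  srp_dnac <- as.character(srp_dnac)
  check_in_universe(srp_wt, universe, "srp_wt")
  check_in_universe(srp_dnac, universe, "srp_dnac")
  tibble(gene_id = universe) %>%
    mutate(
      nac_class = factor(
        dplyr::case_when(
          .data$gene_id %in% srp_wt & .data$gene_id %in% srp_dnac ~ "NAC-independent",
          .data$gene_id %in% srp_wt ~ "NAC-dependent",
          .data$gene_id %in% srp_dnac ~ "Off-target",
          TRUE ~ "none"
        ),
        levels = nac_levels
      )
    )
}

#' Assign NAC dimer substrates from subunit target sets
#'
#' NAC is a heterodimer of an alpha subunit (Egd2) with one of two beta
#' subunits (Egd1 or Btt1). Targets common to Egd1 and Egd2 are assigned to
#' the Egd1/Egd2 heterodimer; targets common to Egd2 and Btt1 (but not
#' Egd1) to the Btt1/Egd2 heterodimer; targets unique to Egd2 or Btt1 to
#' the corresponding homodimer. Genes in all three sets take the Egd1/Egd2
#' label, with every consistent dimer listed in `consistent_dimers`. A gene
#' in Egd1 and Btt1 but not Egd2 (no shared alpha partner) is labelled
#' Btt1-homodimer, the beta-homodimer taking precedence over Egd1-only.
#'
#' @param egd1,egd2,btt1 target sets for the three NAC subunits.
#' @return Tibble over the union of the three sets with columns `gene_id`,
#'   `dimer` (factor) and `consistent_dimers` (comma-separated string).
#' @export
dimer_assign <- function(egd1, egd2, btt1) {
  egd1 <- as.character(egd1)
  egd2 <- as.character(egd2)
  btt1 <- as.character(btt1)
  union_all <- sort(unique(c(egd1, egd2, btt1)))
  tibble(gene_id = union_all) %>%
    mutate(
      in1 = .data$gene_id %in% egd1,
      in2 = .data$gene_id %in% egd2,
      in3 = .data$gene_id %in% btt1,
      dimer = factor(
        dplyr::case_when(
          .data$in1 & .data$in2 ~ "Egd1/Egd2",
          .data$in2 & .data$in3 ~ "Btt1/Egd2",
          .data$in2 ~ "Egd2-homodimer",
          .data$in3 ~ "Btt1-homodimer",
          .data$in1 ~ "Egd1-only",
          TRUE ~ "unassigned"
        ),
        levels = dimer_levels
      ),
      consistent_dimers = purrr::pmap_chr(
        list(.data$in1, .data$in2, .data$in3),
        function(a, b, c) {
          paste(
            c(
              if (a && b) "Egd1/Egd2",
              if (b && c) "Btt1/Egd2",
              if (b && !a && !c) "Egd2-homodimer",
              if (c && !b) "Btt1-homodimer",
              if (a && !b) "Egd1-only"
            ),
            collapse = ","
          )
        }
      )
    ) %>%
    select("gene_id", "dimer", "consistent_dimers")
}

#' Signal-sequence / transmembrane composition of a target set
#'
#' Fractions of target genes whose encoded protein carries a predicted
#' signal sequence only, a transmembrane region only, both, or neither.
#'
#' @param annotations gene annotation data frame with columns `gene_id`,
#'   `has_ss`, `has_tm`.
#' @param targets target set (character vector); every target must be
#'   annotated.
#' @return Tibble with columns `class` (ss_only, tm_only, both, neither),
#'   `n` and `fraction` (fractions sum to 1).
#' @export
sstm_fraction <- function(annotations, targets) {
  stopifnot(all(c("gene_id", "has_ss", "has_tm") %in% names(annotations)))
  targets <- unique(as.character(targets))
  idx <- match(targets, annotations$gene_id)
  if (anyNA(idx)) {
    stop_missing_annotation(sprintf(
      "%d target gene(s) lack annotations (e.g. %s)",
      sum(is.na(idx)), targets[which(is.na(idx))[1]]
    ))
  }
  ss <- annotations$has_ss[idx]
  tm <- annotations$has_tm[idx]
  cls <- dplyr::case_when(
    ss & tm ~ "both",
    ss ~ "ss_only",
    tm ~ "tm_only",
    TRUE ~ "neither"
  )
  tibble(class = c("ss_only", "tm_only", "both", "neither")) %>%
    mutate(
      n = vapply(.data$class, function(k) sum(cls == k), integer(1), USE.NAMES = FALSE),
      fraction = .data$n / length(targets)
    )
}

#' Category membership table for a target set
#'
#' Counts target genes per annotation category (e.g. GO cellular-component
#' terms) and reports each category's percentage of the stated total. Genes
#' carrying several categories count once in each (so counts may sum to more
#' than the total). Percentages are rounded half-up to one decimal.
#'
#' @param category_map data frame with columns `gene_id` and `category`
#'   (one row per assignment).
#' @param targets target set (character vector of gene ids).
#' @param total denominator for percentages; defaults to the number of
#'   distinct target genes. Must be >= 1.
#' @return Tibble with columns `category`, `count`, `percent` and `genes`
#'   (list-column), sorted by descending count (ties by category name),
#'   with attribute `total`.
#' @export
category_table <- function(category_map, targets, total = NULL) {
  stopifnot(all(c("gene_id", "category") %in% names(category_map)))
  targets <- unique(as.character(targets))
  if (is.null(total)) total <- length(targets)
  if (is.na(total) || total < 1) {
    stop_invalid_input("`total` must be >= 1 (empty target set needs an explicit total)")
  }
  out <- category_map %>%
    filter(.data$gene_id %in% targets) %>%
    dplyr::distinct(.data$gene_id, .data$category) %>%
    group_by(.data$category) %>%
    summarise(
      count = dplyr::n(),
      genes = list(.data$gene_id),
      .groups = "drop"
    ) %>%
    mutate(percent = round_half_up(100 * .data$count / total, 1)) %>%
    arrange(desc(.data$count), .data$category) %>%
    select("category", "count", "percent", "genes")
  attr(out, "total") <- as.integer(total)
  out
}

#' Distribution of enrichment scores by feature class
#'
#' Box-plot summaries of a per-gene score (typically the SAM d statistic)
#' within each feature class, e.g. SS-only / TM-only / both / neither.
#'
#' @param scores data frame with columns `gene_id` and `score`.
#' @param classes data frame with columns `gene_id` and `class`.
#' @return Tibble with one row per class: `class`, `n`, `median`, `q25`,
#'   `q75`, `whisker_low`, `whisker_high`.
#' @export
enrichment_distribution <- function(scores, classes) {
  stopifnot(
    all(c("gene_id", "score") %in% names(scores)),
    all(c("gene_id", "class") %in% names(classes))
  )
  joined <- dplyr::inner_join(classes, scores, by = "gene_id")
  empties <- setdiff(unique(classes$class), unique(joined$class))
  if (length(empties) > 0L) {
    stop_empty_class(sprintf(
      "class(es) with no scored genes: %s", paste(empties, collapse = ", ")
    ))
  }
  joined %>%
    group_by(.data$class) %>%
    summarise(boxplot_stats(.data$score), .groups = "drop")
}

#' Plot per-class enrichment distributions
#'
#' @param dist a tibble from [enrichment_distribution()].
#' @return A ggplot object drawing boxes from the precomputed statistics.
#' @export
plot_enrichment_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$class)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_low, ymax = .data$whisker_high),
      width = 0.3, linetype = "dashed"
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q25, ymax = .data$q75),
      fill = "grey85", width = 0.6
    ) +
    ggplot2::labs(x = NULL, y = "enrichment (SAM d)") +
    ggplot2::theme_minimal()
}
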