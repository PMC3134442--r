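#' Simulate one immunopurification experiment
#'
#' Produces a gene x replicate table of log2(IP/reference) ratios. Each
#' entry is `effect_size * [gene is a planted target] + N(0, noise_sd^2)`,
#' and each entry is independently missing with probability `missing_rate`
#' (missing completely at random).
#'
#' @param genome an `rnc_genome` from [generate_genome()], or its `genes`
#'   tibble (only `gene_id` is used).
#' @param planted_targets character vector of gene ids carrying the
#'   enrichment signal; must be a subset of the genome's gene ids.
#' @param effect_size mean log2-ratio shift of planted targets (>= 0).
#' @param noise_sd replicate noise standard deviation (> 0).
#' @param missing_rate per-entry missingness probability in `[0, 1)`.
#' @param n_replicates number of biological replicates (>= 2).
#' @param seed integer seed; the matrix is deterministic given it.
#' @param condition label used to name replicate columns.
#' @return A wide tibble: `gene_id` plus one numeric column per replicate
#'   (`<condition>_r1`, ...), with `NA` for missing entries.
#' @export
simulate_ip <- function(genome, planted_targets,
                        effect_size = 2, noise_sd = 0.5,
                        missing_rate = 0.02, n_replicates = 4,
                        seed = 1L, condition = "IP") {
  genes <- if (inherits(genome, "rnc_genome")) genome$genes else genome
  gene_ids <- as_gene_ids(genes, "genome")
  planted_targets <- as.character(planted_targets)
  if (!all(planted_targets %in% gene_ids)) {
    stop_invalid_config("planted targets must be a subset of genome gene ids")
  }
  if (n_replicates < 2) stop_invalid_config("`n_replicates` must be >= 2")
  if (effect_size < 0) stop_invalid_config("`effect_size` must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_invalid_config("`missing_rate` must be in [0, 1)")
  }
  if (noise_sd <= 0) stop_invalid_config("`noise_sd` must be > 0")

  n <- length(gene_ids)
  mu <- effect_size * (gene_ids %in% planted_targets)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * n_replicates, mean = mu, sd = noise_sd),
      nrow = n, ncol = n_replicates
    )
    if (missing_rate > 0) {
      X[runif(n * n_replicates) < missing_rate] <- NA_real_
    }
    out <- as_tibble(X, .name_repair = "minimal")
    names(out) <- sprintf("%s_r%d", condition, seq_len(n_replicates))
    dplyr::bind_cols(tibble(gene_id = gene_ids), out)
  })
}

#' Study configuration for the synthetic interactome
#'
#' Defaults encode the conditions the synthetic study emulates: ~1000 genes,
#' four biological replicates per bait, a mean log2 enrichment of 2 against
#' replicate noise of sd 0.5, and planted target sets whose covariate
#' structure mirrors the biology (SRP targets drawn preferentially from
#' SS/TM genes; NAC-dependent SRP targets of low abundance; off-target SRP
#' gains in the NAC-deletion strain drawn from abundant cytosolic genes;
#' near-identical Egd1/Egd2 target sets with a small mitochondrially biased
#' Btt1 set).
#'
#' @param n_genes genome size.
#' @param n_replicates biological replicates per bait.
#' @param effect_size planted mean log2-ratio shift.
#' @param noise_sd replicate noise sd.
#' @param missing_rate per-entry missingness probability.
#' @param baits bait roster; a subset of the default names.
#' @param translatome_fraction fraction of the genome engaged by ribosomal
#'   baits.
#' @param srp_fraction fraction of the genome in the SRP (wild-type) target
#'   set.
#' @param srp_sstm_share share of SRP (wild-type) targets drawn from
#'   SS/TM-flagged genes (default 0.70, the SS/TM share characteristic of
#'   the wild-type SRP interactome).
#' @param nac_dependent_fraction fraction of wild-type SRP targets (the
#'   lowest-abundance ones) lost in the NAC-deletion strain.
#' @param off_target_fraction size of the cytosolic off-target set gained in
#'   the NAC-deletion strain, as a fraction of the wild-type SRP set
#'   (default 0.60, sized so the SS/TM share of the deletion-strain
#'   interactome drops to ~40%).
#' @param mem_fraction fraction of the genome in the membrane-associated set.
#' @param egd2_fraction,btt1_fraction NAC subunit target-set sizes as genome
#'   fractions.
#' @return A named list of class `rnc_study_config`.
#' @export
study_config <- function(n_genes = 1000,
                         n_replicates = 4,
                         effect_size = 2,
                         noise_sd = 0.5,
                         missing_rate = 0.02,
                         baits = c(
                           "Rpl16", "Rpl17", "Egd2", "Egd1", "Btt1",
                           "Srp54_WT", "Srp54_dNAC", "Mem"
                         ),
                         translatome_fraction = 0.85,
                         srp_fraction = 0.15,
                         srp_sstm_share = 0.70,
                         nac_dependent_fraction = 0.30,
                         off_target_fraction = 0.60,
                         mem_fraction = 0.40,
                         egd2_fraction = 0.70,
                         btt1_fraction = 0.08) {
  known <- c(
    "Rpl16", "Rpl17", "Egd2", "Egd1", "Btt1",
    "Srp54_WT", "Srp54_dNAC", "Mem"
  )
  if (length(baits) < 1 || !all(baits %in% known)) {
    stop_invalid_config(sprintf(
      "unknown bait name(s): %s",
      paste(setdiff(baits, known), collapse = ", ")
    ))
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    effect_size = effect_size, noise_sd = noise_sd,
    missing_rate = missing_rate, baits = baits,
    translatome_fraction = translatome_fraction,
    srp_fraction = srp_fraction, srp_sstm_share = srp_sstm_share,
    nac_dependent_fraction = nac_dependent_fraction,
    off_target_fraction = off_target_fraction,
    mem_fraction = mem_fraction,
    egd2_fraction = egd2_fraction, btt1_fraction = btt1_fraction
  )
  fracs <- unlist(cfg[grep("fraction$", names(cfg))])
  if (any(fracs < 0 | fracs > 1)) {
    stop_invalid_config("all *_fraction parameters must be in [0, 1]")
  }
  if (cfg$effect_size < 0) stop_invalid_config("`effect_size` must be >= 0")
  structure(cfg, class = "rnc_study_config")
}

# weighted sample without replacement, returning gene ids
sample_genes <- function(gene_ids, size, weights = NULL) {
  size <- min(size, length(gene_ids))
  gene_ids[sample.int(length(gene_ids), size, prob = weights)]
}

#' Simulate a full ribosome-nascent-chain interactome study
#'
#' Generates a genome and one replicated IP ratio table per bait, with
#' planted target sets whose overlap structure gives every downstream
#' classifier recoverable ground truth:
#' * `Rpl16` / `Rpl17` share the translatome (a large random gene subset);
#' * `Srp54_WT` targets are drawn preferentially from SS/TM-flagged genes;
#' * `Srp54_dNAC` (SRP in the NAC-deletion strain) loses the
#'   lowest-abundance wild-type targets ("NAC-dependent") and gains
#'   abundance-weighted cytosolic genes ("off-target");
#' * `Egd2` and `Egd1` target sets nearly coincide, while `Btt1` is a small
#'   set biased toward mitochondrial genes;
#' * `Mem` (membrane fraction) favours secretory-pathway and mitochondrial
#'   genes.
#'
#' Per-bait random streams are derived from the master seed and the bait
#' name, so adding or removing a bait never changes the others' data.
#'
#' @param config a [study_config()].
#' @param seed master integer seed.
#' @return An object of class `rnc_study`: a list with `genome`
#'   (`rnc_genome`), `matrices` (named list of wide ratio tibbles, one per
#'   bait), `truths` (tibble: bait_id, planted targets as a list-column,
#'   effect_size, noise_sd, missing_rate, n_replicates, seed), and
#'   `nac_truth` (tibble of planted NAC-dependence classes).
#' @export
simulate_study <- function(config = study_config(), seed = 1L) {
  if (!inherits(config, "rnc_study_config")) {
    config <- do.call(study_config, as.list(config))
  }
  genome <- generate_genome(config$n_genes, seed = split_seed(seed, "genome"))
  genes <- genome$genes
  n <- nrow(genes)

  planted <- withr::with_seed(split_seed(seed, "targets"), {
    translatome <- sample_genes(genes$gene_id, round(config$translatome_fraction * n))
    sstm <- genes$has_ss | genes$has_tm
    n_srp <- round(config$srp_fraction * n)
    n_srp_sstm <- min(round(config$srp_sstm_share * n_srp), sum(sstm))
    srp_wt <- c(
      sample_genes(genes$gene_id[sstm], n_srp_sstm),
      sample_genes(genes$gene_id[!sstm], n_srp - n_srp_sstm)
    )
    # NAC-dependent SRP targets are the least abundant wild-type targets
    wt_ab <- genes$abundance[match(srp_wt, genes$gene_id)]
    n_dep <- round(config$nac_dependent_fraction * length(srp_wt))
    nac_dependent <- srp_wt[order(wt_ab)][seq_len(n_dep)]
    # off-targets gained in the deletion strain: abundant cytosolic genes
    cyto_pool <- genes$gene_id[genes$localization == "cytosol" &
      !(genes$gene_id %in% srp_wt)]
    off_target <- sample_genes(
      cyto_pool, round(config$off_target_fraction * length(srp_wt)),
      weights = genes$abundance[match(cyto_pool, genes$gene_id)]
    )
    srp_dnac <- union(setdiff(srp_wt, nac_dependent), off_target)

    mem_w <- dplyr::case_when(
      genes$localization %in% secretory_localizations ~ 15,
      genes$localization == "mitochondrion" ~ 6,
      TRUE ~ 0.5
    )
    mem <- sample_genes(genes$gene_id, round(config$mem_fraction * n), weights = mem_w)

    egd2 <- sample_genes(translatome, round(config$egd2_fraction * n))
    # Egd1 nearly coincides with Egd2 (shared heterodimer substrates)
    drop_n <- max(1L, round(0.05 * length(egd2)))
    egd1 <- union(
      setdiff(egd2, sample_genes(egd2, drop_n)),
      sample_genes(setdiff(translatome, egd2), drop_n)
    )
    btt1 <- sample_genes(
      genes$gene_id, round(config$btt1_fraction * n),
      weights = ifelse(genes$localization == "mitochondrion", 10, 1)
    )
    list(
      Rpl16 = translatome, Rpl17 = translatome,
      Egd2 = egd2, Egd1 = egd1, Btt1 = btt1,
      Srp54_WT = srp_wt, Srp54_dNAC = srp_dnac, Mem = mem,
      nac_dependent = nac_dependent, off_target = off_target
    )
  })

  nac_truth <- tibble(gene_id = genes$gene_id) %>%
    mutate(nac_class = dplyr::case_when(
      .data$gene_id %in% planted$nac_dependent ~ "NAC-dependent",
      .data$gene_id %in% planted$off_target ~ "Off-target",
      .data$gene_id %in% planted$Srp54_WT ~ "NAC-independent",
      TRUE ~ "none"
    ))

  matrices <- list()
  truth_rows <- list()
  for (bait in config$baits) {
    bait_seed <- split_seed(seed, paste0("bait:", bait))
    matrices[[bait]] <- simulate_ip(
      genome, planted[[bait]],
      effect_size = config$effect_size, noise_sd = config$noise_sd,
      missing_rate = config$missing_rate,
      n_replicates = config$n_replicates,
      seed = bait_seed, condition = bait
    )
    truth_rows[[bait]] <- tibble(
      bait_id = bait, planted = list(planted[[bait]]),
      effect_size = config$effect_size, noise_sd = config$noise_sd,
      missing_rate = config$missing_rate,
      n_replicates = config$n_replicates, seed = bait_seed
    )
  }

  structure(
    list(
      genome = genome, matrices = matrices,
      truths = dplyr::bind_rows(truth_rows),
      nac_truth = nac_truth, config = config, seed = seed
    ),
    class = "rnc_study"
  )
}

#' @export
print.rnc_study <- function(x, ...) {
  cat(sprintf(
    "<rnc_study> %d genes, %d baits (%s), %d replicates each\n",
    nrow(x$genome$genes), length(x$matrices),
    paste(names(x$matrices), collapse = ", "),
    x$config$n_replicates
  ))
  invisible(x)
}
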