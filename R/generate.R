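# Background alphabet for synthetic proteins: every residue scores at most
# -0.4 on the Kyte-Doolittle scale, so a window-7 mean can never exceed the
# stretch threshold of 1 outside a planted stretch. This makes planted-stretch
# tests exact.
background_alphabet <- c("S", "T", "N", "Q", "G", "P", "D", "E", "K", "R")
hydrophobic_residues <- c("I", "V", "L", "F")

#' Generate a synthetic protein sequence with planted hydrophobic stretches
#'
#' Background residues are drawn uniformly from a low-hydropathy alphabet
#' (S, T, N, Q, G, P, D, E, K, R; all Kyte-Doolittle scores <= -0.4), so no
#' hydrophobic stretch can arise by chance at threshold 1. Planted stretches
#' are filled with a single high-hydropathy residue.
#'
#' @param length protein length in residues (>= 1).
#' @param stretch_spec optional data frame with columns `start`, `length`,
#'   `residue` describing non-overlapping runs to plant, all inside
#'   `[1, length]`.
#' @param seed optional integer seed; the generator is deterministic given it.
#' @return A single amino-acid string.
#' @export
#' @examples
#' generate_protein(60, data.frame(start = 10, length = 9, residue = "I"), seed = 1)
generate_protein <- function(length, stretch_spec = NULL, seed = NULL) {
  if (!is.numeric(length) || length < 1) {
    stop_invalid_config("`length` must be a positive integer")
  }
  length <- as.integer(length)
  if (!is.null(stretch_spec) && nrow(stretch_spec) > 0L) {
    if (!all(c("start", "length", "residue") %in% names(stretch_spec))) {
      stop_invalid_config("`stretch_spec` needs columns start, length, residue")
    }
    starts <- as.integer(stretch_spec$start)
    lens <- as.integer(stretch_spec$length)
    ends <- starts + lens - 1L
    if (any(starts < 1L) || any(ends > length) || any(lens < 1L)) {
      stop_invalid_config("planted stretches must lie inside [1, length]")
    }
    o <- order(starts)
    if (any(starts[o][-1] <= ends[o][-length(ends)])) {
      stop_invalid_config("planted stretches must not overlap")
    }
  }
  draw <- function() {
    residues <- sample(background_alphabet, length, replace = TRUE)
    if (!is.null(stretch_spec) && nrow(stretch_spec) > 0L) {
      for (i in seq_len(nrow(stretch_spec))) {
        idx <- seq(stretch_spec$start[i], length.out = stretch_spec$length[i])
        residues[idx] <- as.character(stretch_spec$residue[i])
      }
    }
    paste(residues, collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

default_composition <- function() {
  c(
    cytosol = 0.40, nucleus = 0.20, mitochondrion = 0.15,
    ER = 0.08, `plasma-membrane` = 0.06, Golgi = 0.03,
    vacuole = 0.03, unknown = 0.05
  )
}

secretory_localizations <- c("ER", "Golgi", "plasma-membrane", "vacuole")

#' Generate a synthetic genome with annotations and protein sequences
#'
#' Draws per-gene localization from `composition` (a multinomial draw),
#' assigns signal-sequence (SS) and transmembrane (TM) flags with
#' class-dependent probabilities (high for secretory-pathway localizations,
#' low background elsewhere), draws mRNA abundance and translation rate from
#' a correlated bivariate log-normal, and generates a protein sequence per
#' gene. Proteins of SS/TM-flagged genes carry at least one planted
#' hydrophobic stretch (N-terminal for SS, internal for TM), so
#' sequence-feature detectors have recoverable ground truth.
#'
#' @param n_genes number of genes (>= 1).
#' @param composition named vector of localization fractions summing to 1.
#' @param seed integer seed; output is deterministic given it.
#' @param p_ss,p_tm probability of the SS / TM flag for secretory-pathway
#'   genes (defaults 0.5 / 0.7, independent draws).
#' @param p_ss_bg,p_tm_bg background SS / TM probabilities for
#'   non-secretory genes.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters for mRNA
#'   abundance (arbitrary copies).
#' @param rate_sdlog log-scale spread of translation rate; translation rate
#'   correlates with log-abundance (rho = 0.5), emulating the tendency of
#'   abundant mRNAs to be highly translated.
#' @return An object of class `rnc_genome`: a list with `genes` (a tibble of
#'   gene annotations: gene_id, localization, has_ss, has_tm, abundance,
#'   translation_rate, sequence_id) and `proteins` (a tibble of
#'   sequence_id, sequence).
#' @export
generate_genome <- function(n_genes,
                            composition = default_composition(),
                            seed = 1L,
                            p_ss = 0.5, p_tm = 0.7,
                            p_ss_bg = 0.02, p_tm_bg = 0.03,
                            abundance_meanlog = 2, abundance_sdlog = 1,
                            rate_sdlog = 0.5) {
  if (!is.numeric(n_genes) || n_genes < 1) {
    stop_invalid_config("`n_genes` must be >= 1")
  }
  n_genes <- as.integer(n_genes)
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop_invalid_config("`composition` must be a named vector")
  }
  if (abs(sum(composition) - 1) > 1e-9) {
    stop_invalid_config("`composition` fractions must sum to 1")
  }

  withr::with_seed(seed, {
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    localization <- sample(names(composition), n_genes,
      replace = TRUE, prob = composition
    )
    secretory <- localization %in% secretory_localizations
    has_ss <- runif(n_genes) < ifelse(secretory, p_ss, p_ss_bg)
    has_tm <- runif(n_genes) < ifelse(secretory, p_tm, p_tm_bg)

    # correlated log-normal abundance / translation rate
    z1 <- rnorm(n_genes)
    z2 <- 0.5 * z1 + sqrt(1 - 0.5^2) * rnorm(n_genes)
    abundance <- exp(abundance_meanlog + abundance_sdlog * z1)
    translation_rate <- exp(rate_sdlog * z2)

    lengths <- pmin(pmax(round(rlnorm(n_genes, log(450), 0.35)), 80L), 4000L)
    seq_seeds <- sample.int(.Machine$integer.max, n_genes)

    sequences <- character(n_genes)
    for (i in seq_len(n_genes)) {
      spec <- NULL
      if (has_ss[i] || has_tm[i]) {
        rows <- list()
        if (has_ss[i]) {
          # signal-sequence-like stretch near the N terminus
          rows[[length(rows) + 1L]] <- data.frame(
            start = sample(3:12, 1),
            length = sample(9:15, 1),
            residue = sample(hydrophobic_residues, 1)
          )
        }
        if (has_tm[i]) {
          # transmembrane-like stretch in the interior
          tm_len <- sample(15:23, 1)
          lo <- 40L
          hi <- lengths[i] - tm_len - 5L
          rows[[length(rows) + 1L]] <- data.frame(
            start = sample(lo:hi, 1),
            length = tm_len,
            residue = sample(hydrophobic_residues, 1)
          )
        }
        spec <- do.call(rbind, rows)
      }
      sequences[i] <- generate_protein(lengths[i], spec, seed = seq_seeds[i])
    }

    genes <- tibble(
      gene_id = gene_id,
      localization = localization,
      has_ss = has_ss,
      has_tm = has_tm,
      abundance = abundance,
      translation_rate = translation_rate,
      sequence_id = paste0(gene_id, "_p")
    )
    proteins <- tibble(sequence_id = genes$sequence_id, sequence = sequences)
    structure(list(genes = genes, proteins = proteins), class = "rnc_genome")
  })
}

#' @export
print.rnc_genome <- function(x, ...) {
  cat(sprintf(
    "<rnc_genome> %d genes (%d SS/TM), %d protein sequences\n",
    nrow(x$genes), sum(x$genes$has_ss | x$genes$has_tm), nrow(x$proteins)
  ))
  print(utils::head(x$genes, 5))
  invisible(x)
}
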