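#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy scores for the 20 standard amino acids on the
#' Kyte-Doolittle scale. Positive values are hydrophobic (isoleucine is the
#' most hydrophobic at 4.5, arginine the least at -4.5).
#'
#' @format Named numeric vector of length 20 (one-letter residue codes).
#' @export
kyte_doolittle <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# Per-residue scores; 'X' (unknown residue) scores 0 with a warning, any
# other non-standard letter is a format error.
kd_scores <- function(sequence) {
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  unknown <- residues == "X"
  bad <- !(residues %in% names(kyte_doolittle)) & !unknown
  if (any(bad)) {
    stop_format(sprintf(
      "sequence contains non-standard residue(s): %s",
      paste(unique(residues[bad]), collapse = ", ")
    ))
  }
  if (any(unknown)) {
    warn(sprintf("%d 'X' residue(s) scored as 0.0", sum(unknown)))
  }
  scores <- rep(0, length(residues))
  known <- !unknown
  scores[known] <- kyte_doolittle[residues[known]]
  scores
}

#' Sliding-window hydropathy profile
#'
#' Averages Kyte-Doolittle residue scores over a sliding window. Windows are
#' not padded: a sequence of length L yields L - window + 1 values, and
#' `position` indexes each window's first residue (1-based).
#'
#' @param sequence amino-acid string over the 20 standard residues
#'   ('X' is tolerated and scores 0 with a warning).
#' @param window odd window width (default 7, the convention for detecting
#'   transmembrane-like hydrophobic segments).
#' @param sequence_id optional identifier carried in the result.
#' @return A tibble with columns `position` and `value`, with attributes
#'   `window` and `sequence_id`.
#' @export
#' @examples
#' hydropathy_profile(strrep("I", 9))
hydropathy_profile <- function(sequence, window = 7, sequence_id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (window < 1 || window %% 2 == 0) {
    stop_invalid_config("`window` must be an odd positive integer")
  }
  scores <- kd_scores(sequence)
  L <- length(scores)
  if (L < window) {
    stop_too_short(sprintf("sequence length %d is shorter than window %d", L, window))
  }
  cs <- cumsum(c(0, scores))
  np <- L - window + 1
  values <- (cs[(window + 1):(L + 1)] - cs[1:np]) / window
  out <- tibble(position = seq_len(np), value = values)
  attr(out, "window") <- as.integer(window)
  attr(out, "sequence_id") <- sequence_id
  class(out) <- c("hydropathy_profile", class(out))
  out
}

#' Mean hydrophobicity of a protein
#'
#' Overall sequence hydrophobicity, approximated as the mean of the
#' window-7 hydropathy profile.
#'
#' @inheritParams hydropathy_profile
#' @return A single numeric value.
#' @export
mean_hydrophobicity <- function(sequence, window = 7) {
  mean(hydropathy_profile(sequence, window = window)$value)
}

#' N-terminal hydrophobicity
#'
#' Mean hydropathy of the N-terminal region, computed as the average of a
#' window-11 profile over the first `n_residues` residues (the whole
#' sequence when shorter). This is the readout used to relate SRP binding to
#' the hydrophobicity of the nascent chain's first ~50 residues.
#'
#' @inheritParams hydropathy_profile
#' @param n_residues number of N-terminal residues considered (default 50).
#' @return A single numeric value.
#' @export
nterm_hydrophobicity <- function(sequence, n_residues = 50, window = 11) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < window) {
    stop_too_short(sprintf("sequence length %d is shorter than window %d", L, window))
  }
  prefix <- substr(sequence, 1L, min(n_residues, L))
  mean(hydropathy_profile(prefix, window = window)$value)
}

#' Detect hydrophobic stretches in a hydropathy profile
#'
#' Finds maximal runs of consecutive profile positions whose value strictly
#' exceeds `threshold`, and reports runs of at least `min_length` positions.
#' The defaults (threshold 1, minimum 5 on a window-7 profile) define the
#' hydrophobic stretches characteristic of signal sequences and
#' transmembrane segments.
#'
#' Coordinates are in profile space (window-start positions). When the
#' profile carries its window width, residue-space coordinates
#' (`res_start` = start, `res_end` = end + window - 1) are added.
#'
#' @param profile a tibble from [hydropathy_profile()], or any data frame
#'   with `position` and `value` columns.
#' @param threshold strict lower bound on profile values (default 1.0).
#' @param min_length minimum run length in profile positions (default 5).
#' @return A tibble with columns `start`, `end`, `length`, `max_value`
#'   (and `res_start`, `res_end` when the window is known), ordered by
#'   `start`.
#' @export
find_stretches <- function(profile, threshold = 1, min_length = 5) {
  stopifnot(is.data.frame(profile), all(c("position", "value") %in% names(profile)))
  above <- profile$value > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  out <- tibble(
    start = profile$position[starts[keep]],
    end = profile$position[ends[keep]],
    length = r$lengths[keep],
    max_value = vapply(
      which(keep),
      function(i) max(profile$value[starts[i]:ends[i]]),
      numeric(1)
    )
  )
  window <- attr(profile, "window")
  if (!is.null(window)) {
    out$res_start <- out$start
    out$res_end <- out$end + window - 1L
  }
  out
}

#' Length of the first hydrophobic stretch
#'
#' Length (in profile positions) of the N-terminal-most hydrophobic stretch
#' of a protein, or `NA` when the sequence has none.
#'
#' @inheritParams hydropathy_profile
#' @inheritParams find_stretches
#' @return Integer length, or `NA_integer_` when no stretch is detected.
#' @export
first_stretch_length <- function(sequence, window = 7, threshold = 1, min_length = 5) {
  stretches <- find_stretches(
    hydropathy_profile(sequence, window = window),
    threshold = threshold, min_length = min_length
  )
  if (nrow(stretches) == 0L) NA_integer_ else as.integer(stretches$length[[1]])
}

#' Plot a hydropathy profile with detected stretches
#'
#' @inheritParams find_stretches
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(profile, threshold = 1, min_length = 5) {
  stretches <- find_stretches(profile, threshold = threshold, min_length = min_length)
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "window start position", y = "mean Kyte-Doolittle hydropathy",
      title = attr(profile, "sequence_id")
    ) +
    ggplot2::theme_minimal()
  if (nrow(stretches) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = stretches,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p
}
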