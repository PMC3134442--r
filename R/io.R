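#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Tibble with columns `sequence_id` (first token of the header)
#'   and `sequence` (uppercase). Duplicate ids or empty records are format
#'   errors; lowercase residues are uppercased with a warning.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (anyDuplicated(ids)) {
    stop_format(sprintf(
      "duplicate sequence id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  if (any(nchar(seqs) == 0L)) {
    stop_format("FASTA contains empty record(s)")
  }
  if (any(grepl("[a-z]", seqs))) {
    warn("lowercase residues uppercased")
    seqs <- toupper(seqs)
  }
  tibble(sequence_id = ids, sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences data frame with columns `sequence_id` and `sequence`.
#' @param path output path.
#' @param width line-wrapping width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  stopifnot(all(c("sequence_id", "sequence") %in% names(sequences)))
  if (anyDuplicated(sequences$sequence_id)) {
    stop_format("duplicate sequence ids")
  }
  if (any(nchar(sequences$sequence) == 0L)) {
    stop_format("empty sequence(s)")
  }
  set <- Biostrings::BStringSet(setNames(
    sequences$sequence, sequences$sequence_id
  ))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a ratio matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' empty cells for missing values.
#'
#' @param path TSV file path.
#' @return Wide ratio tibble (`gene_id` + numeric replicate columns).
#' @export
read_matrix <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  )
  if (!"gene_id" %in% names(out)) {
    stop_format("first column of a ratio matrix must be named gene_id")
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    stop_format(sprintf(
      "malformed ratio matrix: %s (row %d)", probs$expected[1], probs$row[1]
    ))
  }
  if (anyDuplicated(out$gene_id)) stop_format("duplicate gene ids")
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  out
}

#' Write a ratio matrix to TSV
#'
#' @param ratios wide ratio tibble.
#' @param path output path. Missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(ratios, path) {
  ratio_matrix(ratios) # validates shape
  readr::write_tsv(ratios, path, na = "")
  invisible(path)
}

#' Read / write gene annotation tables
#'
#' Annotation TSVs have columns gene_id, localization, has_ss, has_tm,
#' abundance, translation_rate.
#'
#' @param path TSV path.
#' @return [read_annotations()]: annotation tibble.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      localization = readr::col_character(),
      sequence_id = readr::col_character(),
      has_ss = readr::col_logical(),
      has_tm = readr::col_logical(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' @rdname read_annotations
#' @param annotations annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Write a target set to a text file
#'
#' One gene id per line, preceded by comment lines recording the calling
#' parameters.
#'
#' @param targets a [target_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_set <- function(targets, path) {
  header <- sprintf(
    "# condition: %s\n# q_threshold: %s\n# s0: %s\n# seed: %s",
    attr(targets, "condition") %||% "NA",
    format(attr(targets, "q_threshold")),
    format(attr(targets, "s0")),
    format(attr(targets, "seed"))
  )
  writeLines(c(header, as.character(targets)), path)
  invisible(path)
}

#' Read a target set written by [write_target_set()]
#'
#' @param path file path.
#' @return A [target_set()] with parsed attributes.
#' @export
read_target_set <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  genes <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_attr <- function(key) {
    hit <- grep(sprintf("^# %s:", key), comments, value = TRUE)
    if (length(hit) == 0L) {
      return(NA_character_)
    }
    trimws(sub(sprintf("^# %s:", key), "", hit[[1]]))
  }
  target_set(
    genes,
    condition = get_attr("condition"),
    q_threshold = suppressWarnings(as.numeric(get_attr("q_threshold"))),
    s0 = suppressWarnings(as.numeric(get_attr("s0"))),
    seed = suppressWarnings(as.integer(get_attr("seed")))
  )
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates the analysis end to end on a simulated study: simulate ->
#' feature-filter -> one-class SAM -> target calling -> set classification
#' (quadrants, NAC dependence, dimer assignment, SS/TM composition,
#' localization table) -> annotation enrichment -> summaries, writing every
#' result as TSV/text under `out_dir` together with a machine-readable
#' manifest (config, seeds, thresholds, per-file row counts and checksums).
#'
#' @param config a [study_config()].
#' @param seed master seed for the simulated study.
#' @param out_dir output directory (created if needed).
#' @param q_threshold target-calling q-value cutoff in percent (>= 0).
#' @param alpha significance level for annotation enrichment.
#' @return Invisibly, a list with the study, fits, target sets,
#'   classification tables and the manifest.
#' @export
run_pipeline <- function(config = study_config(), seed = 1L, out_dir,
                         q_threshold = 1, alpha = 0.01) {
  if (q_threshold < 0) stop_invalid_config("`q_threshold` must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop_invalid_config("`alpha` must be in (0, 1)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  study <- simulate_study(config, seed = seed)
  genes <- study$genome$genes
  files <- list()
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] rows in: %d, rows out: %d", stage, n_in, n_out))
  }

  write_fasta(study$genome$proteins, file.path(out_dir, "proteins.fasta"))
  write_annotations(genes, file.path(out_dir, "annotations.tsv"))

  fits <- list()
  targets <- list()
  for (bait in names(study$matrices)) {
    mat <- study$matrices[[bait]]
    filtered <- filter_features(mat, max_missing = 1)
    log_stage(paste0("filter:", bait), nrow(mat), nrow(filtered))
    fit <- sam_one_class(filtered,
      seed = split_seed(seed, paste0("sam:", bait)),
      condition = bait
    )
    fits[[bait]] <- fit
    targets[[bait]] <- call_targets(fit, q_threshold = q_threshold)
    log_stage(paste0("sam:", bait), nrow(filtered), length(targets[[bait]]))
    readr::write_tsv(tidy(fit), file.path(out_dir, sprintf("sam_%s.tsv", bait)))
    write_target_set(targets[[bait]], file.path(out_dir, sprintf("targets_%s.txt", bait)))
  }

  results <- list()
  universe <- if ("Rpl16" %in% names(targets)) {
    as.character(targets$Rpl16)
  } else {
    genes$gene_id
  }
  have <- function(...) all(c(...) %in% names(targets))
  if (have("Srp54_WT", "Mem")) {
    results$quadrants <- quadrant_classify(
      union(universe, union(targets$Srp54_WT, targets$Mem)),
      targets$Srp54_WT, targets$Mem
    )
    readr::write_tsv(results$quadrants, file.path(out_dir, "quadrants.tsv"))
  }
  if (have("Srp54_WT", "Srp54_dNAC")) {
    results$nac <- nac_dependence(
      union(universe, union(targets$Srp54_WT, targets$Srp54_dNAC)),
      targets$Srp54_WT, targets$Srp54_dNAC
    )
    readr::write_tsv(results$nac, file.path(out_dir, "nac_classes.tsv"))
  }
  if (have("Egd1", "Egd2", "Btt1")) {
    results$dimers <- dimer_assign(targets$Egd1, targets$Egd2, targets$Btt1)
    readr::write_tsv(results$dimers, file.path(out_dir, "dimers.tsv"))
  }
  if (have("Srp54_WT")) {
    results$sstm <- sstm_fraction(genes, targets$Srp54_WT)
    readr::write_tsv(results$sstm, file.path(out_dir, "srp_sstm.tsv"))
    loc_map <- genes %>% select("gene_id", category = "localization")
    results$localization_table <- category_table(loc_map, targets$Srp54_WT)
    readr::write_tsv(
      results$localization_table %>% select(-"genes"),
      file.path(out_dir, "srp_localization_table.tsv")
    )
    results$enrichment <- enrich_terms(
      genes %>% select("gene_id", term = "localization"),
      as.character(targets$Srp54_WT), genes$gene_id,
      alpha = alpha
    )
    readr::write_tsv(results$enrichment, file.path(out_dir, "srp_term_enrichment.tsv"))
  }

  # summaries on the first bait's replicate matrix
  first_bait <- names(study$matrices)[[1]]
  filtered1 <- filter_features(study$matrices[[first_bait]])
  r <- pearson_matrix(filtered1)
  readr::write_tsv(tidy(r), file.path(out_dir, "replicate_correlation.tsv"))
  writeLines(
    write_dendrogram(hcluster(filtered1)),
    file.path(out_dir, "replicate_dendrogram.newick")
  )

  manifest_files <- list.files(out_dir, full.names = FALSE)
  manifest_files <- setdiff(manifest_files, "manifest.json")
  manifest <- list(
    package = "rnctools",
    version = as.character(utils::packageVersion("rnctools")),
    seed = seed,
    q_threshold = q_threshold,
    alpha = alpha,
    config = unclass(config),
    files = lapply(setNames(manifest_files, manifest_files), function(f) {
      p <- file.path(out_dir, f)
      list(
        lines = length(readLines(p, warn = FALSE)),
        md5 = unname(tools::md5sum(p))
      )
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    study = study, fits = fits, targets = targets,
    results = results, manifest = manifest
  ))
}
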