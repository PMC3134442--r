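test_that("quadrant classification is definitional and partitions the universe", {
  uni <- sprintf("g%02d", 1:20)
  srp <- uni[1:8]
  mem <- uni[5:12]
  lab <- quadrant_classify(uni, srp, mem)
  expect_equal(as.character(lab$quadrant[lab$gene_id == "g05"]), "SRP+/Mem+")
  expect_equal(as.character(lab$quadrant[lab$gene_id == "g01"]), "SRP+/Mem-")
  expect_equal(as.character(lab$quadrant[lab$gene_id == "g10"]), "SRP-/Mem+")
  expect_equal(as.character(lab$quadrant[lab$gene_id == "g20"]), "SRP-/Mem-")
  expect_equal(sum(table(lab$quadrant)), length(uni))

  # both sets empty
  lab0 <- quadrant_classify(uni, character(0), character(0))
  expect_true(all(lab0$quadrant == "SRP-/Mem-"))

  expect_error(
    quadrant_classify(uni, c(srp, "not_there"), mem),
    class = "rnc_error_consistency"
  )
})

test_that("quadrant counts match brute-force recounts and swap symmetry", {
  set.seed(40)
  for (i in 1:20) {
    uni <- sprintf("g%03d", 1:100)
    srp <- sample(uni, sample(0:60, 1))
    mem <- sample(uni, sample(0:60, 1))
    lab <- quadrant_classify(uni, srp, mem)
    counts <- table(lab$quadrant)
    expect_equal(unname(counts[["SRP+/Mem+"]]), length(intersect(srp, mem)))
    expect_equal(unname(counts[["SRP+/Mem-"]]), length(setdiff(srp, mem)))
    expect_equal(unname(counts[["SRP-/Mem+"]]), length(setdiff(mem, srp)))
    expect_equal(sum(counts), 100)
    # swapping the two sets transposes the off-diagonal counts
    swapped <- table(quadrant_classify(uni, mem, srp)$quadrant)
    expect_equal(unname(swapped[["SRP+/Mem-"]]), unname(counts[["SRP-/Mem+"]]))
    expect_equal(unname(swapped[["SRP+/Mem+"]]), unname(counts[["SRP+/Mem+"]]))
  }
})

test_that("NAC-dependence classes follow the set algebra", {
  uni <- sprintf("g%02d", 1:30)
  a <- uni[1:10]
  lab_same <- nac_dependence(uni, a, a)
  expect_equal(sum(lab_same$nac_class == "NAC-independent"), 10)
  expect_equal(sum(lab_same$nac_class == "NAC-dependent"), 0)
  expect_equal(sum(lab_same$nac_class == "Off-target"), 0)

  b <- uni[11:18]
  lab_disj <- nac_dependence(uni, a, b)
  expect_equal(sum(lab_disj$nac_class == "NAC-dependent"), length(a))
  expect_equal(sum(lab_disj$nac_class == "Off-target"), length(b))
  expect_equal(sum(lab_disj$nac_class == "none"), 30 - 18)

  # idempotence: classifying the labelled universe again changes nothing
  lab2 <- nac_dependence(lab_disj$gene_id, a, b)
  expect_identical(lab_disj, lab2)
})

test_that("dimer assignment implements the subunit-overlap rules", {
  lab <- dimer_assign(
    egd1 = c("a", "b", "t"),
    egd2 = c("b", "c", "d", "t"),
    btt1 = c("d", "e", "t")
  )
  get <- function(g) as.character(lab$dimer[lab$gene_id == g])
  expect_equal(get("b"), "Egd1/Egd2")
  expect_equal(get("d"), "Btt1/Egd2")
  expect_equal(get("c"), "Egd2-homodimer")
  expect_equal(get("e"), "Btt1-homodimer")
  expect_equal(get("a"), "Egd1-only")
  # triple overlap: priority Egd1/Egd2, all consistent dimers recorded
  expect_equal(get("t"), "Egd1/Egd2")
  expect_match(lab$consistent_dimers[lab$gene_id == "t"], "Btt1/Egd2")
})

test_that("dimer class counts equal brute-force set expressions", {
  set.seed(41)
  for (i in 1:20) {
    uni <- sprintf("g%03d", 1:60)
    e1 <- sample(uni, 25)
    e2 <- sample(uni, 30)
    b1 <- sample(uni, 15)
    counts <- table(dimer_assign(e1, e2, b1)$dimer)
    expect_equal(unname(counts[["Egd1/Egd2"]]), length(intersect(e1, e2)))
    expect_equal(
      unname(counts[["Btt1/Egd2"]]),
      length(setdiff(intersect(e2, b1), e1))
    )
    expect_equal(
      unname(counts[["Egd2-homodimer"]]),
      length(setdiff(e2, union(e1, b1)))
    )
    expect_equal(
      unname(counts[["Btt1-homodimer"]]),
      length(setdiff(b1, e2))
    )
    # beta-homodimer precedence: Egd1-only excludes Btt1-bound genes
    expect_equal(
      unname(counts[["Egd1-only"]]),
      length(setdiff(e1, union(e2, b1)))
    )
  }
})

test_that("SS/TM fractions sum to one and match recounts", {
  ann <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    has_ss = rep(c(TRUE, FALSE), 20),
    has_tm = rep(c(TRUE, TRUE, FALSE, FALSE), 10)
  )
  fr <- sstm_fraction(ann, ann$gene_id)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$n[fr$class == "both"], sum(ann$has_ss & ann$has_tm))
  expect_equal(fr$n[fr$class == "neither"], sum(!ann$has_ss & !ann$has_tm))

  all_ss <- ann
  all_ss$has_ss <- TRUE
  all_ss$has_tm <- FALSE
  fr2 <- sstm_fraction(all_ss, all_ss$gene_id)
  expect_equal(fr2$fraction, c(1, 0, 0, 0))

  expect_error(
    sstm_fraction(ann, c("g01", "missing")),
    class = "rnc_error_missing_annotation"
  )
})

test_that("category tables reproduce the printed worked-example percentages", {
  t1 <- readr::read_tsv(
    system.file("extdata", "table1_srp_no_sstm_categories.tsv", package = "rnctools"),
    show_col_types = FALSE
  )
  tab <- category_table(t1, unique(t1$gene_id), total = 213)
  printed <- dplyr::distinct(t1, .data$category, .data$printed_count, .data$printed_percent)
  merged <- dplyr::left_join(tab, printed, by = "category")
  expect_equal(merged$count, merged$printed_count)
  expect_equal(merged$percent, merged$printed_percent)

  t2 <- readr::read_tsv(
    system.file("extdata", "table2_mem_not_srp_categories.tsv", package = "rnctools"),
    show_col_types = FALSE
  )
  tab2 <- category_table(t2, unique(t2$gene_id), total = 541)
  printed2 <- dplyr::distinct(t2, .data$category, .data$printed_count, .data$printed_percent)
  merged2 <- dplyr::left_join(tab2, printed2, by = "category")
  expect_equal(merged2$count, merged2$printed_count)
  expect_equal(merged2$percent, merged2$printed_percent)
})

test_that("category table handles multi-membership, sorting and totals", {
  cmap <- tibble::tibble(
    gene_id = c("a", "a", "b", "c", "c", "d"),
    category = c("X", "Y", "X", "Y", "Z", "X")
  )
  tab <- category_table(cmap, c("a", "b", "c", "d"))
  expect_equal(tab$category, c("X", "Y", "Z")) # desc count, ties by name
  expect_equal(tab$count, c(3, 2, 1))
  expect_equal(sum(tab$count), 6) # multi-membership exceeds total of 4
  expect_equal(tab$percent, c(75, 50, 25))
  expect_error(category_table(cmap, character(0)), class = "rnc_error_invalid_input")
})

test_that("half-up rounding matches the printed convention", {
  expect_equal(round_half_up(29.65, 1), 29.7)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(100 * 63 / 213, 1), 29.6)
  expect_equal(round_half_up(100 * 27 / 541, 1), 5.0)
})

test_that("enrichment distributions summarise classes correctly", {
  scores <- tibble::tibble(gene_id = sprintf("g%02d", 1:30), score = c(rep(5, 10), rnorm(20)))
  classes <- tibble::tibble(
    gene_id = scores$gene_id,
    class = rep(c("TM", "neither", "neither"), 10)
  )
  out <- enrichment_distribution(scores, classes)
  expect_equal(nrow(out), 2)
  # constant class collapses to a point
  single <- enrichment_distribution(
    dplyr::mutate(scores[1:10, ], score = 2.5),
    classes[1:10, ]
  )
  expect_equal(single$median, single$q25)
  expect_equal(single$median, single$q75)
  # medians equal direct recomputation
  for (cl in out$class) {
    ids <- classes$gene_id[classes$class == cl]
    expect_equal(
      out$median[out$class == cl],
      median(scores$score[scores$gene_id %in% ids])
    )
  }
  neither_only <- scores[scores$gene_id %in% classes$gene_id[classes$class == "neither"], ]
  expect_error(
    enrichment_distribution(neither_only, classes),
    class = "rnc_error_empty_class"
  )
})
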