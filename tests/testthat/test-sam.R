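make_matrix <- function(X, ids = sprintf("g%02d", seq_len(nrow(X)))) {
  out <- tibble::as_tibble(X, .name_repair = "minimal")
  names(out) <- sprintf("r%d", seq_len(ncol(X)))
  dplyr::bind_cols(tibble::tibble(gene_id = ids), out)
}

test_that("spot quality filter applies strict thresholds measurement-wise", {
  spots <- tibble::tibble(
    gene_id = c("a", "a", "b", "b"),
    sample_id = c("s1", "s2", "s1", "s2"),
    value = c(1.5, 2.0, -0.5, 0.7),
    regression_correlation = c(0.61, 0.60, 0.9, 0.59),
    signal_over_background = c(2.6, 10, 2.5, 3.0)
  )
  out <- spot_quality_filter(spots)
  expect_equal(out$s1[out$gene_id == "a"], 1.5) # 0.61 / 2.6 survives
  expect_true(is.na(out$s2[out$gene_id == "a"])) # corr exactly 0.6 fails
  expect_true(is.na(out$s1[out$gene_id == "b"])) # s/b exactly 2.5 fails
  expect_true(is.na(out$s2[out$gene_id == "b"]))
  expect_error(
    spot_quality_filter(spots[setdiff(names(spots), "signal_over_background")]),
    class = "rnc_error_format"
  )
})

test_that("spot filter survivor count equals a row-by-row recount", {
  set.seed(14)
  spots <- tidyr::expand_grid(
    gene_id = sprintf("g%03d", 1:40),
    sample_id = sprintf("s%d", 1:4)
  )
  spots$value <- rnorm(nrow(spots))
  spots$regression_correlation <- runif(nrow(spots), 0.3, 1)
  spots$signal_over_background <- runif(nrow(spots), 1, 5)
  out <- spot_quality_filter(spots)
  survivors <- sum(!is.na(as.matrix(out[-1])))
  recount <- 0
  for (i in seq_len(nrow(spots))) {
    if (spots$regression_correlation[i] > 0.6 && spots$signal_over_background[i] > 2.5) {
      recount <- recount + 1
    }
  }
  expect_equal(survivors, recount)
})

test_that("feature filter drops genes missing two or more values", {
  X <- matrix(rnorm(20), 5, 4)
  X[1, 1:2] <- NA # 2 missing -> dropped
  X[2, 1] <- NA # 1 missing -> kept
  m <- make_matrix(X)
  out <- filter_features(m)
  expect_equal(out$gene_id, m$gene_id[-1])
  # identity on complete data
  complete <- make_matrix(matrix(rnorm(12), 3, 4))
  expect_identical(filter_features(complete), complete)
})

test_that("feature filter retained set equals a brute-force recount", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  X[sample(length(X), 60)] <- NA
  m <- make_matrix(X)
  for (mm in 0:3) {
    kept <- filter_features(m, max_missing = mm)$gene_id
    manual <- m$gene_id[apply(is.na(X), 1, sum) <= mm]
    expect_identical(kept, manual)
  }
})

test_that("all-zero data yields d = 0 and no significant genes", {
  m <- make_matrix(matrix(0, 100, 4))
  fit <- sam_one_class(m, s0 = 1, seed = 1)
  expect_true(all(fit$result$d == 0))
  expect_true(all(fit$result$q == 100))
})

test_that("d and q match the exhaustive sign-flip enumeration oracle", {
  set.seed(19)
  for (rep in 1:5) {
    X <- matrix(rnorm(24, mean = rep(c(1.5, 0), c(2, 4))), 6, 4)
    m <- make_matrix(X)
    fit <- sam_one_class(m, s0 = 0, seed = 1)
    want <- oracle_sam(`rownames<-`(X, m$gene_id), s0 = 0)
    expect_equal(fit$result$d, want$d, tolerance = 1e-12)
    expect_equal(fit$result$q, want$q, tolerance = 1e-12)
  }
  # also with 3 replicates and a missing value
  X <- matrix(rnorm(18), 6, 3)
  X[2, 1] <- NA
  m <- make_matrix(X)
  fit <- sam_one_class(m, s0 = 0.1, seed = 1, impute = "none")
  want <- oracle_sam(`rownames<-`(X, m$gene_id), s0 = 0.1)
  expect_equal(fit$result$d, want$d, tolerance = 1e-12)
  expect_equal(fit$result$q, want$q, tolerance = 1e-12)
})

test_that("ranking by |d| is scale equivariant", {
  set.seed(23)
  X <- matrix(rnorm(400), 100, 4)
  m1 <- make_matrix(X)
  m2 <- make_matrix(X * 3)
  f1 <- sam_one_class(m1, s0 = 0.2, seed = 1)
  f2 <- sam_one_class(m2, s0 = 0.6, seed = 1) # s0 rescaled with the data
  expect_equal(order(abs(f1$result$d)), order(abs(f2$result$d)))
  expect_equal(f1$result$d * 1, f2$result$d, tolerance = 1e-12)
})

test_that("a gene's d ignores the positions of its missing cells", {
  x <- c(1.2, 0.8, 1.5)
  X1 <- rbind(c(x, NA), matrix(rnorm(12), 3, 4))
  X2 <- rbind(c(NA, x), matrix(rnorm(12), 3, 4))
  d1 <- sam_one_class(make_matrix(X1), s0 = 0.1, seed = 1, impute = "none")$result$d[1]
  d2 <- sam_one_class(make_matrix(X2), s0 = 0.1, seed = 1, impute = "none")$result$d[1]
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("insufficient replication is a classed error", {
  expect_error(
    sam_one_class(make_matrix(matrix(rnorm(5), 5, 1))),
    class = "rnc_error_insufficient_replicates"
  )
  X <- matrix(rnorm(12), 3, 4)
  X[1, 1:3] <- NA
  expect_error(
    sam_one_class(make_matrix(X)),
    class = "rnc_error_insufficient_replicates"
  )
})

test_that("planted signals are recovered with controlled false discoveries", {
  recs <- numeric(10)
  fdps <- numeric(10)
  for (i in 1:10) {
    g <- generate_genome(1000, seed = 100 + i)
    planted <- g$genes$gene_id[1:50]
    m <- simulate_ip(g, planted,
      effect_size = 2, noise_sd = 0.5,
      missing_rate = 0, n_replicates = 4, seed = 200 + i
    )
    called <- call_targets(sam_one_class(m, seed = 300 + i))
    recs[i] <- mean(planted %in% called)
    fdps[i] <- if (length(called) > 0) mean(!(called %in% planted)) else 0
  }
  expect_gte(mean(recs) * 50, 45) # >= 45 of 50 planted on average
  expect_lte(mean(fdps), 0.05)
  # Jaccard overlap between called and planted sets
  expect_gte(mean(recs) / (1 + mean(fdps)), 0.85)
})

test_that("target calling respects threshold monotonicity and sign", {
  set.seed(5)
  X <- matrix(rnorm(400), 100, 4)
  X[1:10, ] <- X[1:10, ] + 2
  X[11:15, ] <- X[11:15, ] - 2
  fit <- sam_one_class(make_matrix(X), seed = 1)
  t1 <- call_targets(fit, q_threshold = 1)
  t5 <- call_targets(fit, q_threshold = 5)
  expect_true(all(t1 %in% t5))
  both <- call_targets(fit, q_threshold = 1, sign = "both")
  expect_true(all(t1 %in% both))
  expect_true(all(fit$result$d[match(t1, fit$result$gene_id)] > 0))

  empty_fit <- sam_one_class(make_matrix(matrix(0, 4, 4)), s0 = 1, seed = 1)
  expect_length(call_targets(empty_fit), 0)
})

test_that("q is monotone non-increasing in |d|", {
  set.seed(77)
  X <- matrix(rnorm(240), 60, 4)
  X[1:6, ] <- X[1:6, ] + 1.5
  res <- sam_one_class(make_matrix(X), seed = 2)$result
  o <- order(-abs(res$d))
  expect_true(all(diff(res$q[o]) >= -1e-12))
})

test_that("random-pattern mode engages beyond the exhaustive budget", {
  set.seed(6)
  X <- matrix(rnorm(200), 20, 10)
  fit <- sam_one_class(make_matrix(X), n_permutations = 500, seed = 4)
  expect_false(fit$exhaustive)
  expect_equal(fit$n_permutations, 500)
  fit2 <- sam_one_class(make_matrix(X), n_permutations = 500, seed = 4)
  expect_identical(fit$result, fit2$result)
})
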