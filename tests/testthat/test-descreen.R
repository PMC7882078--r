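test_that("knn imputation fills gaps from nearest observed neighbours", {
  st <- make_study(n_features = 6, n_per_group = 2, seed = 5)
  expect_identical(knn_impute(st, k = 2)$values, st$values)

  vals <- rbind(A = c(NA, 1, 2, 3), B = c(5, 1.1, 2.1, 3.1),
                C = c(50, 60, 70, 80))
  colnames(vals) <- paste0("s", 1:4)
  st <- expression_study(vals, c("disease", "disease", "control", "control"))
  out <- knn_impute(st, k = 1)
  expect_equal(out$values["A", 1], 5)          # B is the unique neighbour
  expect_identical(out$values[-1, ], st$values[-1, ])

  set.seed(9)
  vals <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
  vals[cbind(c(1, 3, 4), c(2, 4, 1))] <- NA
  st <- expression_study(vals, c("disease", "disease", "control", "control"))
  expect_equal(knn_impute(st, k = 2)$values, knn_oracle(vals, 2))

  vals[2, ] <- NA
  expect_error(expression_study(vals, rep(c("disease", "control"), each = 2)) |>
                 knn_impute(k = 2), "f2")
})

test_that("outlier statistics honour their degenerate and hand cases", {
  # COPA: centred disease values are all zero, so any percentile is zero
  expect_equal(outlier_statistic(c(0, 0, 0, 0), c(-1, 1, -2, 2), "COPA"), 0)
  # OS: no disease value above q75 + IQR of the pooled data -> empty sum
  expect_equal(outlier_statistic(c(1, 2), c(0, 1, 2, 3), "OS"), 0)
  # Welch t hand oracle: means 2 vs 5, per-group variance 1
  expect_equal(outlier_statistic(c(4, 5, 6), c(1, 2, 3), "t"),
               3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(outlier_statistic(c(4, 5, 6), c(1, 2, 3), "t"), 4),
               3.6742)
  expect_error(outlier_statistic(c(1, 2, 3), c(5, 5, 5, 5), "ORT"),
               "degenerate")
})

test_that("MOST and LSOSS match exhaustive subset oracles", {
  set.seed(21)
  for (i in 1:120) {
    d <- rnorm(6, 7); c0 <- rnorm(6, 7)
    if (i %% 3 == 0) d[1:2] <- d[1:2] + 4  # planted outliers
    expect_equal(outlier_statistic(d, c0, "MOST"), most_oracle(d, c0),
                 tolerance = 1e-10)
    expect_equal(outlier_statistic(d, c0, "LSOSS"), lsoss_oracle(d, c0),
                 tolerance = 1e-10)
  }
})

test_that("all six statistics are invariant under a global location shift", {
  set.seed(31)
  for (i in 1:20) {
    d <- rnorm(8, 7); c0 <- rnorm(10, 7)
    shift <- runif(1, -50, 50)
    for (m in c("t", "COPA", "OS", "ORT", "MOST", "LSOSS")) {
      expect_equal(outlier_statistic(d + shift, c0 + shift, m),
                   outlier_statistic(d, c0, m), tolerance = 1e-8)
    }
  }
})

test_that("outlier statistics are non-decreasing in a planted up-outlier", {
  set.seed(41)
  d0 <- rnorm(9, 7); c0 <- rnorm(9, 7)
  for (m in c("COPA", "OS", "ORT", "MOST", "LSOSS")) {
    prev <- -Inf
    for (mag in seq(2, 10, by = 1)) {
      d <- d0; d[1] <- d[1] + mag
      cur <- outlier_statistic(d, c0, m)
      expect_gte(cur, prev - 1e-8)
      prev <- cur
    }
  }
})

test_that("top-fraction gene lists are ranked, truncated and tie-stable", {
  st1 <- make_study(n_features = 10, n_per_group = 5, seed = 51,
                    shift_features = c("f001", "f002"), shift = 4)
  st2 <- make_study(n_features = 10, n_per_group = 5, seed = 52,
                    shift_features = c("f001", "f002"), shift = 4)
  lists <- de_genes(list(st1, st2), method = "t", top_fraction = 0.4)
  expect_equal(lengths(lists), c(4L, 4L))
  expect_true(all(c("f001", "f002") %in% lists[[1]]))
  full <- de_genes(list(st1), method = "t", top_fraction = 1)[[1]]
  expect_setequal(full, rownames(st1$values))

  # planted subgroup outliers occupy top ranks under the outlier statistics
  st3 <- make_study(n_features = 60, n_per_group = 10, seed = 53,
                    shift_features = sprintf("f%03d", 1:6), shift = 5,
                    subgroup = 3)
  top <- de_genes(list(st3), method = "OS", top_fraction = 0.15)[[1]]
  expect_true(all(sprintf("f%03d", 1:6) %in% top))
})

test_that("method selection maximizes mean pairwise overlap", {
  a <- list(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
  b <- list(c("g1", "g2", "g3"), c("g4", "g5", "g6"))
  sel <- select_method_by_overlap(list(t = a, COPA = b))
  expect_identical(sel$best, "t")
  expect_equal(sel$report$mean_overlap, c(100, 0))

  expect_identical(select_method_by_overlap(list(OS = b))$best, "OS")

  # randomized case against an exhaustive pairwise-intersection oracle
  set.seed(61)
  universe <- sprintf("g%02d", 1:40)
  lists <- lapply(c(t = 1, OS = 2, MOST = 3), function(i) {
    lapply(1:3, function(j) sample(universe, 10))
  })
  sel <- select_method_by_overlap(lists)
  oracle <- sapply(lists, function(l) {
    o <- c()
    for (i in 1:2) for (j in (i + 1):3) {
      o <- c(o, 100 * length(intersect(l[[i]], l[[j]])) / 10)
    }
    mean(o)
  })
  expect_equal(sel$report$mean_overlap, unname(oracle[sel$report$method]))
  expect_identical(sel$best, names(which.max(oracle))[1])
})

test_that("miRNA t screening controls direction and the alpha boundary", {
  st <- make_study(n_features = 10, n_per_group = 9, seed = 71,
                   shift_features = "f001", shift = 6)
  de <- de_mirnas(st, alpha = 0.05)
  expect_true("f001" %in% de$feature_id)
  expect_identical(de$direction[de$feature_id == "f001"], "up")

  all_feats <- de_mirnas(st, alpha = 1)
  expect_equal(nrow(all_feats), 10)

  vals <- st$values
  vals["f002", ] <- 3  # constant everywhere: untestable
  st2 <- expression_study(vals, st$groups)
  expect_warning(de2 <- de_mirnas(st2, alpha = 1), "skipped")
  expect_false("f002" %in% de2$feature_id)
})

test_that("outlier statistics beat t for subgroup shifts, not uniform ones", {
  set.seed(81)
  n_sig <- 40
  sig_ids <- sprintf("f%03d", seq_len(n_sig))
  st_sub <- make_study(n_features = 400, n_per_group = 20, seed = 82,
                       shift_features = sig_ids, shift = 3, subgroup = 5)
  detect <- function(study, method) {
    top <- de_genes(list(study), method = method, top_fraction = 0.1)[[1]]
    mean(sig_ids %in% top)
  }
  t_rate <- detect(st_sub, "t")
  for (m in c("COPA", "OS", "ORT", "MOST", "LSOSS")) {
    expect_gt(detect(st_sub, m), t_rate)
  }
  # uniform whole-group shift: t is competitive with the best outlier stat
  st_uni <- make_study(n_features = 400, n_per_group = 20, seed = 83,
                       shift_features = sig_ids, shift = 1.2)
  rates <- sapply(c("t", "COPA", "OS", "ORT", "MOST", "LSOSS"),
                  function(m) detect(st_uni, m))
  expect_gte(rates["t"], max(rates) - 0.1)
})
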