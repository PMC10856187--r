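test_that("fingerprint tables parse, validate, and round-trip", {
  df <- toy_fp_df()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fingerprint_table(fingerprint_dataset(df), path)
  ds <- read_fingerprint_table(path)
  expect_s3_class(ds, "fpc_fingerprints")
  expect_equal(nrow(ds), 3L)
  expect_true(is.na(ds$C9[3]))
  expect_true(is.na(ds$H_CHO_2[2]))
  for (slot in slot_names) expect_identical(ds[[slot]], df[[slot]])

  dup <- rbind(df, df[1, ])
  expect_error(fingerprint_dataset(dup), "duplicate compound_id.*a")

  bad <- df
  bad$C3 <- NULL
  expect_error(fingerprint_dataset(bad), "C3")

  lines <- readLines(path)
  lines[2] <- sub("163.1", "oops", lines[2], fixed = TRUE)
  bad_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, bad_path)
  expect_error(read_fingerprint_table(bad_path), "row 1, column C3")

  out_of_range <- df
  out_of_range$C1[1] <- 250
  expect_error(fingerprint_dataset(out_of_range), "C1")
})

test_that("tab-delimited fingerprint tables are sniffed", {
  df <- toy_fp_df()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  expect_equal(read_fingerprint_table(path)$C2, df$C2)
})

test_that("column-mean imputation fills gaps without moving the means", {
  df <- toy_fp_df()
  df$C9 <- c(100, 102, NA)
  imp <- impute_missing(fingerprint_dataset(df))
  expect_equal(imp$C9[3], 101)
  expect_equal(imp$C9[1:2], c(100, 102))
  expect_true(attr(imp, "imputed")[3, "C9"])

  full <- toy_fp_df()
  full$C9[3] <- 190
  full$H_CHO_2[2] <- 10.0
  imp2 <- impute_missing(fingerprint_dataset(full))
  for (slot in slot_names) expect_equal(imp2[[slot]], full[[slot]])

  # random dataset: imputation preserves observed column means exactly
  set.seed(11)
  n <- 50
  rand <- tibble::tibble(compound_id = sprintf("r%02d", 1:n),
                         class = rep(c("A", "B"), length.out = n),
                         solvent = "CDCl3")
  for (slot in slot_names) {
    lim <- if (startsWith(slot, "C")) c(80, 200) else c(8, 14)
    x <- runif(n, lim[1], lim[2])
    x[sample(n, 5)] <- NA
    rand[[slot]] <- x
  }
  ds <- fingerprint_dataset(rand)
  imp3 <- impute_missing(ds)
  for (slot in slot_names) {
    expect_equal(mean(imp3[[slot]]), mean(rand[[slot]], na.rm = TRUE),
                 tolerance = 1e-12)
  }
  expect_error(
    impute_missing(fingerprint_dataset(transform(rand, C9 = NA_real_))),
    "C9")
})

test_that("PCA recovers the closed-form solution on a rank-1 toy set", {
  x <- cbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3))
  m <- fit_pca(x, k = 2, autoscale = FALSE)
  expect_equal(unname(m$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(m$explained_variance[2], 0, tolerance = 1e-12)
  # population covariance of 0..3 is 1.25 per column; rank-1 eigenvalue 2.5
  expect_equal(m$explained_variance[1], 2.5, tolerance = 1e-12)
  # hand oracle for the score of (3, 3): centered (1.5, 1.5) along (1,1)/sqrt 2
  expect_equal(drop(project(m, c(a = 3, b = 3)))[1], 1.5 * sqrt(2),
               tolerance = 1e-12)
  expect_equal(drop(project(m, c(a = 1.5, b = 1.5))), c(0, 0),
               tolerance = 1e-12)
})

test_that("PCA loadings are orthonormal and complete", {
  set.seed(21)
  x <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(NULL, slot_names))
  m <- fit_pca(x, k = 12, autoscale = TRUE)
  expect_lt(max(abs(crossprod(m$loadings) - diag(12))), 1e-8)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_equal(sum(m$explained_variance), m$total_variance, tolerance = 1e-8)
  # autoscaled population covariance has unit diagonal: total variance = 12
  expect_equal(m$total_variance, 12, tolerance = 1e-8)
  # completeness: projecting and reconstructing recovers the processed matrix
  z <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  expect_lt(max(abs(project(m, x) %*% t(m$loadings) - z)), 1e-8)
  # sign convention: largest-magnitude element of each loading is positive
  for (j in 1:12) expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
})

test_that("PCA agrees with prcomp up to the sign convention", {
  set.seed(22)
  x <- matrix(rnorm(60 * 12, 100, 5), 60, 12,
              dimnames = list(NULL, slot_names))
  m <- fit_pca(x, k = 4, autoscale = FALSE)
  ref <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in 1:4) {
    expect_equal(abs(sum(m$loadings[, j] * ref$rotation[, j])), 1,
                 tolerance = 1e-8)
  }
  # population vs sample convention differs by (n-1)/n
  n <- nrow(x)
  expect_equal(m$explained_variance,
               ref$sdev[1:4]^2 * (n - 1) / n, tolerance = 1e-8)
})

test_that("degenerate and invalid PCA inputs are handled", {
  x <- matrix(rep(c(1, 2), each = 5), 5, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_pca(x, k = 2, autoscale = FALSE)
  expect_equal(unname(m$explained_variance), c(0, 0))
  expect_equal(unname(project(m, x)), matrix(0, 5, 2), tolerance = 1e-12)
  expect_error(fit_pca(x, k = 2, autoscale = TRUE), "zero-variance")
  expect_error(fit_pca(x[1:2, ], k = 2, autoscale = FALSE), "more observations")
})

test_that("projection is affine and blind to directions outside the basis", {
  set.seed(23)
  x <- matrix(rnorm(40 * 12), 40, 12, dimnames = list(NULL, slot_names))
  full <- fit_pca(x, k = 12, autoscale = FALSE)
  m <- fit_pca(x, k = 2, autoscale = FALSE)
  v <- rnorm(12)
  base <- drop(project(m, m$center))
  for (a in c(-2, 0.5, 3)) {
    expect_equal(drop(project(m, m$center + a * v)) - base,
                 a * (drop(project(m, m$center + v)) - base),
                 tolerance = 1e-10)
  }
  # a difference along a discarded eigenvector leaves the scores unchanged
  w <- full$loadings[, 12]
  p1 <- drop(project(m, m$center + v))
  p2 <- drop(project(m, m$center + v + 5 * w))
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("nearest-centroid assignment is exact at centroids and accurate in simulation", {
  ds <- gen_fingerprint_dataset(make_class_templates(n_classes = 2,
                                                     separation = 10),
                                n_per_class = 20, seed = 5)
  imp <- impute_missing(ds)
  model <- fit_pca(imp, k = 2)
  cls <- "pyrano-diformyl"
  scores <- project(model, imp)
  cent <- colMeans(scores[ds$class == cls, , drop = FALSE])
  # invert the projection of the centroid back to slot space for an exact hit
  fp_at_centroid <- model$center + model$scale *
    drop(model$loadings %*% cent)
  names(fp_at_centroid) <- slot_names
  res <- assign_class(model, imp, fp_at_centroid)
  expect_equal(res$nearest_class, cls)
  expect_equal(res$distances$distance[1], 0, tolerance = 1e-8)

  # two classes, inter-centroid distance ~10x within-class spread:
  # held-out records assign correctly in at least 95% of 200 draws
  big <- gen_fingerprint_dataset(make_class_templates(n_classes = 2,
                                                      separation = 10),
                                 n_per_class = 100, seed = 6)
  expect_gte(loo_centroid_accuracy(big, k = 2), 0.95)
})

test_that("assign_class breaks ties lexicographically and notes tiny classes", {
  df <- toy_fp_df()  # class oxepine-diformyl has a single member
  imp <- impute_missing(fingerprint_dataset(df))
  model <- fit_pca(imp, k = 2)
  res <- assign_class(model, imp, imp[3, ])
  expect_match(res$distances$note[res$distances$class == "oxepine-diformyl"],
               "fewer than 2")
  expect_error(
    assign_class(model, fingerprint_dataset(transform(df, class = "one")),
                 imp[1, ]),
    "at least 2 distinct")
})

test_that("range deviations follow the clamp rule and ignore translations", {
  ds <- gen_fingerprint_dataset(make_class_templates(), 10, seed = 9)
  rng <- class_range_table(ds)
  expect_true(all(rng$min_ppm <= rng$max_ppm))
  expect_true(all(rng$n >= 3))

  # hand-built range check: value 110 against [95, 105] deviates by 5
  df <- toy_fp_df()[rep(1, 4), ]
  df$compound_id <- paste0("p", 1:4)
  df$C2 <- c(95, 100, 105, 99)
  ds2 <- fingerprint_dataset(df)
  fp <- df[1, ]
  fp$C2 <- 110
  rd <- range_deviation(ds2, fp, "pyrano-diformyl")
  expect_equal(rd$deviations$deviation_ppm[rd$deviations$slot == "C2"], 5)
  fp$C2 <- 101
  rd2 <- range_deviation(ds2, fp, "pyrano-diformyl")
  expect_equal(rd2$deviations$deviation_ppm[rd2$deviations$slot == "C2"], 0)

  expect_error(range_deviation(ds2, fp, "nope"),
               "available: pyrano-diformyl")

  # translation consistency: shifting class records and the query together
  shift <- 3.7
  df3 <- df
  df3$C2 <- df3$C2 + shift
  fp3 <- fp
  fp3$C2 <- fp3$C2 + shift
  rd3 <- range_deviation(fingerprint_dataset(df3), fp3, "pyrano-diformyl")
  expect_equal(rd3$deviations$deviation_ppm, rd2$deviations$deviation_ppm,
               tolerance = 1e-12)

  # missing slots are reported unevaluated, not scored
  fp4 <- fp
  fp4$C9 <- NA_real_
  rd4 <- range_deviation(ds2, fp4, "pyrano-diformyl")
  expect_true("C9" %in% rd4$unevaluated)
})

test_that("misassignment flagging combines the PCA and range rules", {
  ds <- gen_fingerprint_dataset(make_class_templates(), 30, seed = 1)
  consistent <- ds[1, ]
  rep_ok <- flag_misassignment(fingerprint_dataset(ds[-1, ]), consistent)
  expect_false(rep_ok$flagged)
  expect_equal(rep_ok$pca_nearest_class, consistent$class)

  planted <- ds[1, ]
  planted$class <- "oxepine-diformyl"
  planted$compound_id <- "planted"
  rep_bad <- flag_misassignment(fingerprint_dataset(ds[-1, ]), planted)
  expect_true(rep_bad$flagged)
  expect_false(rep_bad$pca_nearest_class == planted$class)

  # with an infinite threshold and an agreeing PCA class, never flagged
  rep_inf <- flag_misassignment(fingerprint_dataset(ds[-1, ]), consistent,
                                threshold = Inf)
  expect_false(rep_inf$flagged)
})

test_that("the bundled synthetic fixture classifies cleanly", {
  path <- system.file("extdata", "synthetic_fingerprints.csv",
                      package = "fpcrevise")
  ds <- read_fingerprint_table(path)
  expect_equal(nrow(ds), 30L)
  expect_gte(loo_centroid_accuracy(ds, k = 2), 0.9)
})
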