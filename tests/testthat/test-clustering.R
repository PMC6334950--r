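test_that("correlation filter drops the later-listed of a correlated pair", {
  set.seed(3)
  n <- 60
  x <- rnorm(n)
  data <- tibble::tibble(a = x, b = x, c = rnorm(n), d = rnorm(n))
  # identical columns: rho = 1, later one dropped
  expect_equal(select_segmentation_base(data, c("a", "b", "c")),
               c("a", "c"))
  # independent columns all retained
  expect_equal(select_segmentation_base(data, c("a", "c", "d")),
               c("a", "c", "d"))
  # a pair just under the threshold is kept
  rho_target <- 0.74
  y <- rho_target * scale(x)[, 1] + sqrt(1 - rho_target^2) * scale(rnorm(n))[, 1]
  data$e <- y
  r <- cor(data$a, data$e)
  expect_lt(abs(r), 0.75)
  expect_equal(select_segmentation_base(data, c("a", "e")), c("a", "e"))

  # cap: at most one variable per ten observations
  small <- data[1:20, ]
  expect_length(select_segmentation_base(small, c("a", "c", "d")), 2)
  expect_error(
    select_segmentation_base(tibble::tibble(a = letters[1:20]), "a"),
    "numeric")
})

test_that("standardization yields centered unit-variance columns and is scale invariant", {
  data <- tibble::tibble(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_cohort(data)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  z10 <- standardize_cohort(dplyr::mutate(data, a = a * 10))
  expect_equal(c(z10), c(z))
  # sample-sd convention
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_error(standardize_cohort(tibble::tibble(a = rep(1, 5))), "a")
})

test_that("Ward agglomeration matches the brute-force minimum-variance oracle", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(3:7, 1)
    x <- matrix(rnorm(n * sample(2:4, 1)), nrow = n)
    hc <- ward_cluster(x)
    expect_lt(max(abs(ward_oracle_cophenetic(x) -
                        as.matrix(stats::cophenetic(hc)))), 1e-8)
    expect_true(all(diff(hc$height) >= -1e-12)) # monotone heights
  }
  # two tight pairs far apart: first merges are within-pair
  x <- rbind(c(0, 0), c(0.01, 0), c(10, 10), c(10, 10.02))
  hc <- ward_cluster(x)
  expect_setequal(hc$merge[1, ], c(-1, -2))
  expect_setequal(hc$merge[2, ], c(-3, -4))
  # n = 2: one merge at the Euclidean distance
  x2 <- rbind(c(0, 0), c(3, 4))
  expect_equal(ward_cluster(x2)$height, 5)
  expect_error(ward_cluster(x2[1, , drop = FALSE]), "at least 2")
})

test_that("silhouette selection finds the generating number of well-separated groups", {
  set.seed(23)
  blobs <- rbind(
    matrix(rnorm(40, 0), ncol = 2),
    matrix(rnorm(40, 8), ncol = 2),
    matrix(rnorm(40, c(0, 16)), ncol = 2)
  )
  d <- dist(blobs)
  hc <- stats::hclust(d, method = "ward.D2")
  sel <- choose_k(hc, d, 2:6)
  expect_equal(sel$chosen_k, 3)
  expect_true(all(sel$widths$sil_width >= -1 & sel$widths$sil_width <= 1))

  two <- rbind(matrix(rnorm(30, 0, 0.1), ncol = 2),
               matrix(rnorm(30, 20, 0.1), ncol = 2))
  d2 <- dist(two)
  sel2 <- choose_k(stats::hclust(d2, method = "ward.D2"), d2, 2:6)
  expect_equal(sel2$chosen_k, 2)
  expect_error(choose_k(hc, d, integer(0)), "empty")
  expect_error(choose_k(hc, d, 1:3), "k_range")
})

test_that("cluster profiles reproduce hand-computed medians and center correctly", {
  data <- tibble::tibble(v = c(1, 2, 3, 10, 20, 30))
  labels <- c(1, 1, 1, 2, 2, 2)
  prof <- cluster_profiles(data, labels)
  expect_equal(prof$profiles$median, c(2, 20))
  expect_equal(prof$profiles$q1, c(1.5, 15))
  expect_equal(prof$profiles$q3, c(2.5, 25))
  # single cluster: scaled medians are zero
  one <- cluster_profiles(data, rep(1, 6))
  expect_equal(one$scaled_medians$scaled_median, 0)
  # constant variable flags a zero scale
  expect_warning(
    cluster_profiles(tibble::tibble(v = rep(1, 4)), c(1, 1, 2, 2)),
    "zero overall IQR")
})

test_that("the clustering pipeline is invariant to row order", {
  d <- derive_cohort(simulate_cohort(noise_sd = 0.2, seed = 8))
  fit <- cluster_cohort(d)
  set.seed(99)
  perm <- sample(nrow(d))
  fit_p <- cluster_cohort(d[perm, ])
  expect_equal(fit_p$chosen_k, fit$chosen_k)
  expect_equal(sort(tabulate(fit_p$labels)), sort(tabulate(fit$labels)))
  # identical partition up to label names
  tab <- table(fit$labels[perm], fit_p$labels)
  expect_equal(sum(apply(tab, 1, max)), nrow(d))
})

test_that("tidy, glance and plot methods expose the fit", {
  d <- derive_cohort(simulate_cohort(noise_sd = 0.2, seed = 4))
  fit <- cluster_cohort(d)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(d))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(d))
  expect_equal(gl$chosen_k, fit$chosen_k)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_silhouette(fit), "ggplot")
  expect_output(print(fit), "Ward")
})
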