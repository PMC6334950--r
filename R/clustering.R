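#' Default segmentation base for cohort clustering
#'
#' The eleven candidate variables, in physiological priority order, used
#' to segment a post-parturient cohort: the temperature-corrected blood pH
#' as the main dependent acid-base variable; the independent strong-ion
#' determinants Atot(Alb) and SID_m5; the albumin/globulin ratio and
#' hematocrit (dilution/hemoconcentration); BHB, NEFA and SIG(Prt) for the
#' unmeasured-ion and energy-balance axis; and urinary sodium, chloride
#' and the base-acid ratio for renal acid-base excretion.
#'
#' @return Character vector of column names.
#' @export
default_segmentation_variables <- function() {
  c("pH_BT", "Atot_alb", "SID_m5", "AGR", "Hct",
    "cBHB", "cNEFA", "SIG_prt", "cNa_u", "cCl_u", "BAR")
}

#' Select a segmentation base by correlation filtering
#'
#' Walks the candidate list in priority order, dropping any candidate
#' whose absolute Pearson correlation with an already-retained variable
#' reaches `correlation_threshold`, and caps the retained list at
#' `floor(nrow(data) * max_vars_per_obs)` variables (at most one variable
#' per ten observations by default).
#'
#' @param data Cohort data frame containing the candidate columns.
#' @param candidates Ordered character vector of candidate variables
#'   (earlier = higher physiological priority).
#' @param correlation_threshold Absolute Pearson correlation at or above
#'   which the later-listed variable of a pair is dropped; default 0.75.
#' @param max_vars_per_obs Maximum retained variables per observation;
#'   default 0.1.
#' @param max_missing Maximum fraction of missing values tolerated per
#'   candidate; default 0.2.
#' @return Character vector of retained variable names.
#' @export
select_segmentation_base <- function(data,
                                     candidates = default_segmentation_variables(),
                                     correlation_threshold = 0.75,
                                     max_vars_per_obs = 0.1,
                                     max_missing = 0.2) {
  stopifnot(is.data.frame(data), length(candidates) > 0)
  check_range(correlation_threshold, "correlation_threshold", 0, 1,
              open = TRUE)
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols) > 0) {
    stop("candidate variable(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (v in candidates) {
    if (!is.numeric(data[[v]])) {
      stop("candidate variable ", v, " is not numeric", call. = FALSE)
    }
    if (mean(is.na(data[[v]])) > max_missing) {
      stop("candidate variable ", v, " exceeds the missingness limit",
           call. = FALSE)
    }
  }
  cap <- max(1L, floor(nrow(data) * max_vars_per_obs))
  kept <- character(0)
  for (v in candidates) {
    if (length(kept) >= cap) break
    ok <- all(vapply(kept, function(w) {
      r <- stats::cor(data[[v]], data[[w]], use = "complete.obs",
                      method = "pearson")
      is.na(r) || abs(r) < correlation_threshold
    }, logical(1)))
    if (ok) kept <- c(kept, v)
  }
  kept
}

#' Standardize segmentation variables to z-scores
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation (n - 1 divisor).
#'
#' @param data Data frame containing `variables`.
#' @param variables Columns to standardize; defaults to all numeric.
#' @return A numeric matrix with one z-scored column per variable;
#'   centering/scaling stored in attributes `center` and `scale`.
#' @export
standardize_cohort <- function(data, variables = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  m <- as.matrix(data[, variables, drop = FALSE])
  if (anyNA(m)) stop("missing values in segmentation variables", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  zero <- variables[sds == 0]
  if (length(zero) > 0) {
    stop("zero-variance column(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  z <- scale(m, center = TRUE, scale = TRUE)
  structure(z[, , drop = FALSE],
            center = attr(z, "scaled:center"),
            scale = attr(z, "scaled:scale"))
}

#' Ward minimum-variance agglomeration
#'
#' Hierarchical clustering of the standardized matrix using Euclidean
#' distances and the Ward.D2 minimum-variance criterion: at each step the
#' merged pair minimizes the increase in total within-cluster sum of
#' squares, with merge heights on the (unsquared) Euclidean scale.
#'
#' @param z Numeric matrix of standardized observations (rows = animals).
#' @return An object of class `hclust`.
#' @export
ward_cluster <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(z)) stop("missing values in clustering input", call. = FALSE)
  stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
}

#' Silhouette-guided choice of the cluster number
#'
#' Cuts the tree at each candidate `k`, computes mean silhouette widths
#' from the Euclidean distance matrix, and returns the `k` maximizing the
#' mean width (ties broken toward the smaller `k`).  The full per-k table
#' is returned so the complementary criterion — physiological
#' interpretability of the clusters — can be applied by the analyst.
#'
#' @param hc An `hclust` tree from [ward_cluster()].
#' @param d A `dist` object over the same observations.
#' @param k_range Integer vector of candidate cluster numbers, within
#'   `[2, n - 1]`.
#' @return A list with `chosen_k`, `mean_widths` (tibble of k and mean
#'   silhouette width) and `widths` (per-observation widths at chosen k).
#' @export
choose_k <- function(hc, d, k_range = 2:12) {
  if (length(k_range) == 0) stop("k_range is empty", call. = FALSE)
  n <- attr(d, "Size")
  k_range <- as.integer(sort(unique(k_range)))
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  mean_widths <- purrr::map_dfr(k_range, function(k) {
    labels <- stats::cutree(hc, k = k)
    sil <- cluster::silhouette(labels, d)
    tibble::tibble(k = k, mean_width = mean(sil[, "sil_width"]))
  })
  chosen_k <- mean_widths$k[which.max(mean_widths$mean_width)]
  labels <- stats::cutree(hc, k = chosen_k)
  sil <- cluster::silhouette(labels, d)
  list(
    chosen_k = chosen_k,
    mean_widths = mean_widths,
    widths = tibble::tibble(
      observation = seq_len(n),
      cluster = as.integer(sil[, "cluster"]),
      sil_width = sil[, "sil_width"]
    )
  )
}

#' Per-cluster profiles and centered/scaled medians
#'
#' For every numeric variable, computes the median and first/third
#' quartiles within each cluster, plus the centered and scaled cluster
#' medians used for profile plots:
#' (cluster median - overall median) / overall IQR.  Variables with zero
#' overall IQR get `NA` scaled medians (flagged by a warning) rather than
#' an error, since profiling covers all cohort variables, not only the
#' segmentation base.
#'
#' @param data Cohort data frame.
#' @param labels Integer cluster labels, one per row of `data`.
#' @param variables Variables to profile; defaults to all numeric columns.
#' @return A list with tibbles `profiles` (cluster, variable, n, median,
#'   q1, q3) and `scaled_medians` (cluster, variable, scaled_median).
#' @export
cluster_profiles <- function(data, labels, variables = NULL) {
  stopifnot(is.data.frame(data), length(labels) == nrow(data))
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  long <- data |>
    dplyr::mutate(.cluster = as.integer(factor(labels))) |>
    tidyr::pivot_longer(dplyr::all_of(variables), names_to = "variable",
                        values_to = "value")
  profiles <- long |>
    dplyr::group_by(.data$.cluster, .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value, na.rm = TRUE),
      q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::rename(cluster = ".cluster")
  overall <- long |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      overall_median = stats::median(.data$value, na.rm = TRUE),
      overall_iqr = stats::IQR(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(overall$overall_iqr == 0)) {
    warning("zero overall IQR for: ",
            paste(overall$variable[overall$overall_iqr == 0],
                  collapse = ", "),
            "; scaled medians set to NA", call. = FALSE)
  }
  scaled <- profiles |>
    dplyr::left_join(overall, by = "variable") |>
    dplyr::mutate(scaled_median = ifelse(
      .data$overall_iqr == 0, NA_real_,
      (.data$median - .data$overall_median) / .data$overall_iqr
    )) |>
    dplyr::select("cluster", "variable", "scaled_median")
  list(profiles = profiles, scaled_medians = scaled)
}

#' Cluster a cohort into physiological states
#'
#' Runs the full exploratory pipeline on a derived cohort table:
#' correlation-filtered selection of the segmentation base,
#' z-standardization, Euclidean distances, Ward minimum-variance
#' agglomeration, silhouette-guided choice of the cluster number, and
#' per-cluster median/IQR profiling with centered/scaled medians.  Rows
#' with missing segmentation values are dropped (with a message).
#'
#' @param data Derived cohort tibble (e.g. from [derive_cohort()]).
#' @param candidates Ordered candidate segmentation variables.
#' @param k_range Candidate cluster numbers; default 2:12.
#' @param correlation_threshold,max_vars_per_obs Passed to
#'   [select_segmentation_base()].
#' @return An object of class `acidbase_clust`: a list with `variables`,
#'   `hclust`, `distances`, `chosen_k`, `labels`, `silhouette` (per-k mean
#'   widths), `widths` (per-observation), `profiles`, `scaled_medians`,
#'   `data` (the rows clustered), `n`.
#' @examples
#' \donttest{
#' cohort <- derive_cohort(simulate_cohort(seed = 1))
#' fit <- cluster_cohort(cohort)
#' glance(fit)
#' }
#' @export
cluster_cohort <- function(data,
                           candidates = default_segmentation_variables(),
                           k_range = 2:12,
                           correlation_threshold = 0.75,
                           max_vars_per_obs = 0.1) {
  stopifnot(is.data.frame(data))
  present <- intersect(candidates, names(data))
  if (length(present) < length(candidates)) {
    stop("candidate variable(s) not in data: ",
         paste(setdiff(candidates, names(data)), collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(data[, candidates, drop = FALSE])
  if (any(!complete)) {
    message("dropping ", sum(!complete),
            " row(s) with missing segmentation values")
    data <- data[complete, , drop = FALSE]
  }
  vars <- select_segmentation_base(
    data, candidates,
    correlation_threshold = correlation_threshold,
    max_vars_per_obs = max_vars_per_obs
  )
  z <- standardize_cohort(data, vars)
  d <- stats::dist(z, method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  sel <- choose_k(hc, d, k_range)
  labels <- stats::cutree(hc, k = sel$chosen_k)
  prof <- cluster_profiles(data, labels)
  structure(
    list(
      variables = vars,
      hclust = hc,
      distances = d,
      chosen_k = sel$chosen_k,
      labels = as.integer(labels),
      silhouette = sel$mean_widths,
      widths = sel$widths,
      profiles = prof$profiles,
      scaled_medians = prof$scaled_medians,
      data = tibble::as_tibble(data),
      n = nrow(data)
    ),
    class = "acidbase_clust"
  )
}

#' @export
print.acidbase_clust <- function(x, ...) {
  cat("Acid-base cohort clustering (Ward.D2, Euclidean, z-scored)\n")
  cat("  observations:", x$n, "\n")
  cat("  segmentation base:", paste(x$variables, collapse = ", "), "\n")
  cat("  chosen k:", x$chosen_k,
      sprintf("(mean silhouette %.3f)\n",
              x$silhouette$mean_width[x$silhouette$k == x$chosen_k]))
  cat("  cluster sizes:", paste(tabulate(x$labels), collapse = "/"), "\n")
  invisible(x)
}

#' Tidy a cohort clustering fit
#'
#' One row per observation: recovered cluster label and silhouette width.
#'
#' @param x An `acidbase_clust` object.
#' @param ... Unused.
#' @return A tibble with `observation`, `cluster`, `sil_width`.
#' @exportS3Method generics::tidy
tidy.acidbase_clust <- function(x, ...) {
  x$widths
}

#' Glance at a cohort clustering fit
#'
#' @param x An `acidbase_clust` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_variables`, `chosen_k`,
#'   `mean_silhouette`, `min_cluster_size`, `max_cluster_size`.
#' @exportS3Method generics::glance
glance.acidbase_clust <- function(x, ...) {
  sizes <- tabulate(x$labels)
  tibble::tibble(
    n = x$n,
    n_variables = length(x$variables),
    chosen_k = x$chosen_k,
    mean_silhouette = x$silhouette$mean_width[x$silhouette$k == x$chosen_k],
    min_cluster_size = min(sizes),
    max_cluster_size = max(sizes)
  )
}

#' Plot a cohort clustering fit
#'
#' Tile plot of the centered/scaled cluster medians over the segmentation
#' base — blue below the cohort median, red above — the standard way to
#' read the physiological character of each cluster.
#'
#' @param object An `acidbase_clust` object.
#' @param variables Variables to display; defaults to the segmentation
#'   base.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.acidbase_clust <- function(object, variables = object$variables,
                                    ...) {
  df <- dplyr::filter(object$scaled_medians,
                      .data$variable %in% variables)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$cluster),
    y = factor(.data$variable, levels = rev(variables)),
    fill = .data$scaled_median
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  name = "scaled\nmedian") +
    ggplot2::labs(x = "cluster", y = NULL) +
    ggplot2::theme_minimal()
}

#' Silhouette-width profile across candidate cluster numbers
#'
#' @param fit An `acidbase_clust` object.
#' @return A ggplot object of mean silhouette width against k.
#' @export
plot_silhouette <- function(fit) {
  stopifnot(inherits(fit, "acidbase_clust"))
  ggplot2::ggplot(fit$silhouette,
                  ggplot2::aes(x = .data$k, y = .data$mean_width)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = fit$chosen_k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters",
                  y = "mean silhouette width") +
    ggplot2::theme_minimal()
}
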