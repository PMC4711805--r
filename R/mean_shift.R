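#' Kernel density estimate at a point
#'
#' Evaluates `f(x) = 1/(n h^d) * sum_i K((x - x_i)/h)` with
#' `K(x) = c_kd * k(||x||^2)`.
#'
#' @param x Numeric query vector.
#' @param data Numeric matrix (rows are data points) or data frame with the
#'   same number of columns as `length(x)`.
#' @param kernel A [kernel_spec()] or kernel name.
#' @param bandwidth Kernel bandwidth `h` (> 0), in feature (count) units.
#' @return A non-negative scalar; strictly positive for the gaussian kernel.
#' @export
density_estimate <- function(x, data, kernel = "gaussian", bandwidth) {
  data <- as_point_matrix(data)
  if (nrow(data) == 0L) {
    abort("density_estimate needs at least one data point",
      class = "islandshift_input_error"
    )
  }
  stopifnot(bandwidth > 0, length(x) == ncol(data))
  kernel <- as_kernel_spec(kernel, ncol(data))
  d2 <- scaled_sq_dist(x, data, bandwidth)
  kernel$c_kd * sum(kernel$k(d2)) / (nrow(data) * bandwidth^ncol(data))
}

#' Mean-shift vector at a point
#'
#' The shadow-weighted mean of the data minus `x`:
#' `m_h(x) = sum_i x_i g(||(x - x_i)/h||^2) / sum_i g(...) - x`.
#' It points in the direction of maximum density increase. With the flat
#' kernel this is the centroid of the points within distance `h` minus `x`.
#'
#' @inheritParams density_estimate
#' @return A numeric vector of the same length as `x`. When every shadow
#'   weight vanishes (an isolated point under the flat kernel, or total
#'   numerical underflow under the gaussian), a condition of class
#'   `islandshift_isolated_point` is signalled; [shift_to_mode()] treats such
#'   a point as its own mode.
#' @export
mean_shift_vector <- function(x, data, kernel = "gaussian", bandwidth) {
  data <- as_point_matrix(data)
  kernel <- as_kernel_spec(kernel, ncol(data))
  w <- kernel$g(scaled_sq_dist(x, data, bandwidth))
  sw <- sum(w)
  if (sw == 0) {
    abort("all mean-shift weights are zero (isolated point)",
      class = "islandshift_isolated_point"
    )
  }
  colSums(data * w) / sw - x
}

#' Iterate a point to its density mode
#'
#' Repeats `x <- x + m_h(x)` until the displacement norm drops below
#' `epsilon` or `max_iterations` is reached. Under the gaussian kernel the
#' estimated density is non-decreasing along the trajectory.
#'
#' @param x0 Numeric start point.
#' @inheritParams density_estimate
#' @param epsilon Convergence threshold on the displacement norm.
#' @param max_iterations Iteration cap; hitting it flags `converged = FALSE`
#'   rather than erroring.
#' @return A list with `start_point`, `mode`, `iterations` and `converged`.
#' @export
shift_to_mode <- function(x0, data, kernel = "gaussian", bandwidth,
                          epsilon = 1e-3, max_iterations = 500L) {
  data <- as_point_matrix(data)
  kernel <- as_kernel_spec(kernel, ncol(data))
  stopifnot(bandwidth > 0, epsilon > 0, max_iterations >= 1L)
  x <- as.numeric(x0)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iterations) {
    m <- tryCatch(
      mean_shift_vector(x, data, kernel, bandwidth),
      islandshift_isolated_point = function(cnd) NULL
    )
    if (is.null(m)) { # no point carries weight: x is its own mode
      converged <- TRUE
      break
    }
    iterations <- iterations + 1L
    x <- x + m
    if (sqrt(sum(m^2)) < epsilon) {
      converged <- TRUE
      break
    }
  }
  list(start_point = as.numeric(x0), mode = x, iterations = iterations, converged = converged)
}

#' Group converged modes into clusters
#'
#' Single-linkage grouping: two modes belong to the same cluster when they
#' are connected by a chain of pairwise distances strictly below
#' `merge_radius` (floating-point convergence never lands two points on
#' exactly the same mode, so a tolerance is required). Implemented as
#' connected components of the `< merge_radius` proximity graph. Cluster ids
#' are ordered by the first point index that occurs in each cluster.
#'
#' @param modes Numeric matrix of converged modes, one row per point.
#' @param merge_radius Distance below which modes are identified (> 0).
#' @return An integer label vector (1-based cluster ids) of length
#'   `nrow(modes)`.
#' @export
cluster_modes <- function(modes, merge_radius) {
  modes <- as_point_matrix(modes)
  stopifnot(merge_radius > 0)
  n <- nrow(modes)
  if (n == 1L) {
    return(1L)
  }
  adj <- as.matrix(dist(modes)) < merge_radius
  labels <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    next_id <- next_id + 1L
    frontier <- i
    labels[i] <- next_id
    while (length(frontier) > 0L) { # breadth-first flood of the component
      nb <- which(adj[frontier[1L], ] & labels == 0L)
      labels[nb] <- next_id
      frontier <- c(frontier[-1L], nb)
    }
  }
  labels
}

#' Mean-shift clustering
#'
#' Runs the three-step mode-seeking procedure from every data point
#' (compute the mean-shift vector, move the point, repeat until the
#' displacement falls below `epsilon`), then assigns points whose modes
#' coincide (within `mode_merge_radius`) to the same cluster. The number of
#' clusters is not specified in advance: it emerges from the bandwidth.
#'
#' @param data Numeric matrix or data frame of feature vectors (for genome
#'   windows, the output of [window_features()]).
#' @inheritParams shift_to_mode
#' @param kernel A [kernel_spec()] or name (`"gaussian"`, `"flat"`).
#' @param bandwidth Kernel bandwidth `h` (> 0), in feature units.
#' @param mode_merge_radius Distance below which converged modes are
#'   identified; defaults to `bandwidth / 10`.
#' @return A `mean_shift_fit` object with elements `labels` (integer cluster
#'   id per point, ordered by first occurrence), `modes` (matrix of cluster
#'   representative modes, one row per cluster), `points` (per-point mode
#'   matrix), `iterations`, `converged`, `n_clusters` and the call
#'   parameters. Use [tidy()] for a per-point tibble and [glance()] for a
#'   one-row summary.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, mean = 8), 20))
#' fit <- mean_shift(x, bandwidth = 1.5)
#' glance(fit)
#' @export
mean_shift <- function(data, bandwidth, kernel = "gaussian",
                       epsilon = 1e-3, max_iterations = 500L,
                       mode_merge_radius = bandwidth / 10) {
  x <- as_point_matrix(data)
  if (nrow(x) == 0L) {
    abort("mean_shift needs at least one data point",
      class = "islandshift_input_error"
    )
  }
  stopifnot(bandwidth > 0, mode_merge_radius > 0)
  kernel <- as_kernel_spec(kernel, ncol(x))
  runs <- purrr::map(seq_len(nrow(x)), function(i) {
    shift_to_mode(x[i, ], x, kernel, bandwidth, epsilon, max_iterations)
  })
  point_modes <- do.call(rbind, purrr::map(runs, "mode"))
  labels <- cluster_modes(point_modes, mode_merge_radius)
  cluster_reps <- do.call(rbind, purrr::map(
    split(seq_len(nrow(x)), labels)[as.character(seq_len(max(labels)))],
    function(idx) colMeans(point_modes[idx, , drop = FALSE])
  ))
  structure(
    list(
      labels = labels,
      modes = cluster_reps,
      points = point_modes,
      iterations = purrr::map_int(runs, "iterations"),
      converged = purrr::map_lgl(runs, "converged"),
      n_clusters = max(labels),
      data = x,
      kernel = kernel,
      bandwidth = bandwidth,
      epsilon = epsilon,
      max_iterations = as.integer(max_iterations),
      mode_merge_radius = mode_merge_radius
    ),
    class = "mean_shift_fit"
  )
}

#' Total mass (bp) of each cluster
#'
#' @param labels Integer cluster labels, one per window.
#' @param widths Window widths in bp (same length as `labels`).
#' @return A tibble with `cluster`, `n_windows` and `mass` (bp).
#' @export
cluster_masses <- function(labels, widths) {
  stopifnot(length(labels) == length(widths))
  tibble::tibble(cluster = labels, width = widths) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_windows = dplyr::n(), mass = sum(.data$width)) |>
    dplyr::arrange(.data$cluster)
}

as_point_matrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "double"
  data
}

scaled_sq_dist <- function(x, data, bandwidth) {
  rowSums(sweep(data, 2L, x)^2) / bandwidth^2
}

#' @export
print.mean_shift_fit <- function(x, ...) {
  cat(sprintf(
    "<mean_shift_fit> %d points, %s kernel, h = %.4g: %d cluster%s\n",
    nrow(x$data), x$kernel$name, x$bandwidth, x$n_clusters,
    if (x$n_clusters == 1L) "" else "s"
  ))
  invisible(x)
}

#' @rdname mean_shift
#' @param x,object A `mean_shift_fit`.
#' @param ... Unused.
#' @method tidy mean_shift_fit
#' @export
tidy.mean_shift_fit <- function(x, ...) {
  tibble::tibble(
    point = seq_along(x$labels),
    cluster = x$labels,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @rdname mean_shift
#' @method glance mean_shift_fit
#' @export
glance.mean_shift_fit <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$data),
    n_clusters = x$n_clusters,
    bandwidth = x$bandwidth,
    kernel = x$kernel$name,
    all_converged = all(x$converged),
    max_iterations_used = max(x$iterations)
  )
}
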