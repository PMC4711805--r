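#' Predict genomic islands in a bacterial genome
#'
#' Runs the full pipeline: read the genome, partition it into fixed-length
#' windows with (A,T,C,G) count features, compute host window statistics,
#' select compositionally deviant artificial fragments from the donor pool,
#' search for the largest bandwidth that separates every fragment into its
#' own cluster, re-cluster the host windows alone at that bandwidth, and
#' call clusters of at most `max_island_mass` bp as genomic islands.
#'
#' The final clustering excludes the artificial fragments (islands are host
#' intervals); set `keep_fragments_in_final = TRUE` to cluster host and
#' fragments together and drop fragment-only clusters afterwards.
#'
#' @param genome A `genome_sequence` or path to a FASTA file.
#' @param donors A [donor_pool()], or path to a directory of donor FASTA
#'   files.
#' @param window_length Window length `j` in bp; default 50,000.
#' @param n_fragments Number of artificial fragments; default 5.
#' @param std_coeff Deviation band coefficient `c` (>= 1); default 1.
#' @param max_island_mass Maximum island cluster mass in bp; default
#'   200,000 (must be >= `window_length`).
#' @param kernel Kernel name (`"gaussian"`, `"flat"`) or [kernel_spec()].
#' @param epsilon Mean-shift convergence threshold; default 1e-3.
#' @param max_iterations Mean-shift iteration cap; default 500.
#' @param seed Integer seed for the fragment scan order.
#' @param quantifier Deviation quantifier, `"any"` or `"all"`.
#' @param dissimilarity_threshold Minimum pairwise fragment dissimilarity;
#'   default 0.075.
#' @param decay Bandwidth decrement factor; default 0.9.
#' @param h_init,h_min Bandwidth search bounds; `NULL` for the defaults of
#'   [find_bandwidth()].
#' @param on_bandwidth_failure `"warn"` (default: report zero islands with a
#'   prominent warning) or `"abort"`.
#' @param keep_fragments_in_final Keep artificial fragments in the final
#'   clustering run; default `FALSE`.
#' @return A `gi_scan` object with elements `genome_id`, `genome_length`,
#'   `params`, `windows`, `stats`, `fragments`, `bandwidth`, `search_history`,
#'   `clusters` (per-window tibble: `index`, `start`, `end`, `cluster`),
#'   `cluster_masses`, `islands` (see [call_islands()]), `warnings` and
#'   `genome`. Methods: [print()], [tidy()] (the island tibble), [glance()]
#'   (one-row summary), [autoplot()] (G+C profile with islands highlighted).
#' @examples
#' \donttest{
#' sim <- simulate_host_genome(
#'   genome_length = 1e6, background_gc = 0.55,
#'   implants = data.frame(start = 4e5, length = 1e5, gc = 0.30), seed = 7
#' )
#' pool <- simulate_donor_pool(genome_length = 2e5, seed = 7)
#' scan <- detect_islands(sim$genome, pool, seed = 7)
#' tidy(scan)
#' }
#' @export
detect_islands <- function(genome, donors,
                           window_length = 50000L,
                           n_fragments = 5L,
                           std_coeff = 1,
                           max_island_mass = 200000L,
                           kernel = "gaussian",
                           epsilon = 1e-3,
                           max_iterations = 500L,
                           seed = 1L,
                           quantifier = "any",
                           dissimilarity_threshold = 0.075,
                           decay = 0.9,
                           h_init = NULL,
                           h_min = NULL,
                           on_bandwidth_failure = c("warn", "abort"),
                           keep_fragments_in_final = FALSE) {
  on_bandwidth_failure <- match.arg(on_bandwidth_failure)
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.character(donors)) donors <- read_donor_pool(donors)
  stopifnot(inherits(genome, "genome_sequence"), inherits(donors, "donor_pool"))
  validate_run_config(window_length, n_fragments, std_coeff, max_island_mass)

  windows <- partition_windows(genome, window_length)
  stats <- window_stats(windows)
  fragments <- select_artificial_fragments(
    donors, stats, window_length,
    std_coeff = std_coeff, n_fragments = n_fragments, seed = seed,
    quantifier = quantifier,
    dissimilarity_threshold = dissimilarity_threshold
  )

  host_x <- window_features(windows)
  frag_x <- window_features(fragments)
  warnings <- character()
  search <- tryCatch(
    find_bandwidth(
      host_x, frag_x,
      kernel = kernel, decay = decay,
      h_init = h_init, h_min = h_min,
      epsilon = epsilon, max_iterations = max_iterations
    ),
    islandshift_bandwidth_error = function(cnd) {
      if (on_bandwidth_failure == "abort") {
        abort(conditionMessage(cnd),
          class = "islandshift_bandwidth_error",
          history = cnd$history
        )
      }
      cnd
    }
  )

  if (inherits(search, "bandwidth_search")) {
    bandwidth <- search$bandwidth
    history <- search$history
    if (keep_fragments_in_final) {
      labels <- search$fit$labels[seq_len(nrow(windows))]
    } else {
      fit <- mean_shift(host_x, bandwidth, kernel, epsilon, max_iterations)
      labels <- fit$labels
    }
    islands <- call_islands(windows, labels, max_island_mass)
  } else {
    warnings <- c(
      warnings,
      "bandwidth search failed: no separating bandwidth found; reporting zero islands"
    )
    warn(warnings[length(warnings)])
    bandwidth <- NA_real_
    history <- search$history
    labels <- rep(1L, nrow(windows))
    islands <- empty_island_tibble()
  }

  structure(
    list(
      genome_id = genome$id,
      genome_length = genome$length,
      params = list(
        window_length = as.integer(window_length),
        n_fragments = as.integer(n_fragments),
        std_coeff = std_coeff,
        max_island_mass = as.integer(max_island_mass),
        kernel = if (inherits(kernel, "kernel_spec")) kernel$name else kernel,
        epsilon = epsilon,
        max_iterations = as.integer(max_iterations),
        seed = as.integer(seed),
        quantifier = quantifier,
        dissimilarity_threshold = dissimilarity_threshold,
        decay = decay,
        bandwidth = bandwidth
      ),
      windows = windows,
      stats = stats,
      fragments = fragments,
      bandwidth = bandwidth,
      search_history = history,
      clusters = tibble::tibble(
        index = windows$index,
        start = windows$start,
        end = windows$end,
        cluster = labels
      ),
      cluster_masses = cluster_masses(labels, windows$width),
      islands = islands,
      warnings = warnings,
      genome = genome
    ),
    class = "gi_scan"
  )
}

validate_run_config <- function(window_length, n_fragments, std_coeff, max_island_mass) {
  if (window_length < 1000) {
    abort("window_length must be at least 1,000 bp", class = "islandshift_input_error")
  }
  if (n_fragments < 1) {
    abort("n_fragments must be at least 1", class = "islandshift_input_error")
  }
  if (std_coeff < 1) {
    abort("std_coeff must be at least 1", class = "islandshift_input_error")
  }
  if (max_island_mass < window_length) {
    abort("max_island_mass must be at least one window length",
      class = "islandshift_input_error"
    )
  }
  invisible(TRUE)
}

#' @export
print.gi_scan <- function(x, ...) {
  writeLines(format_island_report(
    x$islands, x$genome_id,
    params = x$params[c(
      "window_length", "n_fragments", "std_coeff",
      "max_island_mass", "kernel", "seed", "bandwidth"
    )],
    warnings = x$warnings
  ))
  invisible(x)
}

#' @rdname detect_islands
#' @param x,object A `gi_scan`.
#' @param ... Unused.
#' @method tidy gi_scan
#' @export
tidy.gi_scan <- function(x, ...) {
  x$islands
}

#' @rdname detect_islands
#' @method glance gi_scan
#' @export
glance.gi_scan <- function(x, ...) {
  tibble::tibble(
    genome_id = x$genome_id,
    genome_length = x$genome_length,
    n_windows = nrow(x$windows),
    bandwidth = x$bandwidth,
    n_bandwidth_evals = nrow(x$search_history),
    n_clusters = max(x$clusters$cluster),
    n_islands = nrow(x$islands),
    island_mass = sum(x$islands$mass),
    failed = length(x$warnings) > 0L
  )
}

#' @rdname detect_islands
#' @param step G+C profile sampling interval for [autoplot()], in bp.
#' @method autoplot gi_scan
#' @export
autoplot.gi_scan <- function(object, step = 1000L, ...) {
  plot_gc_profile(gc_cumulative(object$genome, step), object$islands) +
    ggplot2::ggtitle(sprintf(
      "%s: %d genomic island%s", object$genome_id,
      nrow(object$islands), if (nrow(object$islands) == 1L) "" else "s"
    ))
}

#' Write a full set of scan outputs
#'
#' Writes `<prefix>.report.txt` (human-readable, Mb coordinates),
#' `<prefix>.islands.bed` (0-based half-open), `<prefix>.clusters.tsv`
#' (window-to-cluster assignments), `<prefix>.params.json` (machine-readable
#' parameter block including the tuned bandwidth) and, optionally,
#' `<prefix>.gc.png`.
#'
#' @param scan A `gi_scan`.
#' @param prefix Output path prefix.
#' @param plot Also write the G+C profile plot; default `FALSE`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_gi_report <- function(scan, prefix, plot = FALSE) {
  stopifnot(inherits(scan, "gi_scan"))
  paths <- c(
    report = paste0(prefix, ".report.txt"),
    bed = paste0(prefix, ".islands.bed"),
    clusters = paste0(prefix, ".clusters.tsv"),
    params = paste0(prefix, ".params.json")
  )
  writeLines(
    format_island_report(scan$islands, scan$genome_id, scan$params, scan$warnings),
    paths[["report"]]
  )
  write_island_bed(scan$islands, scan$genome_id, paths[["bed"]])
  writeLines(
    c(
      "index\tstart\tend\tcluster",
      sprintf(
        "%d\t%d\t%d\t%d",
        scan$clusters$index, scan$clusters$start,
        scan$clusters$end, scan$clusters$cluster
      )
    ),
    paths[["clusters"]]
  )
  jsonlite::write_json(scan$params, paths[["params"]], auto_unbox = TRUE, digits = NA)
  if (plot) {
    paths <- c(paths, gc = paste0(prefix, ".gc.png"))
    ggplot2::ggsave(paths[["gc"]], autoplot(scan), width = 8, height = 3, dpi = 150)
  }
  invisible(paths)
}
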