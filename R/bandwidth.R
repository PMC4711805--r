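#' Does a fragment's composition deviate from the host windows?
#'
#' A fragment qualifies as compositionally deviant when its per-nucleotide
#' window sum falls outside the band `[mean - c * sd, mean + c * sd]` built
#' from the host genome's full windows. Because the four sums are
#' constrained (they total about the window length), requiring all four to
#' deviate is near-degenerate; the default quantifier accepts a fragment as
#' soon as *any* nucleotide deviates, and `"all"` is available for the
#' strict reading.
#'
#' @param counts A named (a, t, c, g) count vector, or a matrix/tibble of
#'   them (one fragment per row).
#' @param stats Host [window_stats()].
#' @param std_coeff Positive band coefficient `c`, at least 1. Larger values
#'   demand fragments further from the host composition.
#' @param quantifier `"any"` (default) or `"all"`: how many of the four
#'   nucleotides must deviate.
#' @return A logical vector, one element per fragment.
#' @export
composition_deviates <- function(counts, stats, std_coeff = 1,
                                 quantifier = c("any", "all")) {
  quantifier <- match.arg(quantifier)
  stopifnot(inherits(stats, "window_stats"))
  if (std_coeff < 1) {
    abort("std_coeff must be at least 1", class = "islandshift_input_error")
  }
  x <- fragment_matrix(counts)
  lo <- stats$mean - std_coeff * stats$sd
  hi <- stats$mean + std_coeff * stats$sd
  out <- sweep(x, 2L, lo, `<`) | sweep(x, 2L, hi, `>`)
  if (quantifier == "any") apply(out, 1L, any) else apply(out, 1L, all)
}

# Coerce a count 4-vector, matrix or tibble with a/t/c/g columns to a
# one-row-per-fragment matrix in (a, t, c, g) order.
fragment_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    return(window_features(counts))
  }
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(ncol(counts) == 4L)
  storage.mode(counts) <- "double"
  counts
}

#' Compositional dissimilarity between two fragments
#'
#' The fraction of the window mass whose composition differs:
#' `sum(|a - b|) / (2 j)` for count 4-vectors of windows of length `j`.
#' Symmetric, zero iff the compositions are identical, 1 when the windows
#' share no base composition at all. Fragments entering the bandwidth
#' heuristic must be mutually dissimilar by more than 7.5%.
#'
#' @param a,b (a, t, c, g) count vectors of two windows of equal length.
#' @param window_length Window length `j` in bp.
#' @return A fraction in \[0, 1\].
#' @examples
#' composition_dissimilarity(
#'   c(50, 20, 15, 15), c(40, 30, 15, 15),
#'   window_length = 100
#' )
#' @export
composition_dissimilarity <- function(a, b, window_length) {
  stopifnot(length(a) == length(b), window_length > 0)
  sum(abs(as.numeric(a) - as.numeric(b))) / (2 * window_length)
}

#' Read a donor pool from a directory of FASTA files
#'
#' Loads the first record of every `.fa`/`.fna`/`.fasta` file in `dir` —
#' the pool of genomes from which artificial calibration fragments are
#' drawn. A useful pool spans a wide G+C range around the host's.
#'
#' @param dir Directory containing FASTA files.
#' @return A `donor_pool` object: list with `genomes` (list of
#'   `genome_sequence`) and `sources` (file paths).
#' @export
read_donor_pool <- function(dir) {
  if (!dir.exists(dir)) {
    abort(paste0("donor directory not found: ", dir), class = "islandshift_io_error")
  }
  files <- list.files(dir, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L) {
    abort(paste0("no FASTA files in donor directory ", dir),
      class = "islandshift_input_error"
    )
  }
  donor_pool(purrr::map(files, read_genome_fasta), sources = files)
}

#' Construct a donor pool from genome objects
#' @param genomes List of `genome_sequence` objects.
#' @param sources Optional provenance strings (defaults to genome ids).
#' @return A `donor_pool`.
#' @export
donor_pool <- function(genomes, sources = NULL) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  stopifnot(all(purrr::map_lgl(genomes, inherits, "genome_sequence")))
  structure(
    list(
      genomes = genomes,
      sources = sources %||% purrr::map_chr(genomes, "id")
    ),
    class = "donor_pool"
  )
}

#' @export
print.donor_pool <- function(x, ...) {
  cat(sprintf("<donor_pool> %d genomes\n", length(x$genomes)))
  for (g in x$genomes) {
    cat(sprintf("  %s: %s bp, GC %.1f%%\n", g$id, format(g$length, big.mark = ","), 100 * gc_fraction(g)))
  }
  invisible(x)
}

#' Select artificial fragments from a donor pool
#'
#' Enumerates every full window of every donor genome, shuffles the
#' candidates reproducibly under `seed`, and greedily accepts the first
#' windows that (a) deviate from the host composition per
#' [composition_deviates()] and (b) differ from every already-accepted
#' fragment by more than `dissimilarity_threshold` in compositional mass.
#' These fragments are inserted among the host windows during the bandwidth
#' search; they stand in for horizontally acquired material of known
#' foreignness.
#'
#' @param pool A [donor_pool()] (host genome must not be in it).
#' @param stats Host [window_stats()].
#' @param window_length Window length `j` in bp (fragments have exactly this
#'   length).
#' @param std_coeff Deviation band coefficient `c` (>= 1); default 1.
#' @param n_fragments Number of fragments to select; default 5.
#' @param seed Integer seed controlling the scan order.
#' @param quantifier Passed to [composition_deviates()].
#' @param dissimilarity_threshold Minimum pairwise [composition_dissimilarity()]
#'   between accepted fragments; default 0.075.
#' @return A tibble of `n_fragments` rows: `donor_id`, `donor_offset` (bp,
#'   0-based), `length`, `a`, `t`, `c`, `g`.
#' @export
select_artificial_fragments <- function(pool, stats, window_length,
                                        std_coeff = 1, n_fragments = 5L,
                                        seed = 1L,
                                        quantifier = "any",
                                        dissimilarity_threshold = 0.075) {
  stopifnot(inherits(pool, "donor_pool"), n_fragments >= 1L)
  candidates <- purrr::map_dfr(pool$genomes, function(donor) {
    if (donor$length < window_length) {
      return(tibble::tibble())
    }
    id <- donor$id
    w <- partition_windows(donor, window_length)
    w <- dplyr::filter(w, !.data$is_partial)
    dplyr::mutate(w, donor_id = id, .before = 1L)
  })
  if (nrow(candidates) == 0L) {
    abort("donor pool has no full windows at this window length",
      class = "islandshift_input_error"
    )
  }
  candidates <- withr::with_seed(
    seed,
    dplyr::slice_sample(candidates, n = nrow(candidates))
  )
  ok <- composition_deviates(candidates, stats, std_coeff, quantifier)
  candidates <- candidates[ok, , drop = FALSE]
  chosen <- integer(0)
  feats <- window_features(candidates)
  for (i in seq_len(nrow(candidates))) {
    dis <- purrr::map_dbl(
      chosen,
      function(ch) composition_dissimilarity(feats[i, ], feats[ch, ], window_length)
    )
    if (all(dis > dissimilarity_threshold)) {
      chosen <- c(chosen, i)
      if (length(chosen) == n_fragments) break
    }
  }
  if (length(chosen) < n_fragments) {
    abort(sprintf(
      paste0(
        "insufficient donor diversity: only %d of %d artificial fragments ",
        "satisfy the deviation and mutual-dissimilarity criteria"
      ),
      length(chosen), n_fragments
    ), class = "islandshift_insufficient_donors")
  }
  dplyr::select(
    candidates[chosen, ],
    "donor_id",
    donor_offset = "start", length = "width", "a", "t", "c", "g"
  )
}

#' Are all artificial fragments separated?
#'
#' Strict predicate: every artificial fragment must sit in a cluster that
#' contains no host window, and no two artificial fragments may share a
#' cluster. The relaxed reading (`strict = FALSE`) only requires separation
#' from the host.
#'
#' @param labels Integer cluster labels covering host windows and artificial
#'   fragments.
#' @param artificial_idx Positions in `labels` that are artificial fragments.
#' @param strict Require fragments pairwise-separated too (default `TRUE`).
#' @return `TRUE` or `FALSE`.
#' @export
is_separated <- function(labels, artificial_idx, strict = TRUE) {
  art <- labels[artificial_idx]
  host <- labels[-artificial_idx]
  if (any(art %in% host)) {
    return(FALSE)
  }
  if (strict && anyDuplicated(art) > 0L) {
    return(FALSE)
  }
  TRUE
}

#' Search for the largest separating bandwidth
#'
#' Runs mean shift on the host windows plus the artificial fragments at a
#' generous initial bandwidth, then shrinks the bandwidth geometrically
#' (`h <- h * decay`) until every artificial fragment separates into its own
#' cluster ([is_separated()]). The first — hence largest — separating
#' bandwidth is returned: at that kernel scale, windows as foreign as the
#' fragments detach from the host clusters, so genuinely transferred
#' regions should too.
#'
#' @param host_features Feature matrix of host windows ([window_features()]).
#' @param fragment_features Feature matrix of artificial fragments.
#' @param kernel A [kernel_spec()] or name.
#' @param h_init Starting bandwidth; defaults to the maximum pairwise
#'   distance among host window vectors (one cluster is all but guaranteed
#'   there).
#' @param decay Multiplicative decrement in (0, 1); default 0.9.
#' @param h_min Floor; default `h_init / 1000`. Reaching it unseparated
#'   raises an error of class `islandshift_bandwidth_error` carrying the
#'   search history.
#' @param strict Separation predicate strictness (see [is_separated()]).
#' @inheritParams mean_shift
#' @return A `bandwidth_search` object: list with `bandwidth` (the tuned
#'   `h`), `history` (tibble of `h`, `separated`, `n_clusters`), `h_init`,
#'   `decay`, `h_min` and `fit` (the `mean_shift_fit` at the returned
#'   bandwidth).
#' @export
find_bandwidth <- function(host_features, fragment_features, kernel = "gaussian",
                           h_init = NULL, decay = 0.9, h_min = NULL,
                           epsilon = 1e-3, max_iterations = 500L,
                           strict = TRUE) {
  host <- as_point_matrix(host_features)
  frag <- as_point_matrix(fragment_features)
  stopifnot(ncol(host) == ncol(frag), decay > 0, decay < 1)
  if (is.null(h_init)) h_init <- max(dist(host))
  if (is.null(h_min)) h_min <- h_init / 1000
  if (h_init <= h_min) {
    abort("h_init must exceed h_min", class = "islandshift_input_error")
  }
  all_points <- rbind(host, frag)
  art_idx <- nrow(host) + seq_len(nrow(frag))
  history <- list()
  h <- h_init
  while (h >= h_min) {
    fit <- mean_shift(all_points, h, kernel, epsilon, max_iterations)
    sep <- is_separated(fit$labels, art_idx, strict)
    history[[length(history) + 1L]] <-
      tibble::tibble(h = h, separated = sep, n_clusters = fit$n_clusters)
    if (sep) {
      return(structure(
        list(
          bandwidth = h, history = dplyr::bind_rows(history),
          h_init = h_init, decay = decay, h_min = h_min, fit = fit
        ),
        class = "bandwidth_search"
      ))
    }
    h <- h * decay
  }
  abort(
    "bandwidth search failed: no bandwidth above the floor separates all artificial fragments",
    class = "islandshift_bandwidth_error",
    history = dplyr::bind_rows(history)
  )
}

#' @export
print.bandwidth_search <- function(x, ...) {
  cat(sprintf(
    "<bandwidth_search> h = %.5g after %d evaluation%s (h_init = %.5g, decay = %.2f)\n",
    x$bandwidth, nrow(x$history), if (nrow(x$history) == 1L) "" else "s",
    x$h_init, x$decay
  ))
  invisible(x)
}
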