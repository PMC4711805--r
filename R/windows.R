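#' Partition a genome into fixed-length windows with nucleotide counts
#'
#' Tiles the genome with consecutive, non-overlapping windows of
#' `window_length` bp starting at position 0. A trailing partial window (when
#' the genome length is not a multiple of `window_length`) is retained and
#' flagged `is_partial`: islands can reach the genome end, so the trailing
#' slice must stay clusterable. Its counts are raw, not rescaled.
#'
#' Coordinates are 0-based half-open throughout the package: window `k` spans
#' `[k * window_length, min((k + 1) * window_length, genome_length))`.
#'
#' @param genome A `genome_sequence` (see [read_genome_fasta()]).
#' @param window_length Nominal window length `j` in bp; at least 1,000.
#' @return A tibble with one row per window: `index` (0-based ordinal),
#'   `start`, `end` (bp, 0-based half-open), `width` (bp), `a`, `t`, `c`, `g`
#'   (nucleotide counts), `n` (masked-base count) and `is_partial`.
#' @examples
#' g <- genome_sequence("toy", strrep("ACGT", 600))
#' partition_windows(g, window_length = 1000)
#' @export
partition_windows <- function(genome, window_length) {
  stopifnot(inherits(genome, "genome_sequence"))
  window_length <- as.integer(window_length)
  if (window_length < 1000L) {
    abort("window_length must be at least 1,000 bp",
      class = "islandshift_input_error"
    )
  }
  if (genome$length < window_length) {
    abort(sprintf(
      "genome %s (%d bp) is shorter than one window (%d bp)",
      genome$id, genome$length, window_length
    ), class = "islandshift_input_error")
  }
  starts <- seq.int(0L, genome$length - 1L, by = window_length)
  ends <- pmin(starts + window_length, genome$length)
  counts <- count_window_bases(genome$sequence, starts, ends)
  tibble::tibble(
    index = seq_along(starts) - 1L,
    start = starts,
    end = ends,
    width = ends - starts,
    a = counts[, "A"],
    t = counts[, "T"],
    c = counts[, "C"],
    g = counts[, "G"],
    n = counts[, "N"],
    is_partial = ends - starts < window_length
  )
}

# Per-window base counts via Biostrings views (0-based half-open input).
count_window_bases <- function(sequence, starts, ends) {
  v <- Biostrings::Views(Biostrings::BString(sequence), start = starts + 1L, end = ends)
  m <- Biostrings::letterFrequency(v, letters = c("A", "T", "C", "G", "N"))
  storage.mode(m) <- "integer"
  m
}

#' Count A, T, C and G in a window sequence
#'
#' `N` (and any masked base) contributes to no component.
#'
#' @param sequence A nucleotide string.
#' @return A named integer 4-vector with components `a`, `t`, `c`, `g`.
#' @examples
#' count_nucleotides("ANGT")
#' @export
count_nucleotides <- function(sequence) {
  m <- count_window_bases(normalise_sequence(sequence), 0L, nchar(sequence))
  setNames(as.integer(m[1L, c("A", "T", "C", "G")]), c("a", "t", "c", "g"))
}

#' Per-nucleotide mean and standard deviation of window sums
#'
#' Computes, for each of A, T, C and G, the mean and standard deviation of
#' the per-window count across all *full* windows of the host genome.
#' Partial trailing windows are excluded: their sums are not comparable to
#' full-window sums. The standard deviation is the population form (divide
#' by n) — recorded here as the package convention.
#'
#' @param windows A window tibble from [partition_windows()].
#' @return A `window_stats` object: list with `mean` and `sd` (named
#'   4-vectors over `a`, `t`, `c`, `g`) and `n_windows` (full windows used).
#' @export
window_stats <- function(windows) {
  full <- dplyr::filter(windows, !.data$is_partial)
  if (nrow(full) < 2L) {
    abort("window_stats needs at least 2 full windows",
      class = "islandshift_input_error"
    )
  }
  x <- window_features(full)
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  structure(
    list(mean = mu, sd = sdv, n_windows = nrow(full)),
    class = "window_stats"
  )
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf("<window_stats> over %d full windows\n", x$n_windows))
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Extract the (A, T, C, G) feature matrix from a window or fragment tibble
#'
#' @param windows A tibble with numeric columns `a`, `t`, `c`, `g`.
#' @return A numeric matrix with one row per window and columns
#'   `a`, `t`, `c`, `g` — the clustering feature vectors.
#' @export
window_features <- function(windows) {
  m <- as.matrix(windows[, c("a", "t", "c", "g")])
  storage.mode(m) <- "double"
  m
}
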