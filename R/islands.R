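#' Call genomic islands from a host-window clustering
#'
#' Clusters whose total window mass does not exceed `max_mass` (200 kb by
#' default) are candidate genomic islands: a horizontally acquired region is
#' expected to occupy few windows, while the vertically inherited backbone
#' forms one massive cluster. The mass test applies to the *whole* cluster —
#' its windows need not be consecutive, since one donor can leave several
#' insertions of the same composition. For reporting, each qualifying
#' cluster is split into maximal runs of consecutive window indices, one
#' interval per run, all sharing the source `cluster_id`.
#'
#' @param windows Host window tibble from [partition_windows()] (artificial
#'   fragments must already be removed).
#' @param labels Integer cluster labels, one per window row.
#' @param max_mass Maximum total cluster mass in bp for a cluster to be
#'   called an island (inclusive); default 200,000.
#' @return A tibble of islands sorted by `start`: `island_id` (`GI01`, ...),
#'   `start`, `end` (bp, 0-based half-open), `n_windows`, `mass` (bp of the
#'   interval), `cluster_id`, `cluster_mass` (bp of the whole source
#'   cluster) and `window_indices` (list column). Zero rows when no cluster
#'   qualifies.
#' @export
call_islands <- function(windows, labels, max_mass = 200000) {
  stopifnot(nrow(windows) == length(labels), max_mass > 0)
  masses <- cluster_masses(labels, windows$width)
  small <- masses$cluster[masses$mass <= max_mass]
  if (length(small) == 0L) {
    return(empty_island_tibble())
  }
  runs <- tibble::tibble(
    index = windows$index,
    start = windows$start,
    end = windows$end,
    width = windows$width,
    cluster_id = labels
  ) |>
    dplyr::filter(.data$cluster_id %in% small) |>
    dplyr::arrange(.data$index) |>
    dplyr::group_by(.data$cluster_id) |>
    # a run breaks wherever consecutive member indices are not adjacent
    dplyr::mutate(run = cumsum(c(1L, diff(.data$index) != 1L))) |>
    dplyr::group_by(.data$cluster_id, .data$run) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_windows = dplyr::n(),
      mass = sum(.data$width),
      window_indices = list(.data$index),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$start)
  islands <- dplyr::left_join(
    runs,
    dplyr::select(masses, cluster_id = "cluster", cluster_mass = "mass"),
    by = "cluster_id"
  )
  dplyr::transmute(
    islands,
    island_id = sprintf("GI%02d", dplyr::row_number()),
    start = .data$start,
    end = .data$end,
    n_windows = .data$n_windows,
    mass = .data$mass,
    cluster_id = .data$cluster_id,
    cluster_mass = .data$cluster_mass,
    window_indices = .data$window_indices
  )
}

empty_island_tibble <- function() {
  tibble::tibble(
    island_id = character(),
    start = integer(),
    end = integer(),
    n_windows = integer(),
    mass = integer(),
    cluster_id = integer(),
    cluster_mass = integer(),
    window_indices = list()
  )
}

#' Format island coordinates in Mb
#'
#' @param start,end bp coordinates (0-based half-open).
#' @return Strings like `"1.800-2.000"` (Mb, 3 decimals).
#' @export
format_mb_range <- function(start, end) {
  sprintf("%.3f-%.3f", start / 1e6, end / 1e6)
}

#' Write island calls as a BED file
#'
#' Standard 4-column BED: chrom, start, end, name — 0-based half-open, tab
#' separated, no header.
#'
#' @param islands Island tibble from [call_islands()].
#' @param genome_id Chromosome/record name for column 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_island_bed <- function(islands, genome_id, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s",
    genome_id, islands$start, islands$end, islands$island_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Human-readable island report
#'
#' One line per island in Mb with 3 decimals, preceded by the run
#' parameters; states explicitly when no islands were detected.
#'
#' @param islands Island tibble from [call_islands()].
#' @param genome A `genome_sequence` (or its id as a string).
#' @param params Named list of run parameters to echo.
#' @param warnings Character vector of warnings to include.
#' @return A character vector of report lines.
#' @export
format_island_report <- function(islands, genome, params = list(),
                                 warnings = character()) {
  id <- if (inherits(genome, "genome_sequence")) genome$id else as.character(genome)
  lines <- c(
    sprintf("Genomic island report for %s", id),
    sprintf("  %s: %s", names(params), purrr::map_chr(params, function(p) paste(format(p), collapse = " ")))
  )
  if (length(warnings) > 0L) {
    lines <- c(lines, paste0("WARNING: ", warnings))
  }
  if (nrow(islands) == 0L) {
    lines <- c(lines, "no genomic islands detected")
  } else {
    lines <- c(lines, sprintf(
      "%s\t%s Mb\t%d windows\t%d bp\tcluster %d",
      islands$island_id, format_mb_range(islands$start, islands$end),
      islands$n_windows, islands$mass, islands$cluster_id
    ))
  }
  lines
}
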