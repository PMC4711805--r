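#' Simulate a host genome with implanted compositionally divergent segments
#'
#' Generates an i.i.d. background of the requested G+C fraction (G and C
#' split evenly, likewise A and T) and overwrites each implant interval with
#' bases drawn at its own G+C fraction — the compositional footprint a
#' horizontally transferred region leaves, with none of its sequence-level
#' structure (no codon bias, no boundary motifs). Reproducible under `seed`.
#'
#' @param genome_length Genome length in bp.
#' @param background_gc Background G+C fraction in (0, 1).
#' @param implants A data frame with columns `start` (bp, 0-based), `length`
#'   (bp) and `gc`, or `NULL` for a homogeneous genome. Implants must lie
#'   within the genome and not overlap.
#' @param seed Integer seed.
#' @param id Genome identifier.
#' @return A list with `genome` (a `genome_sequence`) and `truth` (tibble of
#'   implant intervals: `start`, `end`, `gc`; zero rows when none).
#' @examples
#' sim <- simulate_host_genome(
#'   genome_length = 100000, background_gc = 0.55,
#'   implants = data.frame(start = 40000, length = 20000, gc = 0.30),
#'   seed = 1
#' )
#' sim$truth
#' @export
simulate_host_genome <- function(genome_length, background_gc = 0.55,
                                 implants = NULL, seed = 1L,
                                 id = "synthetic_host") {
  stopifnot(genome_length >= 1, background_gc > 0, background_gc < 1)
  if (is.null(implants) || nrow(implants) == 0L) {
    implants <- tibble::tibble(start = integer(), length = integer(), gc = numeric())
  }
  implants <- tibble::as_tibble(implants)
  implants <- dplyr::arrange(implants, .data$start)
  stopifnot(all(implants$gc > 0 & implants$gc < 1))
  if (any(implants$start < 0) ||
    any(implants$start + implants$length > genome_length)) {
    abort("implants must lie within the genome", class = "islandshift_spec_error")
  }
  if (nrow(implants) > 1L &&
    any(implants$start[-1L] < (implants$start + implants$length)[-nrow(implants)])) {
    abort("implants must not overlap", class = "islandshift_spec_error")
  }
  seq <- withr::with_seed(seed, {
    bases <- random_bases(genome_length, background_gc)
    for (i in seq_len(nrow(implants))) {
      idx <- implants$start[i] + seq_len(implants$length[i])
      bases[idx] <- random_bases(implants$length[i], implants$gc[i])
    }
    paste(bases, collapse = "")
  })
  list(
    genome = genome_sequence(id, seq),
    truth = tibble::tibble(
      start = as.integer(implants$start),
      end = as.integer(implants$start + implants$length),
      gc = implants$gc
    )
  )
}

random_bases <- function(n, gc) {
  sample(
    c("G", "C", "A", "T"), n,
    replace = TRUE,
    prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  )
}

#' Simulate a donor pool spanning a G+C gradient
#'
#' Writes one homogeneous i.i.d. FASTA genome per requested G+C fraction —
#' a stand-in for a curated collection of donor bacteria with diverse base
#' compositions. Adjacent fractions at least 0.10 apart guarantee the
#' mutual-dissimilarity rule can be met, and fractions well away from the
#' host's guarantee deviating fragments exist.
#'
#' @param gc_values G+C fractions, one donor genome each; default
#'   `c(0.25, 0.35, 0.45, 0.65, 0.75)`.
#' @param genome_length Length of each donor genome in bp; default 300,000.
#' @param seed Integer seed.
#' @param dir Directory to write FASTA files into (created if needed), or
#'   `NULL` to keep the pool in memory only.
#' @return A [donor_pool()]; when `dir` is given, `sources` holds the
#'   written file paths.
#' @export
simulate_donor_pool <- function(gc_values = c(0.25, 0.35, 0.45, 0.65, 0.75),
                                genome_length = 300000L, seed = 1L,
                                dir = NULL) {
  stopifnot(length(gc_values) >= 1L, all(gc_values > 0 & gc_values < 1))
  genomes <- withr::with_seed(seed, purrr::map(gc_values, function(gc) {
    genome_sequence(
      sprintf("donor_gc%02.0f", 100 * gc),
      paste(random_bases(genome_length, gc), collapse = "")
    )
  }))
  if (is.null(dir)) {
    return(donor_pool(genomes))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map2_chr(genomes, gc_values, function(g, gc) {
    p <- file.path(dir, paste0(g$id, ".fasta"))
    write_genome_fasta(g, p)
    p
  })
  donor_pool(genomes, sources = paths)
}

#' Write implant truth intervals as a BED file
#'
#' @param truth Truth tibble from [simulate_host_genome()].
#' @param genome_id Record name for column 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, genome_id, path) {
  writeLines(
    sprintf("%s\t%d\t%d\timplant%02d", genome_id, truth$start, truth$end, seq_len(nrow(truth))),
    path
  )
  invisible(path)
}
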