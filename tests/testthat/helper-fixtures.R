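# Shared fixture builders and oracles. Everything is generated in code; no
# stored data files.

# Write a FASTA file into a temp path and return the path.
write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fna")
  writeLines(lines, path)
  path
}

# A deterministic genome of exactly `length` bp built by repeating "ACGT".
repeat_genome <- function(length, id = "rep") {
  genome_sequence(id, substr(strrep("ACGT", ceiling(length / 4)), 1L, length))
}

# Build a window tibble directly from a count matrix (one row per window),
# bypassing sequence handling — for arithmetic-level tests.
windows_from_counts <- function(counts, width = 50000L) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  tibble::tibble(
    index = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * width,
    end = seq_len(n) * width,
    width = width,
    a = counts[, 1L], t = counts[, 2L], c = counts[, 3L], g = counts[, 4L],
    n = 0L,
    is_partial = FALSE
  )
}

# Random gaussian blob instance in d dimensions: k centers, n points.
blob_instance <- function(n, centers, sd = 1) {
  k <- nrow(centers)
  idx <- sample(k, n, replace = TRUE)
  centers[idx, , drop = FALSE] +
    matrix(stats::rnorm(n * ncol(centers), sd = sd), n)
}

# Canonical form of a label vector: relabelled by first occurrence, so two
# partitions are equal iff their canonical forms are identical.
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

# Independent reference mean-shift (gaussian kernel), implemented separately
# in numpy and used strictly as a test oracle.
reference_mean_shift <- function(x, bandwidth, epsilon = 1e-8,
                                 max_iterations = 1000L,
                                 merge_radius = bandwidth / 10) {
  script <- system.file("oracle", "mean_shift_reference.py", package = "islandshift")
  csv <- tempfile(fileext = ".csv")
  write.table(format(x, digits = 17), csv,
    sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  out <- system2(
    "python",
    c(script, csv, bandwidth, epsilon, max_iterations, merge_radius),
    stdout = TRUE
  )
  as.integer(out)
}

python_available <- function() {
  nzchar(Sys.which("python"))
}

# Study conditions for the end-to-end synthetic benchmark: a 2 Mb host at
# GC 0.55 carrying one 150 kb implant at GC 0.30, placed at 0.9 Mb on the
# default 50 kb window grid; donor pool spanning GC 0.25-0.75.
benchmark_host <- function(seed) {
  simulate_host_genome(
    genome_length = 2e6, background_gc = 0.55,
    implants = data.frame(start = 900000, length = 150000, gc = 0.30),
    seed = seed
  )
}

benchmark_scan <- function(seed, implant = TRUE) {
  sim <- if (implant) {
    benchmark_host(seed)
  } else {
    simulate_host_genome(genome_length = 2e6, background_gc = 0.55, seed = seed)
  }
  pool <- simulate_donor_pool(seed = seed)
  list(
    truth = sim$truth,
    scan = detect_islands(sim$genome, pool, seed = seed)
  )
}
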