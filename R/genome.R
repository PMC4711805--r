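#' Read a genome from a FASTA file
#'
#' Reads the first record of a FASTA file (`.fna`/`.fa`/`.fasta`), upper-cases
#' the sequence and masks every character outside `A`, `C`, `G`, `T` as `N`
#' (IUPAC ambiguity codes carry no information for mononucleotide counting).
#' Files with more than one record trigger a warning and only the first
#' record is used: the method operates on a single chromosome or plasmid.
#'
#' @param path Path to a FASTA file with at least one record. Line wrapping
#'   and lowercase bases are tolerated.
#' @return A `genome_sequence` object: a list with elements `id` (record
#'   identifier, first whitespace-delimited token of the header), `sequence`
#'   (upper-cased character scalar over the alphabet `{A,C,G,T,N}`) and
#'   `length` (bp).
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">toy", "acgtACGT"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "islandshift_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("no FASTA records in ", path), class = "islandshift_format_error")
  }
  if (length(set) > 1L) {
    warn(paste0(
      path, " contains ", length(set),
      " records; only the first (", names(set)[1L], ") is used"
    ))
  }
  seq <- normalise_sequence(as.character(set[[1L]]))
  if (nchar(seq) == 0L) {
    abort(paste0("first record of ", path, " is empty"),
      class = "islandshift_format_error"
    )
  }
  id <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  genome_sequence(id, seq)
}

#' Construct a genome sequence object
#'
#' @param id Record identifier.
#' @param sequence Nucleotide string; upper-cased and masked to `{A,C,G,T,N}`.
#' @return A `genome_sequence` object.
#' @export
genome_sequence <- function(id, sequence) {
  sequence <- normalise_sequence(sequence)
  structure(
    list(id = as.character(id), sequence = sequence, length = nchar(sequence)),
    class = "genome_sequence"
  )
}

normalise_sequence <- function(x) {
  gsub("[^ACGT]", "N", toupper(x))
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf(
    "<genome_sequence> %s: %s bp (GC %.1f%%)\n",
    x$id, format(x$length, big.mark = ","), 100 * gc_fraction(x)
  ))
  invisible(x)
}

#' G+C fraction of a genome (N bases excluded from the denominator)
#' @param genome A `genome_sequence`.
#' @return A fraction in \[0, 1\].
#' @export
gc_fraction <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  f <- Biostrings::letterFrequency(
    Biostrings::BString(genome$sequence),
    letters = c("G", "C", "A", "T")
  )
  (f[["G"]] + f[["C"]]) / sum(f)
}

#' Write genome sequences to a FASTA file
#'
#' @param genomes A `genome_sequence` or list of them.
#' @param path Output file path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  set <- Biostrings::BStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
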