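#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (ACGT, case preserved).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, revcomp_cpp, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence at a given GC content
#'
#' Draws bases i.i.d. with P(G) = P(C) = gc/2. Uses the current R RNG
#' stream, so wrap in `set.seed()` for reproducibility.
#'
#' @param n sequence length in bp.
#' @param gc GC fraction in \[0, 1\].
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  random_seq_cpp(as.integer(n), gc)
}

# Normalized representation of a sequence: for circular molecules the
# lexicographically minimal rotation of min(seq, revcomp(seq)); for linear
# ones just min(seq, revcomp(seq)).
normalize_sequence <- function(seq, circular = TRUE) {
  if (circular) min_rotation_cpp(seq) else min(seq, revcomp_cpp(seq))
}

# Extract the plain sequence vector from the various read containers used
# in the package (character vector, data.table/data.frame with `seq`).
read_seqs <- function(reads) {
  if (is.character(reads)) return(reads)
  if (is.list(reads) && !is.null(reads$seq)) return(as.character(reads$seq))
  stop("cannot interpret `reads`: expected character vector or table with a `seq` column")
}

read_ids <- function(reads) {
  if (is.character(reads)) {
    if (!is.null(names(reads))) return(names(reads))
    return(sprintf("read_%06d", seq_along(reads)))
  }
  if (is.list(reads) && !is.null(reads$id)) return(as.character(reads$id))
  sprintf("read_%06d", length(read_seqs(reads)))
}

#' Write paired reads to a FASTQ file pair
#'
#' Mates are split on the `/1` / `/2` id suffix and written to
#' `<prefix>_R1.fastq` and `<prefix>_R2.fastq` with constant quality 'I'
#' (Phred 40, Phred+33 encoding).
#'
#' @param reads a data.table with columns `id` and `seq` (ids carrying
#'   `/1`/`/2` suffixes) as produced by [simulate_reads()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths written.
#' @export
write_fastq_pair <- function(reads, prefix) {
  mate <- ifelse(endsWith(reads$id, "/2"), 2L, 1L)
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    sel <- mate == m
    x <- Biostrings::DNAStringSet(reads$seq[sel])
    names(x) <- reads$id[sel]
    q <- Biostrings::BStringSet(strrep("I", nchar(reads$seq[sel])))
    Biostrings::writeXStringSet(x, paths[m], format = "fastq", qualities = q)
  }
  invisible(paths)
}

#' Read a FASTQ file (or pair) into a read table
#'
#' @param paths one or more FASTQ file paths.
#' @return data.table with columns `id`, `seq`.
#' @export
read_fastq <- function(paths) {
  parts <- lapply(paths, function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    data.table::data.table(id = names(x), seq = as.character(x))
  })
  data.table::rbindlist(parts)
}

#' Write named sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# Deterministic per-stage seed fan-out from one master seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, classify = 2L, assemble = 3L, repeats = 4L,
               satellitome = 5L, phylo = 6L, report = 7L, sample = 8L,
               bootstrap = 9L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) * 101L + offsets[[stage]] * 7919L) %% .Machine$integer.max
}
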