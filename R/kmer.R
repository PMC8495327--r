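# Canonical k-mer machinery and compartment-wise read classification.

#' Canonical k-mers of a sequence
#'
#' Slides a window of length `k` over `seq`; windows containing non-ACGT
#' symbols are skipped; each remaining window is replaced by the
#' lexicographic minimum of itself and its reverse complement. `k` must be
#' odd so no k-mer equals its own reverse complement; k in 11..31 is the
#' usual genome-skimming regime, smaller odd values are accepted for toy
#' examples.
#'
#' @param seq a DNA string.
#' @param k odd integer window size, 3..31.
#' @return named integer vector: canonical k-mer -> occurrence count.
#'   Empty when `k > nchar(seq)`.
#' @export
canonical_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1L, is.character(seq))
  k <- as.integer(k)
  if (k < 3L || k > 31L) stop("k must be in [3, 31]")
  if (k %% 2L == 0L) stop("k must be odd (a k-mer must not equal its own reverse complement)")
  if (k > nchar(seq)) return(setNames(integer(0), character(0)))
  if (k <= 26L) {
    res <- kmer_count_cpp(seq, k, canonical = TRUE)
    return(setNames(as.integer(res$count), decode_kmers_cpp(res$kmer, k)))
  }
  # k = 27..31: exact numeric codes unavailable, fall back to string windows
  n <- nchar(seq)
  win <- substring(seq, seq_len(n - k + 1L), k:n)
  ok <- !grepl("[^ACGTacgt]", win)
  win <- toupper(win[ok])
  if (!length(win)) return(setNames(integer(0), character(0)))
  canon <- pmin(win, revcomp(win))
  tab <- table(canon)
  setNames(as.integer(tab), names(tab))
}

#' Build an error-tolerant k-mer profile from reads or sequences
#'
#' Counts canonical k-mers across all input sequences and drops k-mers seen
#' fewer than `min_count` times. `min_count = 2` (the default for read data
#' downstream) prunes most singleton sequencing-error k-mers; use
#' `min_count = 1` for assembled/reference sequences.
#'
#' @param x character vector of sequences, or a read table with a `seq`
#'   column.
#' @param k k-mer size (odd, <= 26 so codes are exact in doubles).
#' @param min_count minimum occurrence count for a k-mer to be retained.
#' @param source optional label recorded on the profile.
#' @return an object of class `kmer_profile`: list with `k`, sorted numeric
#'   `kmers`, parallel `counts`, `n_distinct`, `source`.
#' @export
build_profile <- function(x, k = 21, min_count = 1, source = NA_character_) {
  seqs <- read_seqs(x)
  k <- as.integer(k)
  if (min_count < 1) stop("min_count must be >= 1")
  if (length(seqs) == 0L) {
    res <- list(kmer = numeric(0), count = numeric(0))
  } else {
    res <- kmer_count_cpp(seqs, k, canonical = TRUE)
  }
  keep <- res$count >= min_count
  p <- list(k = k, kmers = res$kmer[keep], counts = as.integer(res$count[keep]),
            n_distinct = sum(keep), source = source)
  class(p) <- "kmer_profile"
  p
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile k=%d n_distinct=%d source=%s>\n",
              x$k, x$n_distinct, x$source))
  invisible(x)
}

#' Classify reads into genomic compartments by shared k-mer fraction
#'
#' Each read is assigned to the reference class sharing the greatest
#' fraction of the read's distinct canonical k-mers, provided that fraction
#' reaches `min_frac`. Exact ties between classes, and reads below the
#' threshold, go to `"unassigned"`: compartment purity is preferred over
#' recall. Mates of a pair are classified independently.
#'
#' @param reads character vector of read sequences or a table with `seq`
#'   (and optionally `id`).
#' @param references named list: class label -> character vector of
#'   reference sequences (e.g. `list(chloroplast = pt, mitochondrial = mt,
#'   rdna = unit, satellite = consensi, repeat_clustered = te_consensi)`).
#' @param k k-mer size.
#' @param min_frac minimum shared fraction in (0, 1].
#' @return object of class `compartment_bins`: a data.table with columns
#'   `id`, `bin`, `best_frac`; attribute `classes` holds the class labels.
#' @export
classify_reads <- function(reads, references, k = 21, min_frac = 0.5) {
  if (!length(references)) stop("references must be non-empty")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  classes <- names(references)
  if (is.null(classes) || any(classes == "")) stop("references must be a named list")
  seqs <- read_seqs(reads)
  ids <- read_ids(reads)
  ref_seqs <- unlist(references, use.names = FALSE)
  ref_class <- rep(seq_along(references) - 1L,
                   vapply(references, length, integer(1)))
  res <- classify_frac_cpp(seqs, ref_seqs, ref_class, length(classes), k)
  fr <- res$frac
  best <- apply(fr, 1L, max)
  nbest <- rowSums(fr == best & best > 0)
  which_best <- max.col(fr, ties.method = "first")
  bin <- ifelse(best >= min_frac & nbest == 1L, classes[which_best], "unassigned")
  out <- data.table::data.table(id = ids, bin = bin, best_frac = best)
  data.table::setattr(out, "classes", classes)
  data.table::setattr(out, "class", c("compartment_bins", class(out)))
  out
}

#' Split a read table into per-compartment read sets
#'
#' @param reads read table with `id` and `seq`.
#' @param bins result of [classify_reads()] for the same reads.
#' @return named list of read tables, one per bin present, plus `total`
#'   (all reads).
#' @export
split_by_bin <- function(reads, bins) {
  stopifnot(nrow(reads) == nrow(bins))
  out <- split(seq_len(nrow(reads)), bins$bin)
  res <- lapply(out, function(i) reads[i, ])
  res$total <- reads
  res
}
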