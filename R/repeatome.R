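# Graph-based repeat discovery from sampled reads: ploidy/genome-size
# scaled sampling, k-mer similarity-graph clustering, consensus building,
# tandem (satellite) detection, library classification, and the
# comparative abundance table.

#' Sample reads scaled by ploidy and genome size
#'
#' Species `i` receives `round(base_n * (genome_size_i * ploidy_i/2) /
#' (genome_size_ref * ploidy_ref/2))` reads, sampled uniformly without
#' replacement; the reference is the first-listed species (a diploid).
#' Genome sizes are monoploid (1Cx) sizes.
#'
#' @param readsets named list of read tables (columns `id`, `seq`).
#' @param base_n reads sampled for the reference species.
#' @param ploidies named integer vector (2 = diploid, 4 = tetraploid, ...).
#' @param genome_sizes named numeric vector of monoploid genome sizes (bp).
#' @param seed integer seed.
#' @return named list of sampled read tables.
#' @export
sample_reads_scaled <- function(readsets, base_n, ploidies, genome_sizes,
                                seed = 1) {
  set.seed(seed)
  labs <- names(readsets)
  stopifnot(!is.null(labs), all(labs %in% names(ploidies)),
            all(labs %in% names(genome_sizes)))
  ref <- labs[1]
  unit <- function(s) genome_sizes[[s]] * ploidies[[s]] / 2
  out <- list()
  for (s in labs) {
    n <- as.integer(round(base_n * unit(s) / unit(ref)))
    avail <- nrow(readsets[[s]])
    if (n > avail)
      stop("species ", s, ": requested ", n, " reads but only ", avail,
           " available")
    out[[s]] <- readsets[[s]][sample.int(avail, n), ]
  }
  out
}

#' Cluster reads by shared canonical k-mers
#'
#' Builds a read similarity graph (edge between reads sharing at least
#' `min_shared` distinct canonical k-mers) and takes connected components
#' with at least `min_cluster_size` members as clusters; single-copy reads
#' fall below the edge threshold and stay unclustered. Components (rather
#' than community detection) keep the procedure deterministic. If read ids
#' carry `/1`/`/2` mate suffixes, the fraction of pairs whose mates land in
#' the same cluster is recorded (mates still enter the graph
#' independently).
#'
#' @param reads read table (`id`, `seq`) or character vector; should be a
#'   desk-scale sample (<= 1e5 reads).
#' @param k clustering k-mer size (more sensitive than the AAF k).
#' @param min_shared minimum shared k-mers for an edge.
#' @param min_cluster_size minimum component size reported as a cluster.
#' @return object of class `read_clusters`: data.table with `cluster_id`,
#'   `size`, `abundance` (= size / total reads), `members` (list of read
#'   indices); attributes `n_reads`, `mate_cohesion`, `read_ids`, `seqs`.
#' @export
cluster_reads <- function(reads, k = 17, min_shared = 5,
                          min_cluster_size = 5) {
  seqs <- read_seqs(reads)
  ids <- read_ids(reads)
  lab <- cluster_reads_cpp(seqs, as.integer(k), as.integer(min_shared))
  tab <- table(lab)
  big <- as.integer(names(tab)[tab >= min_cluster_size])
  ord <- big[order(-tab[as.character(big)])]
  n <- length(seqs)
  rows <- lapply(seq_along(ord), function(i) {
    members <- which(lab == ord[i])
    data.table::data.table(cluster_id = sprintf("CL%03d", i),
                           size = length(members),
                           abundance = length(members) / n,
                           members = list(members))
  })
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(cluster_id = character(0), size = integer(0),
                           abundance = numeric(0), members = list())
  # mate co-membership statistic (pairs with both mates clustered)
  cohesion <- NA_real_
  if (any(grepl("/[12]$", ids))) {
    base <- sub("/[12]$", "", ids)
    mate_lab <- split(lab, base)
    paired <- Filter(function(x) length(x) == 2L, mate_lab)
    clustered <- Filter(function(x) all(x %in% ord), paired)
    if (length(clustered))
      cohesion <- mean(vapply(clustered, function(x) x[1] == x[2], logical(1)))
  }
  data.table::setattr(out, "n_reads", n)
  data.table::setattr(out, "mate_cohesion", cohesion)
  data.table::setattr(out, "read_ids", ids)
  data.table::setattr(out, "seqs", seqs)
  data.table::setattr(out, "class", c("read_clusters", class(out)))
  out
}

#' Majority-vote consensus of a read cluster
#'
#' Starts from the most k-mer-rich member read, anchors all members to the
#' growing consensus by exact shared k-mers (both strands), and takes the
#' per-column majority base (ties broken lexicographically), iterating
#' until the consensus stops growing. For tandem arrays the consensus is a
#' concatemer of the monomer; [detect_tandem()] normalizes it by period.
#'
#' @param seqs character vector of member read sequences.
#' @param k anchoring k-mer size.
#' @param min_anchors minimum anchor votes to place a read.
#' @param max_len consensus length cap (bp).
#' @param max_iter maximum extension iterations.
#' @return consensus DNA string.
#' @export
cluster_consensus <- function(seqs, k = 17, min_anchors = 2, max_len = 4000,
                              max_iter = 30) {
  stopifnot(length(seqs) >= 1)
  if (length(seqs) == 1L) return(seqs[[1]])
  counts <- kmer_count_cpp(seqs, as.integer(k), canonical = TRUE)
  richness <- vapply(seqs, function(s) {
    km <- kmer_count_cpp(s, as.integer(k), canonical = TRUE)
    sum(counts$count[match(km$kmer, counts$kmer)], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  consensus <- seqs[[which.max(richness)]]
  for (it in seq_len(max_iter)) {
    pl <- place_reads_cpp(consensus, seqs, as.integer(k))
    placed <- pl$votes >= min_anchors
    if (!any(placed)) break
    off <- ifelse(placed, pl$offset, NA_integer_)
    res <- majority_consensus_cpp(seqs, off, ifelse(placed, pl$strand, 0L),
                                  min_cov = 1L, max_span = as.integer(max_len))
    newc <- res$consensus
    if (nchar(newc) < k) break
    grew <- nchar(newc) - nchar(consensus)
    consensus <- newc
    if (grew < 5L) break
  }
  consensus
}

#' Detect tandem periodicity of a consensus sequence
#'
#' The candidate monomer length `m` is the smallest shift `s` at which the
#' consensus, compared against itself shifted by `s`, mismatches at a
#' fraction of at most `max_mismatch` of the >= `min_overlap` overlapping
#' positions. If some larger shift fits strictly better (e.g. alternating
#' diverged monomer variants: the smallest acceptable period is reported,
#' the better-fitting higher-order one recorded), it becomes
#' `secondary_period`. When no internal shift fits but member reads are
#' supplied, a circular junction test is run: reads anchoring across the
#' end-start junction of the doubled consensus indicate a tandem whose
#' monomer is approximately the whole consensus (the typical outcome for
#' long units, where the consensus converges to about one unit length).
#'
#' @param consensus consensus DNA string.
#' @param reads optional member read sequences for the junction test.
#' @param max_mismatch maximum mismatch fraction at the reported period.
#' @param min_period smallest period considered (guards against
#'   homopolymer/low-complexity shifts).
#' @param min_overlap minimum self-overlap (bp) for a shift to be assessed.
#' @param k anchoring k-mer size for the junction test.
#' @return list with `is_tandem`, `period` (NA when not tandem),
#'   `mismatch`, `secondary_period`, `unit` (one monomer copy when tandem).
#' @export
detect_tandem <- function(consensus, reads = NULL, max_mismatch = 0.2,
                          min_period = 10, min_overlap = 30, k = 17) {
  notandem <- list(is_tandem = FALSE, period = NA_integer_,
                   mismatch = NA_real_, secondary_period = NA_integer_,
                   unit = NA_character_)
  n <- nchar(consensus)
  if (n < min_period + min_overlap) return(notandem)
  mm <- shift_mismatch_cpp(consensus, n - as.integer(min_overlap))
  shifts <- seq_along(mm)
  ok <- shifts >= min_period & mm <= max_mismatch
  if (any(ok)) {
    m <- min(shifts[ok])
    sec <- NA_integer_
    better <- ok & shifts > m & mm < mm[m] - 1e-9
    if (any(better)) sec <- shifts[better][which.min(mm[better])]
    return(list(is_tandem = TRUE, period = as.integer(m), mismatch = mm[m],
                secondary_period = sec, unit = substr(consensus, 1L, m)))
  }
  if (!is.null(reads) && length(reads) >= 2L) {
    pl <- place_reads_cpp(paste0(consensus, consensus), reads, as.integer(k))
    rl <- nchar(reads)
    crosses <- !is.na(pl$offset) & pl$votes >= 5L &
      pl$offset <= n - as.integer(k) & (pl$offset + rl - 1L) > n + as.integer(k)
    if (sum(crosses) >= 2L)
      return(list(is_tandem = TRUE, period = as.integer(n), mismatch = 0,
                  secondary_period = NA_integer_, unit = consensus))
  }
  notandem
}

#' Classify a consensus against a labelled repeat library
#'
#' Score against each library entry = fraction of the consensus's distinct
#' canonical k-mers present in the entry. Best score >= `min_score` wins;
#' an exact tie between entries is `"ambiguous"`; otherwise
#' `"non-classified"`.
#'
#' @param consensus consensus DNA string.
#' @param library named character vector of library sequences.
#' @param k k-mer size.
#' @param min_score minimum winning score.
#' @return list with `label`, `score`.
#' @export
classify_by_library <- function(consensus, library, k = 17, min_score = 0.5) {
  if (!length(library)) stop("library must be non-empty")
  labs <- names(library)
  res <- classify_frac_cpp(consensus, unname(library),
                           seq_along(library) - 1L, length(library),
                           as.integer(k))
  fr <- res$frac[1, ]
  best <- max(fr)
  if (best < min_score) return(list(label = "non-classified", score = best))
  winners <- labs[fr == best]
  if (length(winners) > 1L) return(list(label = "ambiguous", score = best))
  list(label = winners, score = best)
}

#' Comparative repeat-family abundance table
#'
#' Cell (family, species) = 100 x summed abundance of the species'
#' clusters annotated to that family; absent families are 0. Column sums
#' are bounded by 100 x the clustered-read fraction.
#'
#' @param cluster_tables named list (per species) of data.tables with at
#'   least `abundance` and `annotation` columns.
#' @return matrix families x species of genomic abundance in percent.
#' @export
comparative_abundance_table <- function(cluster_tables) {
  species <- names(cluster_tables)
  stopifnot(!is.null(species))
  fams <- sort(unique(unlist(lapply(cluster_tables, function(x) x$annotation))))
  A <- matrix(0, length(fams), length(species),
              dimnames = list(fams, species))
  for (s in species) {
    tab <- cluster_tables[[s]]
    if (!nrow(tab)) next
    agg <- tapply(tab$abundance, tab$annotation, sum)
    A[names(agg), s] <- 100 * agg
  }
  A
}

#' Characterize clusters: consensus, tandem detection, library annotation
#'
#' Convenience wrapper running [cluster_consensus()], [detect_tandem()] and
#' (optionally) [classify_by_library()] on each cluster of a
#' [cluster_reads()] result.
#'
#' @param clusters a `read_clusters` object.
#' @param library optional named library for annotation.
#' @param k consensus/annotation k-mer size.
#' @param min_score see [classify_by_library()].
#' @return data.table with `cluster_id`, `size`, `abundance`, `consensus`,
#'   `is_tandem`, `period`, `annotation`, `score`.
#' @export
characterize_clusters <- function(clusters, library = NULL, k = 17,
                                  min_score = 0.5) {
  seqs <- attr(clusters, "seqs")
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    mem <- clusters$members[[i]]
    cons <- cluster_consensus(seqs[mem], k = k)
    td <- detect_tandem(cons, reads = seqs[mem], k = k)
    ann <- if (!is.null(library))
      classify_by_library(cons, library, k = k, min_score = min_score)
    else list(label = "non-classified", score = NA_real_)
    data.table::data.table(
      cluster_id = clusters$cluster_id[i], size = clusters$size[i],
      abundance = clusters$abundance[i], consensus = cons,
      is_tandem = td$is_tandem, period = td$period,
      annotation = ann$label, score = ann$score)
  })
  data.table::rbindlist(rows)
}
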