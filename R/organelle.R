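# De novo recovery of circular high-copy organelle genomes from reads,
# long-repeat detection, and simplified anchor-based synteny blocks.

#' Assemble a circular high-copy contig from reads
#'
#' Builds a de Bruijn graph from k-mers whose count reaches
#' `depth_threshold` (`"auto"` picks the valley of the k-mer depth
#' histogram below its dominant coverage mode, exploiting the organelle
#' copy-number excess over nuclear background and sequencing errors) and
#' walks unique successors from the deepest unused edge. A walk that
#' returns to its start is circular. The returned sequence is normalized to
#' the lexicographically minimal rotation of min(seq, revcomp), so any
#' rotation of the template assembles to the same string.
#'
#' Branching above the threshold (e.g. an internal repeat >= k) stops the
#' walk and yields partial contigs plus a diagnostic; repeats longer than
#' the insert size cannot be resolved from paired data, mirroring why some
#' real mitogenomes assemble as linear contigs.
#'
#' @param reads character vector of read sequences or a table with `seq`.
#' @param k assembly k-mer size (odd, <= 31).
#' @param depth_threshold numeric k-mer depth threshold, or `"auto"`.
#' @param min_contig_len contigs shorter than this are dropped.
#' @return object of class `circular_contig`: list with `seq` (normalized),
#'   `is_circular`, `mean_depth`, `threshold`, `n_branch`, `fragments`
#'   (all contigs, normalized, longest first).
#' @export
assemble_circular <- function(reads, k = 25, depth_threshold = "auto",
                              min_contig_len = 200) {
  seqs <- read_seqs(reads)
  if (!length(seqs)) stop("no reads supplied")
  thr <- if (identical(depth_threshold, "auto")) -1 else as.numeric(depth_threshold)
  res <- assemble_cpp(seqs, as.integer(k), thr, max_contigs = 32L,
                      min_contig_len = as.integer(min_contig_len))
  if (!length(res$contig))
    stop("insufficient depth: no k-mers above threshold ", res$threshold)
  ord <- order(nchar(res$contig), decreasing = TRUE)
  contigs <- res$contig[ord]
  circ <- res$circular[ord]
  depth <- res$depth[ord]
  norm <- vapply(seq_along(contigs), function(i)
    normalize_sequence(contigs[i], circular = circ[i]), character(1))
  out <- list(seq = norm[1], is_circular = circ[1], mean_depth = depth[1],
              threshold = res$threshold, n_branch = res$n_branch,
              fragments = data.table::data.table(
                seq = norm, is_circular = circ, mean_depth = depth))
  class(out) <- "circular_contig"
  if (res$n_branch > 0)
    message("assembly branched at ", res$n_branch,
            " node(s); emitted ", length(norm), " contig(s)")
  out
}

#' @export
print.circular_contig <- function(x, ...) {
  cat(sprintf("<circular_contig %d bp circular=%s depth=%.1f contigs=%d>\n",
              nchar(x$seq), x$is_circular, x$mean_depth, nrow(x$fragments)))
  invisible(x)
}

# Gapless X-drop extension of an anchored segment: walk outwards scoring
# +1 per match, -3 per mismatch, stop when the running score falls
# `xdrop` below its maximum, and trim back to the score maximum.
.extend_segment <- function(sa, sb, s1, s2, len, min_identity, lim1, lim2,
                            xdrop = 15L) {
  x1 <- utf8ToInt(sa); x2 <- utf8ToInt(sb)
  # the extension end only advances on a run of >= 4 consecutive matches,
  # so isolated chance matches beyond the true repeat edge are not counted
  walk <- function(p1, p2, dir, lim_a, lim_b) {
    score <- 0L; best <- 0L; best_step <- 0L; step <- 0L; run <- 0L
    while (TRUE) {
      q1 <- p1 + dir * (step + 1L); q2 <- p2 + dir * (step + 1L)
      if (q1 < 1L || q2 < 1L || q1 > lim_a || q2 > lim_b) break
      step <- step + 1L
      if (x1[q1] == x2[q2]) { score <- score + 1L; run <- run + 1L }
      else { score <- score - 3L; run <- 0L }
      if (score > best && run >= 4L) { best <- score; best_step <- step }
      if (score < best - xdrop) break
    }
    best_step
  }
  e1 <- s1 + len - 1L; e2 <- s2 + len - 1L
  r <- walk(e1, e2, +1L, lim1, lim2)
  l <- walk(s1, s2, -1L, lim1, lim2)
  s1 <- s1 - l; s2 <- s2 - l
  e1 <- e1 + r
  n <- e1 - s1 + 1L
  mm <- sum(x1[s1:e1] != x2[(s2):(s2 + n - 1L)])
  list(s1 = s1, s2 = s2, len = n, identity = 1 - mm / n)
}

#' Find long internal repeats of a sequence
#'
#' Seeds exact `anchor_len`-mer matches between distinct positions, chains
#' anchors on a common (anti-)diagonal, extends with mismatches, and
#' reports pairs with length > `min_len` and identity > `min_identity`
#' (both strict, matching the conventional ">95% similarity and >500 bp"
#' mitogenome-repeat filter). Direct and inverted repeats are reported;
#' each pair once, with `start1 < start2`, 0-based offsets.
#'
#' @param seq DNA string of length >= `min_len`.
#' @param min_len minimum repeat length (bp, exclusive bound).
#' @param min_identity minimum identity (fraction, exclusive bound).
#' @param anchor_len exact seed length.
#' @param max_join max distance between consecutive anchor starts chained
#'   into one segment.
#' @return data.table with `start1`, `start2` (0-based), `length`,
#'   `identity`, `orientation` (`"+"` direct, `"-"` inverted).
#' @export
find_long_repeats <- function(seq, min_len = 500, min_identity = 0.95,
                              anchor_len = 21, max_join = 100) {
  if (nchar(seq) < min_len) stop("sequence shorter than min_len")
  seq <- toupper(seq)
  n <- nchar(seq)
  k <- as.integer(anchor_len)
  kp <- seq_kmer_pos_cpp(seq, k)
  dt <- data.table::data.table(kmer = kp$kmer, pos = kp$pos)
  out <- list()

  # `pairs` holds anchor starts p1 (in seq) and p2 (in sb, where sb is seq
  # itself for direct repeats or revcomp(seq) for inverted ones); matches
  # run along direct diagonals of (seq, sb) in both cases.
  collect <- function(pairs, sb, inverted) {
    pairs <- data.table::as.data.table(pairs)
    if (!nrow(pairs)) return(invisible())
    pairs[, diag := p2 - p1]
    data.table::setorder(pairs, diag, p1)
    grp <- pairs[, {
      brk <- cumsum(c(1L, diff(p1) > max_join))
      list(p1 = p1, p2 = p2, seg = brk)
    }, by = "diag"]
    segs <- grp[, list(s1 = min(p1), s2 = min(p2),
                       len = max(p1) - min(p1) + k,
                       n_anchor = .N), by = c("diag", "seg")]
    for (r in seq_len(nrow(segs))) {
      ext <- .extend_segment(seq, sb, segs$s1[r], segs$s2[r], segs$len[r],
                             min_identity, n, n)
      if (ext$len > min_len && ext$identity > min_identity) {
        st1 <- ext$s1
        st2 <- if (inverted) n - (ext$s2 + ext$len - 1L) + 1L else ext$s2
        if (st1 == st2) next  # self-trivial
        out[[length(out) + 1L]] <<- data.table::data.table(
          start1 = min(st1, st2) - 1L, start2 = max(st1, st2) - 1L,
          length = ext$len, identity = ext$identity,
          orientation = if (inverted) "-" else "+")
      }
    }
  }

  # direct repeats: duplicated forward k-mers
  dup <- merge(dt, dt, by = "kmer", allow.cartesian = TRUE)
  dup <- dup[dup$pos.x < dup$pos.y, ]
  if (nrow(dup))
    collect(list(p1 = dup$pos.x, p2 = dup$pos.y), seq, inverted = FALSE)

  # inverted repeats: forward k-mers shared with the reverse strand
  rc <- revcomp_cpp(seq)
  kr <- seq_kmer_pos_cpp(rc, k)
  dtr <- data.table::data.table(kmer = kr$kmer, rpos = kr$pos)
  inv <- merge(dt, dtr, by = "kmer", allow.cartesian = TRUE)
  if (nrow(inv)) {
    # forward-strand coordinate of the rc anchor; keep each pair once
    # (also drops palindromic self-hits)
    p2f <- n - (inv$rpos + k - 1L) + 1L
    inv <- inv[inv$pos < p2f, ]
    if (nrow(inv))
      collect(list(p1 = inv$pos, p2 = inv$rpos), rc, inverted = TRUE)
  }

  if (!length(out))
    return(data.table::data.table(start1 = integer(0), start2 = integer(0),
                                  length = integer(0), identity = numeric(0),
                                  orientation = character(0)))
  res <- unique(data.table::rbindlist(out))
  # drop near-duplicate reports of the same repeat (overlapping segments)
  data.table::setorder(res, -length)
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i < nrow(res)) for (j in (i + 1L):nrow(res)) {
      if (!keep[j]) next
      if (res$orientation[i] == res$orientation[j] &&
          abs(res$start1[i] - res$start1[j]) < res$length[i] &&
          abs(res$start2[i] - res$start2[j]) < res$length[i]) keep[j] <- FALSE
    }
  }
  res[keep][order(start1, start2)]
}

#' Anchor-chained synteny blocks between two sequences
#'
#' Exact `anchor_len`-mers occurring exactly once in each sequence (on
#' either strand) are chained into maximal collinear same-orientation runs
#' with gaps <= `max_gap` on both sequences. A simplified, annotation-free
#' stand-in for gene-order synteny.
#'
#' @param seqA,seqB DNA strings.
#' @param anchor_len exact anchor length.
#' @param max_gap maximum gap (bp) between consecutive anchors in a block.
#' @param min_anchors minimum anchors per reported block.
#' @return data.table with 0-based half-open intervals `startA`, `endA`,
#'   `startB`, `endB`, `orientation` (`"+"`/`"-"`), `n_anchors`.
#' @export
synteny_blocks <- function(seqA, seqB, anchor_len = 21, max_gap = 1000,
                           min_anchors = 2) {
  stopifnot(nchar(seqA) > 0, nchar(seqB) > 0)
  k <- as.integer(anchor_len)
  canon_tab <- function(s) {
    kp <- seq_kmer_pos_cpp(toupper(s), k)
    dt <- data.table::data.table(fwd = kp$kmer, pos = kp$pos)
    rc_codes <- encode_kmers_cpp(decode_kmers_cpp(dt$fwd, k), k, canonical = TRUE)
    dt[, canon := rc_codes]
    dt[, strand := ifelse(fwd == canon, "+", "-")]
    dt[, n := .N, by = "canon"]
    dt[n == 1L]
  }
  ta <- canon_tab(seqA)
  tb <- canon_tab(seqB)
  m <- merge(ta, tb, by = "canon", suffixes = c("A", "B"))
  if (!nrow(m))
    return(data.table::data.table(startA = integer(0), endA = integer(0),
                                  startB = integer(0), endB = integer(0),
                                  orientation = character(0),
                                  n_anchors = integer(0)))
  m[, orientation := ifelse(strandA == strandB, "+", "-")]
  data.table::setorder(m, posA)
  # chain
  blocks <- list()
  cur <- m[1]
  flush <- function(rows) {
    if (nrow(rows) < min_anchors) return(invisible())
    blocks[[length(blocks) + 1L]] <<- data.table::data.table(
      startA = min(rows$posA) - 1L, endA = max(rows$posA) + k - 1L,
      startB = min(rows$posB) - 1L, endB = max(rows$posB) + k - 1L,
      orientation = rows$orientation[1], n_anchors = nrow(rows))
  }
  cur_rows <- m[1]
  for (i in seq_len(nrow(m))[-1]) {
    prev <- m[i - 1L]
    ok <- m$orientation[i] == prev$orientation &&
      (m$posA[i] - prev$posA) <= max_gap &&
      ((m$orientation[i] == "+" && m$posB[i] > prev$posB &&
          (m$posB[i] - prev$posB) <= max_gap) ||
       (m$orientation[i] == "-" && m$posB[i] < prev$posB &&
          (prev$posB - m$posB[i]) <= max_gap))
    if (ok) {
      cur_rows <- rbind(cur_rows, m[i])
    } else {
      flush(cur_rows)
      cur_rows <- m[i]
    }
  }
  flush(cur_rows)
  if (!length(blocks))
    return(data.table::data.table(startA = integer(0), endA = integer(0),
                                  startB = integer(0), endB = integer(0),
                                  orientation = character(0),
                                  n_anchors = integer(0)))
  data.table::rbindlist(blocks)
}
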