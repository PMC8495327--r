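# Alignment-and-assembly-free (AAF) distances, neighbor joining, bootstrap,
# alignment-based identity trees, tree comparison, polyploid placement
# classification, maternal-parent inference and calibration-based dating.

#' AAF distance between two k-mer profiles
#'
#' `n_s` = number of shared distinct canonical k-mers, `p = n_s /
#' min(n_A, n_B)`, `d = -(1/k) log(p)`. The `min` denominator makes the
#' estimate robust to unequal genome size or coverage. Disjoint profiles
#' get the cap `d_cap`.
#'
#' @param a,b `kmer_profile` objects with equal `k`.
#' @param d_cap distance assigned when no k-mer is shared.
#' @return nonnegative distance (substitutions/site scale).
#' @export
aaf_distance <- function(a, b, d_cap = 1.0) {
  stopifnot(inherits(a, "kmer_profile"), inherits(b, "kmer_profile"))
  if (a$k != b$k) stop("profiles have different k")
  if (a$n_distinct == 0L || b$n_distinct == 0L) stop("empty profile")
  ns <- inter_size_cpp(a$kmers, b$kmers)
  if (ns == 0) return(d_cap)
  d <- -log(ns / min(a$n_distinct, b$n_distinct)) / a$k
  min(d, d_cap)
}

#' AAF distance matrix over a list of profiles
#'
#' @param profiles named list of `kmer_profile` objects.
#' @param d_cap see [aaf_distance()].
#' @return symmetric matrix with zero diagonal, attribute `method = "aaf"`.
#' @export
aaf_distance_matrix <- function(profiles, d_cap = 1.0) {
  n <- length(profiles)
  labs <- names(profiles)
  if (is.null(labs)) stop("profiles must be named")
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- aaf_distance(profiles[[i]], profiles[[j]], d_cap)
  attr(D, "method") <- "aaf"
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ with the Q criterion; negative branch-length estimates are
#' clamped to zero; ties in Q are broken deterministically by matrix row
#' order (i.e. the order taxa are supplied).
#'
#' @param D symmetric distance matrix with row/col names (>= 3 taxa).
#' @return unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  labs <- rownames(D)
  n <- nrow(D)
  if (is.null(labs) || n < 3) stop("need a named matrix over >= 3 taxa")
  if (!isTRUE(all.equal(D, t(D)))) stop("distance matrix must be symmetric")
  frag <- labs
  Dm <- D
  fmt <- function(x) formatC(max(x, 0), digits = 12, format = "g")
  while (n > 3) {
    r <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
    li <- Dm[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (n - 2))
    lj <- Dm[bi, bj] - li
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[bi], fmt(li), frag[bj], fmt(lj))
    dn <- (Dm[bi, ] + Dm[bj, ] - Dm[bi, bj]) / 2
    keep <- setdiff(seq_len(n), c(bi, bj))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dn[keep]),
                 c(dn[keep], 0))
    frag <- c(frag[keep], newfrag)
    dimnames(Dm2) <- list(NULL, NULL)
    Dm <- Dm2
    n <- n - 1L
  }
  la <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  lb <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  lc <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(la), frag[2], fmt(lb),
                 frag[3], fmt(lc))
  ape::read.tree(text = nwk)
}

# Non-trivial bipartitions of an (unrooted) tree as canonical strings: for
# each internal edge, the leaf set on the side NOT containing the first
# leaf label (alphabetically), sorted and pasted.
tree_splits <- function(tree, include_trivial = FALSE) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  out <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    side <- below[[child]]
    if (anchor %in% side) side <- setdiff(labs, side)
    sz <- length(side)
    if (!include_trivial && (sz < 2 || sz > ntip - 2)) next
    if (include_trivial && (sz < 1 || sz > ntip - 1)) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Count of non-trivial bipartitions present in exactly one of the trees.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Bootstrap supports for an AAF neighbor-joining tree
#'
#' Each replicate resamples every profile's distinct k-mers with
#' replacement to the original distinct count (the resampling unit is the
#' k-mer, giving a deterministic contract independent of read length),
#' recomputes the distance matrix and the NJ tree; the support of a
#' bipartition is the percentage of replicates containing it.
#'
#' @param profiles named list of `kmer_profile` objects.
#' @param B number of replicates.
#' @param seed integer seed.
#' @param d_cap see [aaf_distance()].
#' @return list with `tree` (the point-estimate NJ tree, node labels =
#'   supports) and `supports` (data.table `split`, `support`).
#' @export
bootstrap_supports <- function(profiles, B = 100, seed = 1, d_cap = 1.0) {
  stopifnot(B >= 1)
  set.seed(seed)
  point <- neighbor_joining(aaf_distance_matrix(profiles, d_cap))
  target <- tree_splits(point)
  hits <- setNames(numeric(length(target)), target)
  for (b in seq_len(B)) {
    rp <- lapply(profiles, function(p) {
      km <- sort(unique(sample(p$kmers, p$n_distinct, replace = TRUE)))
      q <- list(k = p$k, kmers = km, counts = rep(1L, length(km)),
                n_distinct = length(km), source = p$source)
      class(q) <- "kmer_profile"
      q
    })
    tb <- neighbor_joining(aaf_distance_matrix(rp, d_cap))
    sb <- tree_splits(tb)
    hit <- target %in% sb
    hits[hit] <- hits[hit] + 1
  }
  supports <- data.table::data.table(split = target,
                                     support = 100 * hits / B)
  tree <- annotate_supports(point, supports)
  list(tree = tree, supports = supports)
}

# Write split supports onto node labels of a tree (rooted internally at its
# stored root; unmatched nodes get "").
annotate_supports <- function(tree, supports) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  node_lab <- rep("", tree$Nnode)
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    side <- below[[nd]]
    if (anchor %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    m <- match(key, supports$split)
    if (!is.na(m)) node_lab[nd - ntip] <- as.character(supports$support[m])
  }
  tree$node.label <- node_lab
  tree
}

#' Global pairwise identity (Needleman-Wunsch)
#'
#' Global alignment with match 1, mismatch -1, linear gap -2 (defaults);
#' identity = matched columns / alignment length (gap columns count
#' against identity).
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap scoring parameters.
#' @return percent identity in \[0, 100\].
#' @export
global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = -gap)
  100 * Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Identity-based NJ tree from a set of sequences
#'
#' Pairwise distance = 1 - identity/100 from [global_identity()], then
#' neighbor joining. The alignment-based comparator to the AAF trees.
#'
#' @param seqs named character vector of >= 3 sequences.
#' @param ... passed to [global_identity()].
#' @return unrooted `ape::phylo`; the distance matrix is attached as
#'   attribute `"D"`.
#' @export
identity_tree <- function(seqs, ...) {
  n <- length(seqs)
  if (n < 3) stop("need >= 3 sequences")
  labs <- names(seqs)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- 1 - global_identity(seqs[[i]], seqs[[j]], ...) / 100
  attr(D, "method") <- "identity"
  tr <- neighbor_joining(D)
  attr(tr, "D") <- D
  tr
}

#' Classify where a polyploid attaches relative to two diploid clades
#'
#' Finds the smallest bipartition side containing the polyploid together
#' with at least one member of either clade; if that smallest enclosing
#' group contains members of exactly one clade, the tree is labelled after
#' that clade ("plastome-like" vs "rDNA-like" style classification);
#' ambiguous or mixed attachments (e.g. at the root between both clades)
#' are `"unresolved"`.
#'
#' @param tree unrooted `ape::phylo` containing the polyploid.
#' @param polyploid leaf label of the polyploid.
#' @param cladeI,cladeII disjoint character vectors of diploid leaf labels.
#' @return `"cladeI_like"`, `"cladeII_like"` or `"unresolved"`.
#' @export
classify_polyploid_topology <- function(tree, polyploid, cladeI, cladeII) {
  if (!polyploid %in% tree$tip.label) stop("polyploid absent from tree")
  if (length(intersect(cladeI, cladeII))) stop("clades must be disjoint")
  if (polyploid %in% c(cladeI, cladeII)) stop("polyploid must not be in a clade")
  labs <- sort(tree$tip.label)
  ntip <- length(labs)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  sides <- list()
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[child]])
    side <- below[[child]]
    sides[[length(sides) + 1L]] <- side
    sides[[length(sides) + 1L]] <- setdiff(labs, side)
  }
  diploids <- c(cladeI, cladeII)
  cand <- Filter(function(s) polyploid %in% s && any(diploids %in% s), sides)
  if (!length(cand)) return("unresolved")
  sizes <- vapply(cand, length, integer(1))
  minimal <- cand[sizes == min(sizes)]
  verdicts <- vapply(minimal, function(s) {
    hasI <- any(cladeI %in% s); hasII <- any(cladeII %in% s)
    if (hasI && !hasII) "cladeI_like"
    else if (hasII && !hasI) "cladeII_like"
    else "unresolved"
  }, character(1))
  v <- unique(verdicts)
  if (length(v) == 1L) v else "unresolved"
}

#' Infer the maternal parent of a polyploid from an organelle distance matrix
#'
#' The candidate is the diploid at minimal organelle (plastome/mitogenome)
#' distance from the polyploid; all diploids within `rel_tolerance` of the
#' minimum are reported as a tie set (mirroring cases where two close
#' diploids cannot be separated).
#'
#' @param D distance matrix (e.g. from [aaf_distance_matrix()]).
#' @param polyploid polyploid label (row of `D`).
#' @param diploids candidate diploid labels.
#' @param rel_tolerance relative tolerance for the tie set.
#' @return list with `maternal` (the argmin), `ties` (labels within
#'   tolerance, including the argmin), `distances`.
#' @export
infer_maternal_parent <- function(D, polyploid, diploids, rel_tolerance = 0.1) {
  stopifnot(polyploid %in% rownames(D), all(diploids %in% rownames(D)),
            length(diploids) >= 2)
  d <- D[polyploid, diploids]
  mn <- min(d)
  ties <- names(d)[d <= mn * (1 + rel_tolerance) + 1e-12]
  list(maternal = names(d)[which.min(d)], ties = ties, distances = d)
}

#' Scale a tree to absolute ages by secondary root calibration
#'
#' The tree is midpoint-rooted, made ultrametric by averaging node-to-leaf
#' path lengths (UPGMA-style heights, with parent heights clamped to be at
#' least their children's), and node ages are set to relative heights times
#' `root_age`; leaves are age 0.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param root_age root age in Mya (default 12.4, secondary calibration).
#' @return rooted ultrametric `ape::phylo` with edge lengths in Mya and a
#'   numeric attribute `"node_ages"` (ages of internal nodes, in node
#'   order).
#' @export
scale_tree_ages <- function(tree, root_age = 12.4) {
  tr <- phangorn::midpoint(tree)
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  h <- numeric(nnode)       # height above leaves
  nl <- integer(nnode)      # number of descendant leaves
  sumd <- numeric(nnode)    # summed node-to-leaf distances
  nl[seq_len(ntip)] <- 1L
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    len <- tr$edge.length[e]
    nl[par] <- nl[par] + nl[child]
    sumd[par] <- sumd[par] + sumd[child] + nl[child] * len
  }
  for (nd in (ntip + 1L):nnode) h[nd] <- sumd[nd] / nl[nd]
  # clamp: a parent must be at least as high as each child
  tr2 <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[e, 1]; child <- tr2$edge[e, 2]
    h[par] <- max(h[par], h[child])
  }
  root <- ntip + 1L
  if (h[root] <= 0) stop("zero root height; cannot scale ages")
  ages <- h * root_age / h[root]
  tr$edge.length <- ages[tr$edge[, 1]] - ages[tr$edge[, 2]]
  attr(tr, "node_ages") <- ages[(ntip + 1L):nnode]
  tr
}
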