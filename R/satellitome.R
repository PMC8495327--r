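# Mapping-based satellite abundance across species, the 0.01% presence
# rule, family/variant grouping by circular-rotation identity, and
# parental-signature inference for allopolyploids.

#' Unique-mapping satellite abundance per species
#'
#' Each read is assigned to the single consensus sharing the greatest
#' fraction of the read's canonical k-mers, provided that fraction reaches
#' `min_frac`; equal-best ties are discarded entirely (unique mapping).
#' Abundance A\[s, f\] = 100 x assigned reads / total reads of species s
#' (the denominator is all reads of the sample, nuclear plus organelle).
#'
#' @param readsets named list (per species) of read tables or character
#'   vectors.
#' @param consensi named character vector of satellite consensus sequences.
#' @param k k-mer size.
#' @param min_frac minimum shared-k-mer fraction for assignment. The
#'   default 0.35 tolerates ~3% combined divergence (intra-array copy
#'   heterogeneity plus sequencing error) between a read and the consensus
#'   at k = 21, while unrelated reads score near 0.
#' @return object of class `sat_family_table`: list with `A` (species x
#'   family percent matrix), `consensi`, `tau` (presence threshold,
#'   percent), `counts` (per species: assigned / tie / unassigned / total),
#'   `grouping` (NULL until [group_families()] is applied).
#' @export
satellite_abundance <- function(readsets, consensi, k = 21, min_frac = 0.35) {
  stopifnot(length(consensi) > 0, !is.null(names(consensi)))
  species <- names(readsets)
  fams <- names(consensi)
  A <- matrix(0, length(species), length(fams),
              dimnames = list(species, fams))
  counts <- data.table::data.table(species = species, assigned = 0L,
                                   tie = 0L, unassigned = 0L, total = 0L)
  for (si in seq_along(species)) {
    seqs <- read_seqs(readsets[[si]])
    res <- classify_frac_cpp(seqs, unname(consensi),
                             seq_along(consensi) - 1L, length(consensi),
                             as.integer(k))
    fr <- res$frac
    best <- apply(fr, 1L, max)
    nbest <- rowSums(fr == best & best > 0)
    hit <- best >= min_frac
    uniq <- hit & nbest == 1L
    tie <- hit & nbest > 1L
    wb <- max.col(fr, ties.method = "first")
    tab <- table(factor(fams[wb[uniq]], levels = fams))
    A[si, ] <- 100 * as.numeric(tab) / length(seqs)
    n_uniq <- sum(uniq); n_tie <- sum(tie); n_tot <- length(seqs)
    data.table::set(counts, i = si,
                    j = c("assigned", "tie", "unassigned", "total"),
                    value = list(n_uniq, n_tie, n_tot - n_uniq - n_tie, n_tot))
  }
  structure(list(A = A, consensi = consensi, tau = 0.01, counts = counts,
                 grouping = NULL),
            class = "sat_family_table")
}

#' @export
print.sat_family_table <- function(x, ...) {
  cat(sprintf("<sat_family_table %d species x %d consensi, tau=%g%%>\n",
              nrow(x$A), ncol(x$A), x$tau))
  print(round(x$A, 4))
  invisible(x)
}

#' Filter satellites by minimum abundance in at least one sample
#'
#' A consensus is retained iff any species reaches `tau` percent; retained
#' rows keep all species' values, including sub-threshold ones.
#'
#' @param tab a `sat_family_table`.
#' @param tau presence threshold in percent (default 0.01).
#' @return filtered `sat_family_table`.
#' @export
filter_min_abundance <- function(tab, tau = 0.01) {
  stopifnot(inherits(tab, "sat_family_table"), tau >= 0)
  keep <- apply(tab$A, 2L, max) >= tau
  tab$A <- tab$A[, keep, drop = FALSE]
  tab$consensi <- tab$consensi[keep]
  tab$tau <- tau
  if (!is.null(tab$grouping))
    tab$grouping <- tab$grouping[tab$grouping$consensus %in% names(tab$consensi)]
  tab
}

# Best rotation/strand identity between two monomers: one monomer is
# doubled and the other aligned globally-in-pattern / locally-in-subject
# against it, so any rotation can match; identity = matched columns /
# alignment length (indel columns count against identity). Max over both
# strands.
rotation_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  one <- function(p, s) {
    al <- Biostrings::pairwiseAlignment(p, paste0(s, s), type = "global-local",
                                        substitutionMatrix = sm,
                                        gapOpening = 0, gapExtension = -gap)
    Biostrings::nmatch(al) / Biostrings::nchar(al)
  }
  max(one(a, b), one(a, revcomp_cpp(b)))
}

#' Group satellite consensi into families and variants
#'
#' Pairwise identity is computed by global alignment over the best of all
#' monomer rotations and both strands; single-linkage clustering at
#' `family_threshold` defines families; within a family, single-linkage
#' components at `variant_threshold` define variants. Two monomers at 70%
#' rotation identity therefore fall in one family but remain distinct
#' variants under the defaults.
#'
#' @param consensi named character vector of monomer consensus sequences.
#' @param family_threshold identity for same-family membership (fraction).
#' @param variant_threshold identity for same-variant membership.
#' @return data.table with `consensus`, `family`, `variant`; pairwise
#'   identity matrix attached as attribute `"identity"`.
#' @export
group_families <- function(consensi, family_threshold = 0.60,
                           variant_threshold = 0.95) {
  stopifnot(family_threshold > 0, family_threshold <= 1,
            variant_threshold >= family_threshold, variant_threshold <= 1)
  n <- length(consensi)
  labs <- names(consensi)
  id <- matrix(1, n, n, dimnames = list(labs, labs))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      id[i, j] <- id[j, i] <- rotation_identity(consensi[[i]], consensi[[j]])
  link <- function(idx, thr) {
    # single-linkage components over the subset idx
    comp <- seq_along(idx)
    repeat {
      changed <- FALSE
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        if (i < j && id[idx[i], idx[j]] >= thr && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    match(comp, unique(comp))
  }
  fam <- link(seq_len(n), family_threshold)
  rows <- list()
  for (f in sort(unique(fam))) {
    idx <- which(fam == f)
    vr <- link(idx, variant_threshold)
    for (i in seq_along(idx))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        consensus = labs[idx[i]],
        family = sprintf("FAM%02d", f),
        variant = sprintf("FAM%02d.v%d", f, vr[i]))
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "identity", id)
  out
}

#' Presence/absence matrix of satellites
#'
#' @param tab a `sat_family_table` (normally filtered).
#' @param tau presence threshold in percent; a cell is present iff
#'   A\[s, f\] >= tau. With `tau = 0`, any mapped read counts as presence.
#' @return logical species x family matrix.
#' @export
presence_absence <- function(tab, tau = tab$tau) {
  stopifnot(inherits(tab, "sat_family_table"))
  if (tau == 0) tab$A > 0 else tab$A >= tau
}

#' Infer contributing parental clades from satellite presence/absence
#'
#' A satellite is diagnostic for a clade when it is present in at least one
#' clade member and absent in every other diploid. A clade is flagged as a
#' contributor to the polyploid iff at least one of its diagnostic
#' satellites is present in the polyploid.
#'
#' @param pa logical species x satellite matrix from [presence_absence()].
#' @param polyploid polyploid row label.
#' @param clades named list of >= 2 character vectors of diploid labels.
#' @param diploids all diploid labels (defaults to the union of the
#'   clades).
#' @return list with `contributors` (clade names), `diagnostics` (per
#'   clade, its diagnostic satellites), `support` (per clade, diagnostic
#'   satellites present in the polyploid), `inconclusive`.
#' @export
infer_parental_signatures <- function(pa, polyploid, clades,
                                      diploids = unique(unlist(clades))) {
  stopifnot(polyploid %in% rownames(pa), length(clades) >= 2,
            all(unlist(clades) %in% rownames(pa)))
  diagnostics <- list(); support <- list()
  for (cl in names(clades)) {
    members <- clades[[cl]]
    others <- setdiff(diploids, members)
    diag_f <- colnames(pa)[
      apply(pa[members, , drop = FALSE], 2L, any) &
      !apply(pa[others, , drop = FALSE], 2L, any)]
    diagnostics[[cl]] <- diag_f
    support[[cl]] <- diag_f[pa[polyploid, diag_f]]
  }
  contributors <- names(clades)[vapply(support, length, integer(1)) > 0]
  inconclusive <- all(vapply(diagnostics, length, integer(1)) == 0)
  list(contributors = contributors, diagnostics = diagnostics,
       support = support, inconclusive = inconclusive)
}
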