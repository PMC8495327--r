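# Synthetic diploid / allopolyploid genome and read-set generator.
#
# The generator emulates the statistical structure of plant genome-skimming
# data: a handful of diploids diverged on a known tree under Jukes-Cantor
# substitutions, allopolyploids formed by union of two diploid nuclear
# genomes with organelles inherited maternally, species-specific and shared
# tandem satellite families, high-copy organelle compartments, and 2x150 bp
# paired reads with ~350 bp inserts and i.i.d. substitution errors.

#' Species tree specification
#'
#' @param newick rooted Newick string over diploid taxon labels, branch
#'   lengths in substitutions/site.
#' @param root_age_mya calibration age of the root in Mya (default 12.4,
#'   a secondary-calibration age for the group the generator emulates).
#' @return object of class `species_tree_spec` with elements `tree`
#'   (an `ape::phylo`) and `root_age_mya`.
#' @export
species_tree_spec <- function(newick, root_age_mya = 12.4) {
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse Newick string")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length rejected")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  structure(list(tree = tree, root_age_mya = root_age_mya),
            class = "species_tree_spec")
}

#' Satellite family specification
#'
#' A tandem satellite family with a monomer, a target genomic abundance,
#' and optional gain/loss edges on the species tree. A family is present in
#' exactly the leaves below its gain edge minus the leaves below its loss
#' edges; realized abundance drifts multiplicatively (lognormal, sd
#' `drift_sigma` per branch) along the path from its origin.
#'
#' @param family_id character id.
#' @param monomer monomer sequence (50-2000 bp), or an integer length to be
#'   drawn randomly when the blueprint is realized.
#' @param target_abundance target fraction of the nuclear genome (<= 0.05).
#' @param gain character vector of leaf labels spanning the clade on whose
#'   stem edge the family appears; `NULL` = present from the root.
#' @param losses list of such leaf-label vectors for loss edges; each loss
#'   clade must be nested inside the gain clade.
#' @param drift_sigma lognormal sd of the per-branch abundance multiplier.
#' @return object of class `sat_family_spec`.
#' @export
sat_family_spec <- function(family_id, monomer = 165L, target_abundance = 0.01,
                            gain = NULL, losses = list(), drift_sigma = 0) {
  m <- if (is.character(monomer)) nchar(monomer) else as.integer(monomer)
  if (m < 50 || m > 2000) stop("monomer length must be in [50, 2000]")
  if (target_abundance < 0 || target_abundance > 0.05)
    stop("target_abundance must be in [0, 0.05]")
  structure(list(family_id = family_id, monomer = monomer,
                 target_abundance = target_abundance, gain = gain,
                 losses = losses, drift_sigma = drift_sigma),
            class = "sat_family_spec")
}

#' Genome blueprint
#'
#' Desk-scale stand-in for real plant genomes: the defaults (200 kb nuclear,
#' 20 kb plastome, 35 kb mitogenome, organelle copy boost 50) keep the
#' high-plastome-depth regime that makes seed-and-extend organelle assembly
#' work, at a size that simulates in seconds.
#'
#' @param L_nuc nuclear genome length (bp, per monoploid genome).
#' @param L_pt plastome length (bp, circular).
#' @param L_mt mitogenome length (bp, circular).
#' @param organelle_copy_boost relative organelle read-depth multiplier
#'   (>= 10).
#' @param rdna_unit_len length of the tandem rDNA unit (bp).
#' @param rdna_copies tandem copy number of the rDNA unit.
#' @param sat_families list of [sat_family_spec()] objects.
#' @param te_families list of `c(length, copies)` dispersed-repeat families.
#' @param gc_content genomic GC fraction.
#' @param intra_array_div per-site divergence between satellite monomer
#'   copies within one array (copy heterogeneity; no concerted-evolution
#'   homogenization is modelled).
#' @param rdna_intra_div per-site divergence between rDNA unit copies.
#' @return object of class `genome_blueprint`.
#' @export
genome_blueprint <- function(L_nuc = 200000, L_pt = 20000, L_mt = 35000,
                             organelle_copy_boost = 50, rdna_unit_len = 1500,
                             rdna_copies = 4, sat_families = list(),
                             te_families = list(), gc_content = 0.36,
                             intra_array_div = 0.02, rdna_intra_div = 0.005) {
  stopifnot(L_nuc > 0, L_pt > 0, L_mt > 0, organelle_copy_boost >= 10,
            rdna_unit_len > 0, rdna_copies >= 1)
  sat_len <- sum(vapply(sat_families, function(s) {
    m <- if (is.character(s$monomer)) nchar(s$monomer) else s$monomer
    round(s$target_abundance * L_nuc / m) * m
  }, numeric(1)))
  te_len <- sum(vapply(te_families, function(t) t[1] * t[2], numeric(1)))
  if (sat_len + rdna_unit_len * rdna_copies + te_len > L_nuc)
    stop("sum of repeat array lengths exceeds L_nuc")
  structure(list(L_nuc = as.integer(L_nuc), L_pt = as.integer(L_pt),
                 L_mt = as.integer(L_mt),
                 organelle_copy_boost = organelle_copy_boost,
                 rdna_unit_len = as.integer(rdna_unit_len),
                 rdna_copies = as.integer(rdna_copies),
                 sat_families = sat_families, te_families = te_families,
                 gc_content = gc_content, intra_array_div = intra_array_div,
                 rdna_intra_div = rdna_intra_div),
            class = "genome_blueprint")
}

# ---- tree helpers ----

# Node number of the edge on which a clade (given by its leaf labels)
# hangs; a single label means the terminal edge to that tip.
clade_node <- function(tree, taxa) {
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

# ---- satellitome evolution ----

# Core gain/loss + drift bookkeeping. Uses the current RNG stream.
sat_state_over_tree <- function(tree, sat_specs) {
  fams <- vapply(sat_specs, `[[`, character(1), "family_id")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  gain_node <- vapply(sat_specs, function(s)
    if (is.null(s$gain)) root else clade_node(tree, s$gain), integer(1))
  loss_nodes <- lapply(sat_specs, function(s)
    vapply(s$losses, clade_node, integer(1), tree = tree))
  # validate nesting: each loss clade strictly inside the gain clade
  for (i in seq_along(sat_specs)) {
    gtips <- tips_below(tree, gain_node[i])
    for (ln in loss_nodes[[i]]) {
      ltips <- tips_below(tree, ln)
      if (!all(ltips %in% gtips) || length(ltips) >= length(gtips))
        stop("loss edge of family ", fams[i],
             " is not a proper descendant of its gain edge")
    }
  }
  tr <- ape::reorder.phylo(tree, "cladewise")
  nnode <- ntip + tr$Nnode
  present <- matrix(FALSE, nnode, length(fams), dimnames = list(NULL, fams))
  abund <- matrix(0, nnode, length(fams), dimnames = list(NULL, fams))
  present[root, ] <- gain_node == root
  abund[root, ] <- vapply(sat_specs, `[[`, numeric(1), "target_abundance")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    pres <- present[par, ]
    ab <- abund[par, ]
    for (i in seq_along(fams)) {
      if (gain_node[i] == child) pres[i] <- TRUE
      if (child %in% loss_nodes[[i]]) pres[i] <- FALSE
      sg <- sat_specs[[i]]$drift_sigma
      if (sg > 0) ab[i] <- ab[i] * exp(rnorm(1, 0, sg))
    }
    present[child, ] <- pres
    abund[child, ] <- ab
  }
  list(present = present[seq_len(ntip), , drop = FALSE],
       abund = abund[seq_len(ntip), , drop = FALSE],
       tips = tree$tip.label)
}

#' Evolve satellite family presence and abundance over a species tree
#'
#' Families appear on their gain edge, disappear below loss edges, and
#' their abundance drifts multiplicatively (lognormal with per-branch sd
#' `drift_sigma`) along the root-to-leaf path.
#'
#' @param tree_spec a [species_tree_spec()].
#' @param sat_specs list of [sat_family_spec()] objects.
#' @param seed integer seed.
#' @return data.table with columns `species`, `family`, `present`,
#'   `abundance` (realized target fraction; 0 when absent).
#' @export
evolve_satellitome <- function(tree_spec, sat_specs, seed = 1) {
  set.seed(seed)
  st <- sat_state_over_tree(tree_spec$tree, sat_specs)
  dt <- data.table::CJ(species = st$tips,
                       family = colnames(st$present), sorted = FALSE)
  dt[, `:=`(
    present = mapply(function(s, f) st$present[match(s, st$tips), f],
                     species, family),
    abundance = mapply(function(s, f) {
      p <- st$present[match(s, st$tips), f]
      if (p) st$abund[match(s, st$tips), f] else 0
    }, species, family))]
  dt[]
}

# ---- genome evolution ----

jc_subst_prob <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Evolve genomes for every leaf of a species tree
#'
#' Draws a root genome from the blueprint (random background at the given
#' GC, dispersed TE copies, tandem satellite and rDNA arrays at fixed loci,
#' circular plastome and mitogenome), then evolves every compartment along
#' each branch under Jukes-Cantor: a site of a branch of length `d`
#' substitutes with probability `p = (3/4)(1 - exp(-4d/3))`. Satellite
#' arrays are rebuilt at each leaf from the leaf's evolved monomer at the
#' leaf's realized abundance, with `intra_array_div` per-copy heterogeneity.
#'
#' @param tree_spec a [species_tree_spec()].
#' @param blueprint a [genome_blueprint()].
#' @param seed integer seed.
#' @return named list of `sim_genome` objects (one per leaf), each with
#'   `label`, `ploidy`, `nuclear` (named list of subgenome strings), `anno`
#'   (per-subgenome data.table `start`, `end`, `compartment`, `family`),
#'   `plastome`, `mitogenome`, `sat_abundance`, `monomers`, `rdna_unit`,
#'   `organelle_copy_boost`, `parents`.
#' @export
evolve_sequences <- function(tree_spec, blueprint, seed = 1) {
  stopifnot(inherits(tree_spec, "species_tree_spec"),
            inherits(blueprint, "genome_blueprint"))
  set.seed(seed)
  bp <- blueprint
  tree <- ape::reorder.phylo(tree_spec$tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  # materialize monomers / units
  sat_specs <- bp$sat_families
  monomers <- lapply(sat_specs, function(s)
    if (is.character(s$monomer)) toupper(s$monomer)
    else random_dna(s$monomer, bp$gc_content))
  fam_ids <- vapply(sat_specs, `[[`, character(1), "family_id")
  names(monomers) <- fam_ids
  rdna_unit <- random_dna(bp$rdna_unit_len, bp$gc_content)

  # background with embedded TEs, leaving room for arrays
  arr_len <- sum(vapply(seq_along(sat_specs), function(i)
    round(sat_specs[[i]]$target_abundance * bp$L_nuc / nchar(monomers[[i]])) *
      nchar(monomers[[i]]), numeric(1)))
  rdna_len <- bp$rdna_unit_len * bp$rdna_copies
  L_bg <- bp$L_nuc - arr_len - rdna_len
  if (L_bg < 1000) stop("blueprint leaves too little single-copy background")
  bg <- random_dna(L_bg, bp$gc_content)

  # array insertion points: equal background chunks (fixed loci)
  n_arr <- length(sat_specs) + 1L  # satellites + rDNA
  breaks <- round(seq(0, L_bg, length.out = n_arr + 2L))

  # dispersed TEs inside chunks (never across an insertion point)
  te_anno <- data.table::data.table(start = integer(0), end = integer(0),
                                    family = character(0))
  for (ti in seq_along(bp$te_families)) {
    tl <- bp$te_families[[ti]][1]; tc <- bp$te_families[[ti]][2]
    te_seq <- random_dna(tl, bp$gc_content)
    placed <- 0L; tries <- 0L
    while (placed < tc && tries < 200L * tc) {
      tries <- tries + 1L
      st <- sample.int(L_bg - tl, 1L)
      chunk <- findInterval(st, breaks + 1L)
      if (findInterval(st + tl - 1L, breaks + 1L) != chunk) next
      if (nrow(te_anno) && any(pmax(te_anno$start, st) <=
                               pmin(te_anno$end, st + tl - 1L))) next
      substr(bg, st, st + tl - 1L) <- te_seq
      te_anno <- rbind(te_anno, data.table::data.table(
        start = st, end = st + tl - 1L,
        family = sprintf("TE%d", ti)))
      placed <- placed + 1L
    }
  }
  data.table::setorder(te_anno, start)

  pt <- random_dna(bp$L_pt, bp$gc_content)
  mt <- random_dna(bp$L_mt, bp$gc_content)

  # satellite presence/abundance over the tree (same RNG stream)
  sat_st <- if (length(sat_specs)) sat_state_over_tree(tree, sat_specs) else NULL

  # evolve states down the tree
  nnode <- ntip + tree$Nnode
  states <- vector("list", nnode)
  states[[root]] <- list(bg = bg, monomers = monomers, rdna = rdna_unit,
                         pt = pt, mt = mt)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    d <- tree$edge.length[e]
    p <- jc_subst_prob(d)
    s <- states[[par]]
    states[[child]] <- list(
      bg = jc_mutate_cpp(s$bg, p),
      monomers = lapply(s$monomers, jc_mutate_cpp, p = p),
      rdna = jc_mutate_cpp(s$rdna, p),
      pt = jc_mutate_cpp(s$pt, p),
      mt = jc_mutate_cpp(s$mt, p))
  }

  genomes <- vector("list", ntip)
  names(genomes) <- tree$tip.label
  for (tip in seq_len(ntip)) {
    lab <- tree$tip.label[tip]
    s <- states[[tip]]
    pieces <- character(0)
    anno <- list()
    off <- 0L
    add_piece <- function(seqs, comp, fam) {
      len <- sum(nchar(seqs))
      if (len == 0L) return(invisible())
      pieces[[length(pieces) + 1L]] <<- paste(seqs, collapse = "")
      anno[[length(anno) + 1L]] <<- data.table::data.table(
        start = off + 1L, end = off + len, compartment = comp, family = fam)
      off <<- off + len
    }
    add_chunk <- function(i) {
      from <- breaks[i] + 1L; to <- breaks[i + 1L]
      if (to < from) return(invisible())
      chunk_start <- off + 1L
      # TE intervals inside this chunk
      tes <- te_anno[te_anno$start >= from & te_anno$end <= to, ]
      cur <- from
      for (r in seq_len(nrow(tes))) {
        if (tes$start[r] > cur)
          add_piece(substr(s$bg, cur, tes$start[r] - 1L), "single_copy", NA_character_)
        add_piece(substr(s$bg, tes$start[r], tes$end[r]), "repeat_clustered",
                  tes$family[r])
        cur <- tes$end[r] + 1L
      }
      if (cur <= to) add_piece(substr(s$bg, cur, to), "single_copy", NA_character_)
      invisible(chunk_start)
    }
    for (i in seq_len(n_arr)) {
      add_chunk(i)
      if (i <= length(sat_specs)) {
        fam <- fam_ids[i]
        pres <- sat_st$present[tip, fam]
        ab <- sat_st$abund[tip, fam]
        ncop <- if (pres) round(ab * bp$L_nuc / nchar(s$monomers[[fam]])) else 0L
        if (ncop >= 1L) {
          copies <- vapply(seq_len(ncop), function(z)
            jc_mutate_cpp(s$monomers[[fam]], bp$intra_array_div), character(1))
          add_piece(copies, "satellite", fam)
        }
      } else {
        copies <- vapply(seq_len(bp$rdna_copies), function(z)
          jc_mutate_cpp(s$rdna, bp$rdna_intra_div), character(1))
        add_piece(copies, "rdna", "rDNA")
      }
    }
    add_chunk(n_arr + 1L)
    nuc <- paste(pieces, collapse = "")
    ann <- data.table::rbindlist(anno)
    g <- list(label = lab, ploidy = 2L,
              nuclear = setNames(list(nuc), lab),
              anno = setNames(list(ann), lab),
              plastome = s$pt, mitogenome = s$mt,
              monomers = s$monomers, rdna_unit = s$rdna,
              organelle_copy_boost = bp$organelle_copy_boost,
              parents = NULL)
    g$sat_abundance <- realized_sat_abundance(g)
    class(g) <- "sim_genome"
    genomes[[tip]] <- g
  }
  genomes
}

# Realized satellite abundance from annotation intervals: summed satellite
# array length per family over total nuclear length.
realized_sat_abundance <- function(genome) {
  tot <- sum(vapply(genome$nuclear, nchar, numeric(1)))
  ann <- data.table::rbindlist(genome$anno)
  sat <- ann[ann$compartment == "satellite", ]
  if (!nrow(sat)) return(setNames(numeric(0), character(0)))
  agg <- sat[, list(len = sum(end - start + 1)), by = "family"]
  setNames(agg$len / tot, agg$family)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome %s ploidy=%d nuclear=%s bp pt=%d mt=%d>\n",
              x$label, x$ploidy,
              paste(vapply(x$nuclear, nchar, numeric(1)), collapse = "+"),
              nchar(x$plastome), nchar(x$mitogenome)))
  invisible(x)
}

#' Form an allopolyploid from two diploid genomes
#'
#' The polyploid nucleus is the union of both parental nuclear genomes (two
#' annotated subgenomes); plastome and mitogenome are copied from the
#' maternal parent only (strict maternal organelle inheritance); the
#' satellite family set is the union of the parents'. Reflecting the
#' commonly observed attrition of paternal-subgenome repeats in
#' allopolyploids, each paternal satellite array is truncated to
#' `paternal_sat_retention` of its length (set to 1 to disable; families
#' are never lost entirely, so presence/absence is the strict union).
#'
#' @param maternal,paternal diploid `sim_genome` objects.
#' @param label label for the polyploid.
#' @param paternal_sat_retention retained fraction (0, 1] of each paternal
#'   satellite array.
#' @return a `sim_genome` of ploidy 4 with `parents` recorded.
#' @export
make_allopolyploid <- function(maternal, paternal, label,
                               paternal_sat_retention = 0.25) {
  stopifnot(inherits(maternal, "sim_genome"), inherits(paternal, "sim_genome"))
  if (maternal$ploidy != 2L || paternal$ploidy != 2L)
    stop("both parents must be diploid")
  auto <- identical(maternal$label, paternal$label)
  if (auto) warning("same genome passed twice: autopolyploid")
  if (paternal_sat_retention <= 0 || paternal_sat_retention > 1)
    stop("paternal_sat_retention must be in (0, 1]")

  pat_nuc <- paternal$nuclear
  pat_anno <- paternal$anno
  if (paternal_sat_retention < 1) {
    for (sg in names(pat_nuc)) {
      tr <- truncate_satellites(pat_nuc[[sg]], pat_anno[[sg]],
                                paternal_sat_retention)
      pat_nuc[[sg]] <- tr$seq
      pat_anno[[sg]] <- tr$anno
    }
  }
  sub_names <- make.unique(c(names(maternal$nuclear), names(pat_nuc)))
  g <- list(label = label, ploidy = 4L,
            nuclear = setNames(c(maternal$nuclear, pat_nuc), sub_names),
            anno = setNames(c(maternal$anno, pat_anno), sub_names),
            plastome = maternal$plastome, mitogenome = maternal$mitogenome,
            monomers = utils::modifyList(paternal$monomers, maternal$monomers),
            rdna_unit = maternal$rdna_unit,
            organelle_copy_boost = maternal$organelle_copy_boost,
            parents = c(maternal = maternal$label, paternal = paternal$label),
            autopolyploid = auto)
  g$sat_abundance <- realized_sat_abundance(g)
  class(g) <- "sim_genome"
  g
}

# Trim every satellite interval to the first `retention` fraction of its
# length and rebuild sequence + annotation.
truncate_satellites <- function(seq, anno, retention) {
  keep <- character(0)
  rows <- list()
  off <- 0L
  for (r in seq_len(nrow(anno))) {
    s <- anno$start[r]; e <- anno$end[r]
    if (anno$compartment[r] == "satellite") {
      newlen <- max(0L, as.integer(round((e - s + 1L) * retention)))
      if (newlen == 0L) next
      e <- s + newlen - 1L
    }
    keep[[length(keep) + 1L]] <- substr(seq, s, e)
    len <- e - s + 1L
    rows[[length(rows) + 1L]] <- data.table::data.table(
      start = off + 1L, end = off + len,
      compartment = anno$compartment[r], family = anno$family[r])
    off <- off + len
  }
  list(seq = paste(keep, collapse = ""), anno = data.table::rbindlist(rows))
}

#' Simulate paired-end reads from a genome with full truth labels
#'
#' Fragment starts are uniform over each compartment template (circular
#' organelles wrap); per-compartment read-pair counts are
#' `round(coverage * multiplier * L / (2 * read_len))` with organelles
#' multiplied by the blueprint's copy boost; insert lengths are
#' Normal(insert_mean, insert_sd) truncated below at `read_len`; errors are
#' i.i.d. substitutions; qualities are constant. Both mates of a pair carry
#' the compartment/family of the fragment midpoint as truth.
#'
#' @param genome a `sim_genome`.
#' @param coverage nuclear fold-coverage (> 0).
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd insert length distribution (bp).
#' @param error_rate per-base substitution probability.
#' @param seed optional integer seed (`NULL` = current RNG stream).
#' @return list with `reads` (data.table `id`, `seq`) and `truth`
#'   (data.table `read_id`, `species`, `compartment`, `family`).
#' @export
simulate_reads <- function(genome, coverage, read_len = 150L,
                           insert_mean = 350, insert_sd = 30,
                           error_rate = 0.01, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"), coverage > 0)
  if (read_len > insert_mean) stop("read_len must be <= insert_mean")
  if (!is.null(seed)) set.seed(seed)
  boost <- genome$organelle_copy_boost
  templates <- c(
    lapply(names(genome$nuclear), function(sg)
      list(name = sg, seq = genome$nuclear[[sg]], circular = FALSE, mult = 1,
           anno = genome$anno[[sg]])),
    list(list(name = "pt", seq = genome$plastome, circular = TRUE,
              mult = boost, anno = NULL, comp = "chloroplast"),
         list(name = "mt", seq = genome$mitogenome, circular = TRUE,
              mult = boost, anno = NULL, comp = "mitochondrial")))
  reads <- list(); truth <- list()
  for (tm in templates) {
    L <- nchar(tm$seq)
    if (read_len > L) {
      warning("compartment ", tm$name, " shorter than read length; skipped")
      next
    }
    n_pairs <- as.integer(round(coverage * tm$mult * L / (2 * read_len)))
    if (n_pairs < 1L) next
    sim <- sim_reads_cpp(tm$seq, tm$circular, n_pairs, as.integer(read_len),
                         insert_mean, insert_sd, error_rate)
    base_id <- sprintf("%s.%s.%06d", genome$label, tm$name, seq_len(n_pairs))
    mid <- sim$start + sim$insert %/% 2L
    if (tm$circular) mid <- (mid - 1L) %% L + 1L else mid <- pmin(mid, L)
    if (is.null(tm$anno)) {
      comp <- rep(tm$comp, n_pairs)
      fam <- rep(NA_character_, n_pairs)
    } else {
      idx <- findInterval(mid, tm$anno$start)
      comp <- tm$anno$compartment[idx]
      fam <- tm$anno$family[idx]
    }
    reads[[length(reads) + 1L]] <- data.table::data.table(
      id = c(paste0(base_id, "/1"), paste0(base_id, "/2")),
      seq = c(as.character(sim$r1), as.character(sim$r2)))
    truth[[length(truth) + 1L]] <- data.table::data.table(
      read_id = c(paste0(base_id, "/1"), paste0(base_id, "/2")),
      species = genome$label, compartment = c(comp, comp), family = c(fam, fam))
  }
  list(reads = data.table::rbindlist(reads),
       truth = data.table::rbindlist(truth))
}

#' Simulate a complete multi-species genome-skimming study
#'
#' Convenience wrapper: evolves diploid genomes on the tree, forms the
#' requested allopolyploids, simulates reads for every sample, and bundles
#' the full ground truth.
#'
#' @param tree_spec a [species_tree_spec()] over the diploids.
#' @param blueprint a [genome_blueprint()].
#' @param polyploids list of `list(label=, maternal=, paternal=)` entries.
#' @param coverage nuclear fold-coverage per sample.
#' @param paternal_sat_retention see [make_allopolyploid()].
#' @param seed integer seed.
#' @param ... passed to [simulate_reads()].
#' @return object of class `truth_bundle`: list with `genomes`, `reads`
#'   (named list of per-sample read tables), `truth` (combined read truth),
#'   `tree_spec`, `parentage`, `sat_abundance` (species x family matrix).
#' @export
simulate_skim_study <- function(tree_spec, blueprint, polyploids = list(),
                                coverage = 5, paternal_sat_retention = 0.25,
                                seed = 1, ...) {
  set.seed(seed)
  genomes <- evolve_sequences(tree_spec, blueprint, seed = seed)
  parentage <- list()
  for (p in polyploids) {
    genomes[[p$label]] <- make_allopolyploid(
      genomes[[p$maternal]], genomes[[p$paternal]], p$label,
      paternal_sat_retention = paternal_sat_retention)
    parentage[[p$label]] <- c(maternal = p$maternal, paternal = p$paternal)
  }
  reads <- list(); truth <- list()
  for (lab in names(genomes)) {
    sim <- simulate_reads(genomes[[lab]], coverage, ...)
    reads[[lab]] <- sim$reads
    truth[[lab]] <- sim$truth
  }
  fams <- sort(unique(unlist(lapply(genomes, function(g) names(g$sat_abundance)))))
  A <- matrix(0, length(genomes), length(fams),
              dimnames = list(names(genomes), fams))
  for (lab in names(genomes))
    A[lab, names(genomes[[lab]]$sat_abundance)] <-
      genomes[[lab]]$sat_abundance
  structure(list(genomes = genomes, reads = reads,
                 truth = data.table::rbindlist(truth),
                 tree_spec = tree_spec, parentage = parentage,
                 sat_abundance = A),
            class = "truth_bundle")
}

#' Write a simulated study to disk (FASTQ pairs, truth TSV, Newick tree)
#'
#' @param study a `truth_bundle` from [simulate_skim_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(study$reads))
    write_fastq_pair(study$reads[[lab]], file.path(dir, lab))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(study$tree_spec$tree, file.path(dir, "species_tree.nwk"))
  genome_seqs <- unlist(lapply(study$genomes, function(g)
    c(setNames(g$nuclear, paste0(g$label, ".", names(g$nuclear), ".nuc")),
      setNames(list(g$plastome, g$mitogenome),
               paste0(g$label, c(".pt", ".mt"))))), recursive = FALSE)
  write_fasta(genome_seqs, file.path(dir, "genomes.fasta"))
  invisible(dir)
}
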