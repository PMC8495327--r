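# End-to-end orchestration: simulate -> assemble -> repeats -> classify ->
# satellitome -> phylo -> report, as one reproducible run.
#
# Stage order note: compartment classification needs reference sequences
# that are themselves derived from the data (assembled organelles, repeat
# cluster consensi), so assembly and repeat discovery run before
# classification; with user-supplied references those stages simply feed it.

#' Default run configuration
#'
#' Six diploids in two clades plus two allopolyploids with clade-I maternal
#' parents, on the default desk-scale blueprint. Every stage parameter has
#' a default; the config round-trips losslessly through JSON.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; per-stage seeds are derived by fixed offsets.
#' @return nested named list (class `skim_config`).
#' @export
default_config <- function(out_dir = "skim_run", seed = 1) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    write_files = TRUE,
    resume = FALSE,
    simulator = list(
      newick = paste0("((dipA1:0.008,dipA2:0.01):0.025,",
                      "((dipB1:0.012,dipB2:0.009):0.01,",
                      "(dipC1:0.011,dipC2:0.01):0.012):0.015);"),
      root_age_mya = 12.4,
      coverage = 5, error_rate = 0.01, read_len = 150,
      insert_mean = 350, insert_sd = 30,
      paternal_sat_retention = 0.25,
      blueprint = list(
        L_nuc = 200000, L_pt = 20000, L_mt = 35000,
        organelle_copy_boost = 50, rdna_unit_len = 1000, rdna_copies = 6,
        gc_content = 0.36, intra_array_div = 0.02, rdna_intra_div = 0.005,
        sat_families = list(
          list(family_id = "satI", monomer = 165, target_abundance = 0.025,
               gain = c("dipA1", "dipA2"), drift_sigma = 0.1),
          list(family_id = "satII", monomer = 130, target_abundance = 0.02,
               gain = c("dipB1", "dipB2"), drift_sigma = 0.1),
          list(family_id = "satIII", monomer = 110, target_abundance = 0.02,
               gain = c("dipC1", "dipC2"), drift_sigma = 0.1),
          list(family_id = "satShared", monomer = 180,
               target_abundance = 0.015, drift_sigma = 0.1)),
        te_families = list(c(2000, 10), c(800, 15))),
      polyploids = list(
        list(label = "allo1", maternal = "dipA1", paternal = "dipB1"),
        list(label = "allo2", maternal = "dipA2", paternal = "dipC1"))),
    # classification k = 15: reads of a satellite family shared across
    # clades still share >1/3 of their k-mers with a consensus from another
    # species at ~7% divergence, where k = 21 would leave them unassigned
    # and give satellite-poor samples degenerate (capped) AAF rows
    classify = list(k = 15, min_frac = 0.3),
    assemble = list(k = 25, depth_threshold = "auto", subsample = 1),
    repeats = list(base_n = 600, k = 17, min_shared = 5,
                   min_cluster_size = 5, max_clusters = 30,
                   rdna_min_period = 800, min_frac_removal = 0.2),
    satellitome = list(k = 21, min_frac = 0.25, tau = 0.01,
                       family_threshold = 0.60, variant_threshold = 0.95),
    phylo = list(k = 21, min_count = 2, min_count_total = "auto",
                 d_cap = 1.0, B = 0,
                 outgroup = NULL, rel_tolerance = 0.1, min_reads = 50,
                 compartments = c("chloroplast", "mitochondrial", "satellite",
                                  "rdna", "repeat_clustered", "total"),
                 identity_tree = TRUE,
                 cladeI = c("dipA1", "dipA2"),
                 cladeII = c("dipB1", "dipB2", "dipC1", "dipC2")))
  class(cfg) <- c("skim_config", "list")
  cfg
}

#' Read / write a run configuration (JSON)
#'
#' @param path JSON file path.
#' @return for `read_config`, a `skim_config` list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  class(cfg) <- c("skim_config", "list")
  cfg
}

#' @rdname read_config
#' @param cfg a `skim_config` list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

config_blueprint <- function(sim) {
  bp <- sim$blueprint
  sats <- lapply(bp$sat_families, function(s)
    sat_family_spec(s$family_id,
                    if (!is.null(s$monomer_seq)) s$monomer_seq else s$monomer,
                    s$target_abundance,
                    gain = if (length(s$gain)) unlist(s$gain) else NULL,
                    losses = if (length(s$losses)) lapply(s$losses, unlist) else list(),
                    drift_sigma = if (is.null(s$drift_sigma)) 0 else s$drift_sigma))
  genome_blueprint(L_nuc = bp$L_nuc, L_pt = bp$L_pt, L_mt = bp$L_mt,
                   organelle_copy_boost = bp$organelle_copy_boost,
                   rdna_unit_len = bp$rdna_unit_len,
                   rdna_copies = bp$rdna_copies,
                   sat_families = sats,
                   te_families = lapply(bp$te_families, unlist),
                   gc_content = bp$gc_content,
                   intra_array_div = bp$intra_array_div,
                   rdna_intra_div = bp$rdna_intra_div)
}

log_stage <- function(stage, ...) {
  message(sprintf("[skimploid %s] %s", stage,
                  paste(sprintf("%s", c(...)), collapse = " ")))
}

# ---- stages ----

stage_simulate <- function(cfg) {
  sim <- cfg$simulator
  ts <- species_tree_spec(sim$newick, sim$root_age_mya)
  bp <- config_blueprint(sim)
  polys <- lapply(sim$polyploids, function(p)
    list(label = p$label, maternal = p$maternal, paternal = p$paternal))
  simulate_skim_study(ts, bp, polyploids = polys, coverage = sim$coverage,
                      paternal_sat_retention = sim$paternal_sat_retention,
                      seed = stage_seed(cfg$seed, "simulate"),
                      read_len = sim$read_len, insert_mean = sim$insert_mean,
                      insert_sd = sim$insert_sd, error_rate = sim$error_rate)
}

stage_assemble <- function(study, cfg) {
  ac <- cfg$assemble
  L_pt <- cfg$simulator$blueprint$L_pt
  L_mt <- cfg$simulator$blueprint$L_mt
  out <- list()
  frac <- if (is.null(ac$subsample)) 1 else ac$subsample
  for (sp in names(study$reads)) {
    rd <- study$reads[[sp]]
    if (frac < 1) {
      set.seed(stage_seed(cfg$seed, "assemble"))
      rd <- rd[sample.int(nrow(rd), ceiling(frac * nrow(rd))), ]
    }
    asm <- assemble_circular(rd, k = ac$k,
                             depth_threshold = ac$depth_threshold)
    fr <- asm$fragments
    pick <- function(target) {
      rel <- abs(nchar(fr$seq) - target) / target
      i <- which.min(rel)
      if (length(i) && rel[i] < 0.3) fr[i, ] else NULL
    }
    out[[sp]] <- list(pt = pick(L_pt), mt = pick(L_mt), all = fr,
                      threshold = asm$threshold, n_branch = asm$n_branch)
  }
  out
}

stage_repeats <- function(study, contigs, cfg) {
  rc <- cfg$repeats
  ploidies <- vapply(study$genomes, `[[`, integer(1), "ploidy")
  mono <- vapply(study$genomes, function(g)
    sum(nchar(unlist(g$nuclear))) / (g$ploidy / 2), numeric(1))
  # repeat discovery runs on nuclear-derived reads: organelle-matching
  # reads are removed first (organelles dominate raw skim read pools)
  orefs <- list()
  for (sp in names(contigs)) {
    if (!is.null(contigs[[sp]]$pt))
      orefs$chloroplast <- c(orefs$chloroplast, contigs[[sp]]$pt$seq)
    if (!is.null(contigs[[sp]]$mt))
      orefs$mitochondrial <- c(orefs$mitochondrial, contigs[[sp]]$mt$seq)
  }
  nuclear <- study$reads
  mfr <- if (is.null(rc$min_frac_removal)) 0.2 else rc$min_frac_removal
  if (length(orefs)) {
    for (sp in names(nuclear)) {
      b <- classify_reads(nuclear[[sp]], orefs, k = cfg$classify$k,
                          min_frac = mfr)
      nuclear[[sp]] <- nuclear[[sp]][b$bin == "unassigned", ]
    }
  }
  scale <- vapply(names(nuclear), function(s)
    (mono[[s]] * ploidies[[s]] / 2) / (mono[[1]] * ploidies[[1]] / 2),
    numeric(1))
  feasible <- floor(min(vapply(names(nuclear), function(s)
    nrow(nuclear[[s]]) / scale[[s]], numeric(1))))
  base_n <- min(rc$base_n, feasible)
  if (base_n < rc$base_n)
    log_stage("repeats", sprintf("base_n capped at %d (nuclear reads available)",
                                 base_n))
  sampled <- sample_reads_scaled(nuclear, base_n, ploidies, mono,
                                 seed = stage_seed(cfg$seed, "sample"))
  out <- list()
  for (sp in names(sampled)) {
    cl <- cluster_reads(sampled[[sp]], k = rc$k, min_shared = rc$min_shared,
                        min_cluster_size = rc$min_cluster_size)
    top <- utils::head(cl, rc$max_clusters)
    data.table::setattr(top, "seqs", attr(cl, "seqs"))
    lib <- c()
    if (!is.null(contigs[[sp]]$pt)) lib <- c(lib, chloroplast = contigs[[sp]]$pt$seq)
    if (!is.null(contigs[[sp]]$mt)) lib <- c(lib, mitochondrial = contigs[[sp]]$mt$seq)
    ch <- characterize_clusters(top, library = if (length(lib)) lib else NULL,
                                k = rc$k)
    ch[, class := ifelse(annotation %in% c("chloroplast", "mitochondrial"),
                         annotation,
                  ifelse(is_tandem & !is.na(period) & period >= rc$rdna_min_period,
                         "rdna",
                  ifelse(is_tandem, "satellite", "repeat_clustered")))]
    ch[, species := sp]
    out[[sp]] <- ch
  }
  out
}

stage_classify <- function(study, contigs, reptabs, cfg) {
  cc <- cfg$classify
  # global reference panel
  refs <- list(chloroplast = character(0), mitochondrial = character(0),
               rdna = character(0), satellite = character(0),
               repeat_clustered = character(0))
  for (sp in names(contigs)) {
    if (!is.null(contigs[[sp]]$pt))
      refs$chloroplast <- c(refs$chloroplast, contigs[[sp]]$pt$seq)
    if (!is.null(contigs[[sp]]$mt))
      refs$mitochondrial <- c(refs$mitochondrial, contigs[[sp]]$mt$seq)
  }
  # second-pass comparative annotation: a cluster that failed tandem
  # detection in its own sample (too few sampled reads) but matches another
  # sample's satellite consensus is a satellite of that family; without
  # this, such a cluster's consensus captures the sample's satellite reads
  # into the dispersed-repeat bin and the sample's satellite k-mer profile
  # degenerates
  sat_units <- unlist(lapply(reptabs, function(tab) {
    tb <- tab[tab$class == "satellite" & !is.na(tab$period), ]
    vapply(seq_len(nrow(tb)), function(i)
      substr(tb$consensus[i], 1L, min(nchar(tb$consensus[i]),
                                      2L * tb$period[i])), character(1))
  }))
  for (sp in names(reptabs)) {
    tab <- reptabs[[sp]]
    for (i in seq_len(nrow(tab))) {
      cls <- tab$class[i]
      if (cls %in% c("chloroplast", "mitochondrial")) next # covered by contigs
      seqc <- tab$consensus[i]
      if (cls == "repeat_clustered" && length(sat_units)) {
        hit <- classify_by_library(seqc, setNames(sat_units,
                                                  seq_along(sat_units)),
                                   k = 13, min_score = 0.25)
        if (!hit$label %in% "non-classified") cls <- "satellite"
      }
      if (cls %in% c("satellite", "rdna") && !is.na(tab$period[i]))
        seqc <- substr(seqc, 1L, min(nchar(seqc), 2L * tab$period[i]))
      refs[[cls]] <- c(refs[[cls]], seqc)
    }
  }
  refs <- Filter(length, refs)
  bins <- list()
  for (sp in names(study$reads))
    bins[[sp]] <- classify_reads(study$reads[[sp]], refs, k = cc$k,
                                 min_frac = cc$min_frac)
  list(bins = bins, references = refs)
}

stage_satellitome <- function(study, reptabs, cfg) {
  sc <- cfg$satellitome
  panel <- c(); panel_meta <- list()
  for (sp in names(reptabs)) {
    tab <- reptabs[[sp]][class == "satellite"]
    for (i in seq_len(nrow(tab))) {
      nm <- sprintf("%s.%s", sp, tab$cluster_id[i])
      unit <- substr(tab$consensus[i], 1L, tab$period[i])
      panel[nm] <- substr(tab$consensus[i], 1L,
                          min(nchar(tab$consensus[i]), 2L * tab$period[i]))
      panel_meta[[nm]] <- list(unit = unit, period = tab$period[i])
    }
  }
  if (!length(panel))
    return(list(table = NULL, grouping = NULL, pa = NULL, signatures = list()))
  tab <- satellite_abundance(study$reads, panel, k = sc$k,
                             min_frac = sc$min_frac)
  tab <- filter_min_abundance(tab, sc$tau)
  if (!ncol(tab$A))
    return(list(table = tab, grouping = NULL, pa = NULL, signatures = list()))
  units <- vapply(names(tab$consensi), function(nm) panel_meta[[nm]]$unit,
                  character(1))
  grouping <- group_families(units, sc$family_threshold, sc$variant_threshold)
  tab$grouping <- grouping
  pa <- presence_absence(tab, sc$tau)
  clades <- list(cladeI = unlist(cfg$phylo$cladeI),
                 cladeII = unlist(cfg$phylo$cladeII))
  sigs <- list()
  for (p in cfg$simulator$polyploids)
    sigs[[p$label]] <- infer_parental_signatures(pa, p$label, clades)
  list(table = tab, grouping = grouping, pa = pa, signatures = sigs)
}

stage_phylo <- function(study, binsres, contigs, cfg) {
  pc <- cfg$phylo
  bins <- binsres$bins
  compartments <- if (!is.null(pc$compartments)) unlist(pc$compartments)
    else c("chloroplast", "mitochondrial", "satellite", "rdna",
           "repeat_clustered", "total")
  min_reads <- if (is.null(pc$min_reads)) 50L else as.integer(pc$min_reads)
  trees <- list(); dists <- list()
  # Profiles of *total* reads use a coverage-scaled count filter so that,
  # as in real skimming data, only the high-copy fraction (organelles,
  # satellites, rDNA, dispersed repeats) contributes distinct k-mers; at
  # desk-scale coverage single-copy k-mers would otherwise pass the filter
  # and drown the repetitive signal the method rides on.
  mc_total <- pc$min_count_total
  if (is.null(mc_total) || identical(mc_total, "auto"))
    mc_total <- max(pc$min_count, ceiling(3 * cfg$simulator$coverage))
  for (comp in compartments) {
    profiles <- list()
    for (sp in names(bins)) {
      idx <- if (comp == "total") seq_len(nrow(study$reads[[sp]]))
             else which(bins[[sp]]$bin == comp)
      if (length(idx) < min_reads) next
      mc <- if (comp == "total") mc_total else pc$min_count
      profiles[[sp]] <- build_profile(study$reads[[sp]]$seq[idx], k = pc$k,
                                      min_count = mc, source = sp)
    }
    if (length(profiles) < 3) next
    D <- aaf_distance_matrix(profiles, d_cap = pc$d_cap)
    tr <- if (pc$B > 0)
      bootstrap_supports(profiles, B = pc$B,
                         seed = stage_seed(cfg$seed, "bootstrap"),
                         d_cap = pc$d_cap)$tree
    else neighbor_joining(D)
    trees[[comp]] <- tr
    dists[[comp]] <- D
  }
  # alignment-based comparator on assembled plastomes
  if (!identical(pc$identity_tree, FALSE)) {
    pt_seqs <- c()
    for (sp in names(contigs))
      if (!is.null(contigs[[sp]]$pt)) pt_seqs[sp] <- contigs[[sp]]$pt$seq
    if (length(pt_seqs) >= 3)
      trees[["plastome_identity"]] <- identity_tree(pt_seqs)
  }

  polyploids <- vapply(cfg$simulator$polyploids, `[[`, character(1), "label")
  diploids <- setdiff(names(study$reads), polyploids)
  cladeI <- unlist(pc$cladeI); cladeII <- unlist(pc$cladeII)
  labels <- list(); maternal <- list()
  for (p in polyploids) {
    labels[[p]] <- lapply(trees, function(tr) {
      if (!p %in% tr$tip.label) return("unresolved")
      classify_polyploid_topology(tr, p, setdiff(cladeI, p), setdiff(cladeII, p))
    })
    src <- if (!is.null(dists$chloroplast) &&
               p %in% rownames(dists$chloroplast)) "chloroplast" else "total"
    maternal[[p]] <- c(infer_maternal_parent(
      dists[[src]], p, intersect(diploids, rownames(dists[[src]])),
      rel_tolerance = pc$rel_tolerance)[c("maternal", "ties")],
      compartment = src)
  }
  comps <- names(trees)
  rf <- matrix(NA_integer_, length(comps), length(comps),
               dimnames = list(comps, comps))
  for (i in seq_along(comps)) for (j in seq_along(comps)) {
    common <- intersect(trees[[i]]$tip.label, trees[[j]]$tip.label)
    if (length(common) >= 4) {
      ti <- ape::keep.tip(trees[[i]], common)
      tj <- ape::keep.tip(trees[[j]], common)
      rf[i, j] <- robinson_foulds(ti, tj)
    }
  }
  list(trees = trees, dists = dists, labels = labels, maternal = maternal,
       rf = rf)
}

# ---- orchestration ----

#' Run the full genome-skimming pipeline
#'
#' Executes simulate, assemble, repeats, classify, satellitome, phylo and
#' report stages in order, writing each stage's outputs (text artifacts
#' plus a binary checkpoint for resuming) before the next begins. The same
#' config and seed give an identical report body.
#'
#' @param cfg a `skim_config` (see [default_config()], [read_config()]).
#' @param end_stage last stage to run (default `"report"` = all).
#' @return object of class `run_report` (a named list; see
#'   [validate_report()] for the schema).
#' @export
run_pipeline <- function(cfg, end_stage = "report") {
  stages <- c("simulate", "assemble", "repeats", "classify", "satellitome",
              "phylo", "report")
  end_i <- match(end_stage, stages)
  if (is.na(end_i)) stop("unknown stage: ", end_stage)
  out_dir <- cfg$out_dir
  if (isTRUE(cfg$write_files))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- function(name) file.path(out_dir, paste0("stage_", name, ".rds"))
  run_stage <- function(name, fn) {
    if (isTRUE(cfg$resume) && isTRUE(cfg$write_files) &&
        file.exists(ckpt(name))) {
      log_stage(name, "resumed from checkpoint")
      return(readRDS(ckpt(name)))
    }
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_stage(name, sprintf("done in %.1fs",
                            as.numeric(Sys.time() - t0, units = "secs")))
    if (isTRUE(cfg$write_files)) saveRDS(res, ckpt(name))
    res
  }

  study <- run_stage("simulate", function() stage_simulate(cfg))
  if (isTRUE(cfg$write_files)) write_study(study, file.path(out_dir, "sim"))
  if (end_i < 2) return(invisible(study))

  contigs <- run_stage("assemble", function() stage_assemble(study, cfg))
  if (isTRUE(cfg$write_files)) {
    cs <- unlist(lapply(names(contigs), function(sp) {
      v <- c()
      if (!is.null(contigs[[sp]]$pt)) v[paste0(sp, ".pt")] <- contigs[[sp]]$pt$seq
      if (!is.null(contigs[[sp]]$mt)) v[paste0(sp, ".mt")] <- contigs[[sp]]$mt$seq
      v
    }))
    if (length(cs)) write_fasta(cs, file.path(out_dir, "organelle_contigs.fasta"))
  }
  if (end_i < 3) return(invisible(contigs))

  reptabs <- run_stage("repeats", function() stage_repeats(study, contigs, cfg))
  if (isTRUE(cfg$write_files)) {
    allrep <- data.table::rbindlist(reptabs)
    utils::write.table(
      allrep[, c("species", "cluster_id", "size", "abundance", "is_tandem",
                 "period", "annotation", "class")],
      file.path(out_dir, "repeat_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (end_i < 4) return(invisible(reptabs))

  binsres <- run_stage("classify", function()
    stage_classify(study, contigs, reptabs, cfg))
  if (isTRUE(cfg$write_files)) {
    ba <- data.table::rbindlist(lapply(names(binsres$bins), function(sp)
      cbind(species = sp, binsres$bins[[sp]])))
    utils::write.table(ba, file.path(out_dir, "bins.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (end_i < 5) return(invisible(binsres))

  sat <- run_stage("satellitome", function() stage_satellitome(study, reptabs, cfg))
  if (isTRUE(cfg$write_files) && !is.null(sat$table)) {
    utils::write.table(data.frame(species = rownames(sat$table$A),
                                  round(sat$table$A, 5), check.names = FALSE),
                       file.path(out_dir, "sat_abundance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(sat$pa))
      utils::write.table(data.frame(species = rownames(sat$pa), sat$pa,
                                    check.names = FALSE),
                         file.path(out_dir, "sat_presence.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  if (end_i < 6) return(invisible(sat))

  phy <- run_stage("phylo", function() stage_phylo(study, binsres, contigs, cfg))
  if (isTRUE(cfg$write_files))
    for (comp in names(phy$trees))
      ape::write.tree(phy$trees[[comp]],
                      file.path(out_dir, paste0("tree_", comp, ".nwk")))
  if (end_i < 7) return(invisible(phy))

  report <- run_stage("report", function() {
    rep <- list(
      trees = lapply(phy$trees, ape::write.tree),
      rf_matrix = phy$rf,
      topology_labels = phy$labels,
      maternal_calls = phy$maternal,
      satellite_abundance = if (!is.null(sat$table)) sat$table$A else NULL,
      satellite_presence = sat$pa,
      satellite_grouping = if (!is.null(sat$grouping))
        as.data.frame(sat$grouping) else NULL,
      parental_signatures = sat$signatures,
      provenance = list(
        package = "skimploid",
        version = as.character(utils::packageVersion("skimploid")),
        seed = cfg$seed,
        stage_seeds = vapply(c("simulate", "sample", "bootstrap"),
                             function(s) stage_seed(cfg$seed, s), numeric(1)),
        parameters = unclass(cfg)))
    class(rep) <- c("run_report", "list")
    rep
  })
  validate_report(report)
  if (isTRUE(cfg$write_files))
    write_report(report, file.path(out_dir, "report.json"))
  report
}

#' Write a run report to JSON
#' @param report a `run_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate a run report against the published schema
#'
#' The schema (inst/schema/run_report_schema.json) lists the required
#' top-level fields and their types; this checks presence and R-side types.
#'
#' @param report a `run_report` (or a list parsed from report.json).
#' @return TRUE invisibly; stops with a message on violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "run_report_schema.json",
                             package = "skimploid")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  req <- schema$required
  missing <- setdiff(req, names(report))
  if (length(missing))
    stop("report missing required fields: ", paste(missing, collapse = ", "))
  types <- schema$properties
  for (f in names(types)) {
    if (is.null(report[[f]])) next
    want <- types[[f]]$r_type
    if (!is.null(want) && !inherits(report[[f]], want) &&
        !is(report[[f]], want))
      stop("report field '", f, "' has wrong type (want ", want, ")")
  }
  invisible(TRUE)
}

#' Per-compartment topology congruence summary
#'
#' One row per (polyploid, compartment) with the topology label and the RF
#' distance of that compartment's tree to every other compartment tree.
#'
#' @param report a `run_report` with >= 2 compartment trees.
#' @return data.table with `polyploid`, `compartment`, `label`, and
#'   `rf_<comp>` columns.
#' @export
congruence_summary <- function(report) {
  if (length(report$trees) < 2) stop("need >= 2 compartment trees")
  comps <- names(report$trees)
  rows <- list()
  for (p in names(report$topology_labels)) {
    for (comp in comps) {
      lab <- report$topology_labels[[p]][[comp]]
      if (is.null(lab)) lab <- "unresolved"
      row <- data.table::data.table(polyploid = p, compartment = comp,
                                    label = lab)
      for (o in comps)
        row[[paste0("rf_", o)]] <- report$rf_matrix[comp, o]
      rows[[length(rows) + 1L]] <- row
    }
  }
  data.table::rbindlist(rows, fill = TRUE)
}
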