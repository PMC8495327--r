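# Shared fixture builders. Everything is generated in code under fixed
# seeds; sizes are desk-scale (stated in the methods vignette) so the full
# suite stays inside its runtime budget.

# Rotate a string left by n positions.
rotate_seq <- function(s, n) {
  L <- nchar(s)
  n <- n %% L
  if (n == 0) return(s)
  paste0(substr(s, n + 1, L), substr(s, 1, n))
}

# Minimum Hamming distance over all rotations (and both strands) of `a`
# against `b`; sequences must have equal length.
best_rotation_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  L <- nchar(a)
  cand <- vapply(0:(L - 1), function(i)
    skimploid:::hamming_cpp(rotate_seq(a, i), b), integer(1))
  rc <- revcomp(a)
  cand2 <- vapply(0:(L - 1), function(i)
    skimploid:::hamming_cpp(rotate_seq(rc, i), b), integer(1))
  min(c(cand, cand2))
}

# Paired-end reads (both mates, flat character vector) from one template.
pe_reads <- function(tmpl, coverage, circular = FALSE, read_len = 150L,
                     error_rate = 0, insert_mean = 350, insert_sd = 30) {
  n <- max(1L, as.integer(round(coverage * nchar(tmpl) / (2 * read_len))))
  r <- skimploid:::sim_reads_cpp(tmpl, circular, n, read_len, insert_mean,
                                 insert_sd, error_rate)
  c(as.character(r$r1), as.character(r$r2))
}

# Read set where each satellite family holds an exact fraction of the
# reads (read-level abundance truth for mapping-based quantification).
mixture_reads <- function(n_total, fams, monomers, seed) {
  set.seed(seed)
  n_fam <- round(n_total * fams)
  bg <- replicate(n_total - sum(n_fam), random_dna(150, 0.45))
  fam_reads <- unlist(lapply(names(n_fam), function(f) {
    if (n_fam[[f]] == 0) return(character(0))
    arr <- strrep(monomers[[f]], 40)
    starts <- sample.int(nchar(arr) - 150, n_fam[[f]], replace = TRUE)
    substring(arr, starts, starts + 149)
  }))
  data.table::data.table(id = sprintf("r%06d", seq_len(n_total)),
                         seq = c(fam_reads, bg))
}

# A 4-diploid tree spec used by simulator unit tests.
toy_tree <- function() {
  species_tree_spec(
    "((A:0.01,B:0.012):0.02,(C:0.015,D:0.01):0.018);")
}

toy_blueprint <- function(...) {
  defaults <- list(
    L_nuc = 60000, L_pt = 8000, L_mt = 12000, organelle_copy_boost = 20,
    rdna_unit_len = 1000, rdna_copies = 3,
    sat_families = list(
      sat_family_spec("satA", 165, 0.02, gain = c("A", "B"),
                      drift_sigma = 0.1),
      sat_family_spec("satC", 120, 0.015, gain = c("C", "D")),
      sat_family_spec("satAll", 180, 0.01)),
    te_families = list(c(500, 10)))
  args <- utils::modifyList(defaults, list(...))
  do.call(genome_blueprint, args)
}

# Scaled-down 6-diploid + 2-allopolyploid pipeline world for the
# maternal-recovery acceptance test: full default structure, reduced sizes
# for runtime.
accept_config <- function(seed, out_dir = tempfile("skimrun")) {
  cfg <- default_config(out_dir = out_dir, seed = seed)
  cfg$write_files <- FALSE
  cfg$simulator$blueprint$L_nuc <- 150000
  cfg$simulator$blueprint$L_pt <- 6000
  cfg$simulator$blueprint$L_mt <- 8000
  cfg$simulator$blueprint$organelle_copy_boost <- 25
  cfg$simulator$blueprint$te_families <- list(c(800, 6), c(500, 8))
  cfg$simulator$coverage <- 6
  cfg$repeats$base_n <- 450
  cfg$assemble$subsample <- 0.6
  cfg$phylo$compartments <- c("chloroplast", "satellite", "total")
  cfg$phylo$identity_tree <- FALSE
  cfg$phylo$min_reads <- 30
  cfg
}

# Six-diploid world for the AAF topology-recovery acceptance test.
six_diploid_tree <- function() {
  species_tree_spec(paste0(
    "((t1:0.01,t2:0.015):0.02,((t3:0.012,t4:0.008):0.01,",
    "(t5:0.02,t6:0.025):0.015):0.005);"))
}

six_diploid_blueprint <- function() {
  genome_blueprint(L_nuc = 40000, L_pt = 8000, L_mt = 12000,
                   organelle_copy_boost = 20, rdna_unit_len = 1000,
                   rdna_copies = 3,
                   sat_families = list(
                     sat_family_spec("sat1", 165, 0.02, drift_sigma = 0.1)),
                   te_families = list(c(500, 6)))
}
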