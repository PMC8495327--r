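# Scaled read sampling, similarity-graph clustering, consensus building,
# tandem detection, library classification, abundance table.

test_that("sample_reads_scaled scales by ploidy and genome size", {
  set.seed(71)
  mk <- function(n) data.table::data.table(id = sprintf("r%04d", 1:n),
                                           seq = replicate(n, random_dna(60, .5)))
  rs <- list(ref = mk(500), same = mk(500), tet = mk(900))
  pl <- c(ref = 2, same = 2, tet = 4)
  gs <- c(ref = 1e5, same = 1e5, tet = 1e5)
  out <- sample_reads_scaled(rs, 300, pl, gs, seed = 1)
  # two identical diploids -> equal counts
  expect_equal(nrow(out$ref), 300L)
  expect_equal(nrow(out$same), 300L)
  # tetraploid (monoploid size equal, 2x the DNA) -> 2 x base_n
  expect_equal(nrow(out$tet), 600L)
  # sampling without replacement
  expect_false(anyDuplicated(out$tet$id) > 0)
  # requesting more reads than available names the species
  expect_error(sample_reads_scaled(rs, 500, pl, gs, seed = 1), "tet")
  # reproducible under the seed
  out2 <- sample_reads_scaled(rs, 300, pl, gs, seed = 1)
  expect_identical(out, out2)
})

test_that("cluster_reads separates families and leaves unique reads alone", {
  set.seed(73)
  m1 <- random_dna(165, 0.4); m2 <- random_dna(120, 0.4)
  reads <- c(pe_reads(strrep(m1, 20), 25, error_rate = 0.01),
             pe_reads(strrep(m2, 25), 25, error_rate = 0.01),
             replicate(80, random_dna(150, 0.4)))  # non-overlapping unique reads
  truth <- rep(c("f1", "f2", "unique"),
               c(2 * round(25 * 165 * 20 / 300), 2 * round(25 * 120 * 25 / 300), 80))
  cl <- cluster_reads(reads, k = 17, min_shared = 5, min_cluster_size = 5)
  expect_equal(nrow(cl), 2L)
  # clusters are disjoint and pure vs truth
  mem <- unlist(cl$members)
  expect_false(anyDuplicated(mem) > 0)
  for (i in 1:2) {
    tt <- truth[cl$members[[i]]]
    expect_equal(length(unique(tt)), 1L)
    expect_true(unique(tt) %in% c("f1", "f2"))
  }
  expect_false(any(truth[mem] == "unique"))
  # abundance = members / total reads
  expect_equal(cl$abundance, cl$size / length(reads))
  # all reads from one array -> a single cluster
  one <- cluster_reads(pe_reads(strrep(m1, 20), 25), min_cluster_size = 5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$abundance, 1)
})

test_that("cluster_consensus rebuilds the monomer up to rotation", {
  set.seed(79)
  m <- random_dna(165, 0.42)
  # identical reads -> that read
  expect_equal(cluster_consensus(rep(substr(m, 1, 150), 5)), substr(m, 1, 150))
  # error-free reads tiling a circular monomer array
  reads <- pe_reads(strrep(m, 30), 30, error_rate = 0)
  cons <- cluster_consensus(reads, k = 17)
  td <- detect_tandem(cons)
  expect_true(td$is_tandem)
  expect_equal(td$period, 165L)
  expect_equal(best_rotation_hamming(td$unit, m), 0L)
  # 1% error at 30x: majority consensus within 1 mismatch of truth
  reads_e <- pe_reads(strrep(m, 30), 30, error_rate = 0.01)
  cons_e <- cluster_consensus(reads_e, k = 17)
  td_e <- detect_tandem(cons_e)
  expect_true(td_e$is_tandem)
  expect_lte(abs(td_e$period - 165L), 2L)
  if (td_e$period == 165L)
    expect_lte(best_rotation_hamming(td_e$unit, m), 1L)
})

test_that("detect_tandem finds the smallest acceptable period", {
  set.seed(83)
  m <- random_dna(165, 0.4)
  # exact tandem -> exact period
  td <- detect_tandem(strrep(m, 10))
  expect_true(td$is_tandem)
  expect_equal(td$period, 165L)
  # non-repetitive sequence -> not tandem
  expect_false(detect_tandem(random_dna(1000, 0.4))$is_tandem)
  # alternating 5%-diverged monomer variants: smallest acceptable period
  # reported, better-fitting higher-order period recorded as secondary
  v2 <- skimploid:::jc_mutate_cpp(m, 0.05)
  alt <- strrep(paste0(m, v2), 5)
  td2 <- detect_tandem(alt)
  expect_true(td2$is_tandem)
  expect_equal(td2$period, 165L)
  expect_equal(td2$secondary_period, 330L)
  # circular junction fallback: unit-length consensus plus reads
  unit <- random_dna(400, 0.4)
  reads <- pe_reads(strrep(unit, 10), 20, error_rate = 0)
  td3 <- detect_tandem(unit, reads = reads)
  expect_true(td3$is_tandem)
  expect_equal(td3$period, 400L)
})

test_that("classify_by_library scores and labels with tie handling", {
  set.seed(89)
  lib <- c(famA = random_dna(165, 0.4), famB = random_dna(130, 0.4))
  # identical to an entry -> that label at score 1
  r <- classify_by_library(lib[["famA"]], lib, k = 17)
  expect_equal(r$label, "famA")
  expect_equal(r$score, 1.0)
  # below min_score -> non-classified
  r2 <- classify_by_library(random_dna(200, 0.4), lib, k = 17)
  expect_equal(r2$label, "non-classified")
  # equal best scores -> ambiguous
  lib_dup <- c(x = lib[["famA"]], y = lib[["famA"]])
  r3 <- classify_by_library(lib[["famA"]], lib_dup, k = 17)
  expect_equal(r3$label, "ambiguous")
})

test_that("comparative_abundance_table aggregates per family in percent", {
  tabs <- list(
    sp1 = data.table::data.table(abundance = c(0.02, 0.01, 0.005),
                                 annotation = c("famA", "famA", "famB")),
    sp2 = data.table::data.table(abundance = c(0.04),
                                 annotation = c("famB")))
  A <- comparative_abundance_table(tabs)
  expect_equal(A["famA", "sp1"], 3)
  expect_equal(A["famB", "sp1"], 0.5)
  # species lacking a family -> 0
  expect_equal(A["famA", "sp2"], 0)
  # column sums = 100 x clustered fraction <= 100
  expect_equal(colSums(A), c(sp1 = 3.5, sp2 = 4))
  expect_true(all(colSums(A) <= 100))
})
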