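# Synthetic genome / read generator: JC substitution calibration,
# satellitome gain/loss/drift, allopolyploid formation, read simulation.

test_that("JC mutation matches the closed-form substitution probability", {
  set.seed(1)
  s <- random_dna(10000, 0.5)
  # d = 0 -> identity
  expect_identical(skimploid:::jc_mutate_cpp(s, skimploid:::jc_subst_prob(0)), s)
  # L = 10 kb, d = 0.05 -> expected differing fraction p = 0.0484
  p <- skimploid:::jc_subst_prob(0.05)
  expect_equal(p, 0.0484, tolerance = 1e-3)
  obs <- mean(charToRaw(skimploid:::jc_mutate_cpp(s, p)) != charToRaw(s))
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 10000))
  # two leaves at total path 0.1 -> pairwise difference ~ 0.0937
  p2 <- skimploid:::jc_subst_prob(0.1)
  expect_equal(p2, 0.0937, tolerance = 1e-3)
  a <- skimploid:::jc_mutate_cpp(s, skimploid:::jc_subst_prob(0.06))
  b <- skimploid:::jc_mutate_cpp(s, skimploid:::jc_subst_prob(0.04))
  obs2 <- mean(charToRaw(a) != charToRaw(b))
  # compounded mutations overlap slightly, widen to 4 sd
  expect_lt(abs(obs2 - p2), 4 * sqrt(p2 * (1 - p2) / 10000) + 0.004)
  # negative branch length rejected at the tree boundary
  expect_error(species_tree_spec("(A:-0.1,B:0.1);"), "negative")
})

test_that("evolve_satellitome implements gain/loss set logic and drift", {
  ts <- toy_tree()
  # no gains/losses beyond root, zero drift -> all species share all
  # families at target abundance
  specs <- list(sat_family_spec("f1", 100, 0.01),
                sat_family_spec("f2", 100, 0.02))
  tab <- evolve_satellitome(ts, specs, seed = 1)
  expect_true(all(tab$present))
  expect_equal(tab$abundance[tab$family == "f1"], rep(0.01, 4))
  # loss on the branch to one clade -> absent in exactly that clade
  specs2 <- list(sat_family_spec("f1", 100, 0.01,
                                 losses = list(c("C", "D"))))
  tab2 <- evolve_satellitome(ts, specs2, seed = 1)
  expect_equal(tab2$present[match(c("A", "B", "C", "D"), tab2$species)],
               c(TRUE, TRUE, FALSE, FALSE))
  # gain below root -> present only below the gain edge
  specs3 <- list(sat_family_spec("f1", 100, 0.01, gain = c("A", "B")))
  tab3 <- evolve_satellitome(ts, specs3, seed = 1)
  expect_equal(tab3$present[match(c("A", "B", "C", "D"), tab3$species)],
               c(TRUE, TRUE, FALSE, FALSE))
  # loss edge outside the gain clade rejected
  expect_error(
    evolve_satellitome(ts, list(sat_family_spec("f1", 100, 0.01,
                                                gain = c("A", "B"),
                                                losses = list("C"))), 1),
    "descendant")
  # lognormal drift: sd of log abundance ~ sigma * sqrt(branches on path)
  specs4 <- list(sat_family_spec("f1", 100, 0.01, drift_sigma = 0.3))
  la <- replicate(400, {
    t <- evolve_satellitome(ts, specs4, seed = sample.int(1e6, 1))
    log(t$abundance[t$species == "A"])
  })
  # A is two branches below the root
  expect_equal(sd(la), 0.3 * sqrt(2), tolerance = 0.12)
})

test_that("make_allopolyploid unions nuclei and copies organelles maternally", {
  genomes <- evolve_sequences(toy_tree(), toy_blueprint(), seed = 9)
  A <- genomes$A; C <- genomes$C
  P <- make_allopolyploid(A, C, "P", paternal_sat_retention = 1)
  # organelles byte-identical to the maternal parent
  expect_identical(P$plastome, A$plastome)
  expect_identical(P$mitogenome, A$mitogenome)
  # nuclear additivity at full retention
  expect_equal(sum(nchar(unlist(P$nuclear))),
               sum(nchar(unlist(A$nuclear))) + sum(nchar(unlist(C$nuclear))))
  expect_equal(P$ploidy, 4L)
  # satellite family set = union of the parents'
  expect_setequal(names(P$sat_abundance),
                  union(names(A$sat_abundance), names(C$sat_abundance)))
  # maternal-only family present ('satA' gained on the (A,B) stem)
  expect_true("satA" %in% names(P$sat_abundance))
  expect_false("satA" %in% names(C$sat_abundance))
  # paternal truncation shrinks paternal satellite content but keeps it
  P2 <- make_allopolyploid(A, C, "P2", paternal_sat_retention = 0.5)
  expect_true("satC" %in% names(P2$sat_abundance))
  expect_lt(P2$sat_abundance[["satC"]], P$sat_abundance[["satC"]])
  # same genome twice -> autopolyploid warning
  expect_warning(make_allopolyploid(A, A, "auto"), "autopolyploid")
  # non-diploid parent rejected
  expect_error(make_allopolyploid(P, C, "bad"), "diploid")
})

test_that("simulate_reads obeys count, substring and error contracts", {
  set.seed(4)
  tmpl <- random_dna(30000, 0.4)
  # L = 30,000, coverage 10x, 2x150 -> 1,000 read pairs
  r <- skimploid:::sim_reads_cpp(tmpl, FALSE, as.integer(10 * 30000 / 300),
                                 150L, 350, 30, 0)
  expect_length(r$r1, 1000L)
  # error-free reads are exact substrings of the template or its revcomp
  doubled <- paste0(tmpl, tmpl)
  hits <- vapply(head(as.character(r$r1), 50), function(x)
    grepl(x, doubled, fixed = TRUE) ||
      grepl(revcomp(x), doubled, fixed = TRUE), logical(1))
  expect_true(all(hits))
  # error_rate 0.01 -> mean mismatches per 150 bp read ~ 1.5
  re <- skimploid:::sim_reads_cpp(tmpl, FALSE, 2000L, 150L, 350, 30, 0.01)
  mm <- vapply(seq_len(2000L), function(i) {
    frag <- substr(tmpl, re$start[i], re$start[i] + re$insert[i] - 1L)
    a <- substr(frag, 1, 150)
    x <- as.character(re$r1[i])
    min(skimploid:::hamming_cpp(x, a), skimploid:::hamming_cpp(revcomp(x), revcomp(a)),
        skimploid:::hamming_cpp(x, revcomp(substr(frag, re$insert[i] - 149, re$insert[i]))),
        skimploid:::hamming_cpp(revcomp(x), substr(frag, re$insert[i] - 149, re$insert[i])))
  }, numeric(1))
  expect_equal(mean(mm), 1.5, tolerance = 0.12)
})

test_that("per-compartment read counts scale with length x copy multiplier", {
  genomes <- evolve_sequences(toy_tree(), toy_blueprint(), seed = 2)
  sim <- simulate_reads(genomes$A, coverage = 5, error_rate = 0, seed = 3)
  n <- nrow(sim$reads)
  bp <- toy_blueprint()
  L_nuc <- sum(nchar(unlist(genomes$A$nuclear)))
  expected <- 2 * round(5 * c(L_nuc, bp$L_pt * 20, bp$L_mt * 20) / 300)
  tab <- table(sub("^A\\.(\\w+)\\..*$", "\\1", sim$reads$id))
  expect_equal(unname(tab[c("A", "pt", "mt")]), expected,
               tolerance = 1e-6, ignore_attr = TRUE)
  # truth covers every read exactly once; mates pair 1:1
  expect_equal(sort(sim$truth$read_id), sort(sim$reads$id))
  base <- sub("/[12]$", "", sim$reads$id)
  expect_true(all(table(base) == 2L))
})

test_that("identical seeds give byte-identical FASTQ output", {
  genomes <- evolve_sequences(toy_tree(),
                              toy_blueprint(L_nuc = 30000), seed = 5)
  s1 <- simulate_reads(genomes$A, coverage = 2, seed = 42)
  s2 <- simulate_reads(genomes$A, coverage = 2, seed = 42)
  expect_identical(s1, s2)
  d <- tempfile(); dir.create(d)
  p1 <- write_fastq_pair(s1$reads, file.path(d, "x"))
  p2 <- write_fastq_pair(s2$reads, file.path(d, "y"))
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))
})
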