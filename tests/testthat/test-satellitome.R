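# Mapping-based satellite quantification, the 0.01% rule, family/variant
# grouping, parental signatures.

test_that("satellite_abundance implements unique mapping with conservation", {
  set.seed(97)
  mono <- c(f1 = random_dna(165, 0.4), f2 = random_dna(130, 0.4))
  cons <- setNames(paste0(mono, mono), names(mono))
  # 100 of 10,000 reads from f1 -> A = 1.00%
  rs <- list(s1 = mixture_reads(10000, c(f1 = 0.01, f2 = 0), mono, seed = 1))
  tab <- satellite_abundance(rs, cons, k = 21, min_frac = 0.5)
  expect_equal(tab$A["s1", "f1"], 1.0)
  expect_equal(tab$A["s1", "f2"], 0)
  # conservation: assigned + ties + unassigned = total
  ct <- tab$counts
  expect_equal(ct$assigned + ct$tie + ct$unassigned, ct$total)
  # a read matching two consensi equally is counted for neither
  dup <- c(a = cons[["f1"]], b = cons[["f1"]])
  tab2 <- satellite_abundance(list(s = mixture_reads(200, c(f1 = 0.5),
                                                     mono["f1"], seed = 2)),
                              dup, k = 21, min_frac = 0.5)
  expect_equal(unname(tab2$A["s", ]), c(0, 0))
  expect_gt(tab2$counts$tie, 0)
})

test_that("filter_min_abundance applies the 0.01%-in-any-sample rule exactly", {
  set.seed(101)
  mono <- c(lo = random_dna(120, 0.4), hi = random_dna(165, 0.4),
            mid = random_dna(140, 0.4))
  cons <- setNames(paste0(mono, mono), names(mono))
  # species 1: 5 reads of 'lo' (0.005%), 11 of 'mid' (0.011%), 3% of 'hi'
  rs <- list(
    s1 = mixture_reads(100000, c(lo = 5e-5, mid = 11e-5, hi = 0.03),
                       mono, seed = 3),
    s2 = mixture_reads(2000, c(lo = 0, mid = 0, hi = 0.01), mono, seed = 4))
  tab <- satellite_abundance(rs, cons, k = 21, min_frac = 0.5)
  expect_equal(tab$A["s1", "lo"], 0.005)
  expect_equal(tab$A["s1", "mid"], 0.011)
  filt <- filter_min_abundance(tab, tau = 0.01)
  # family peaking at 0.005% dropped; 0.011% in one sample retained
  expect_false("lo" %in% colnames(filt$A))
  expect_true(all(c("mid", "hi") %in% colnames(filt$A)))
  # retained rows keep sub-threshold cells (mid absent in s2 stays visible)
  expect_equal(filt$A["s2", "mid"], 0)
  # tau = 0 -> table unchanged
  expect_equal(filter_min_abundance(tab, 0)$A, tab$A)
  # presence/absence thresholding
  pa <- presence_absence(filt, 0.01)
  expect_true(pa["s1", "mid"])
  expect_false(pa["s2", "mid"])
})

test_that("group_families clusters by rotation/strand identity", {
  set.seed(103)
  m <- random_dna(165, 0.4)
  # ~72% identity by substituting exactly 45 of 165 positions: same
  # family, different variants (the satellite variant-I/variant-II
  # situation at ~70% similarity)
  v <- m
  for (pos in seq(2, 165, by = 11)) {
    for (off in 0:2) {
      p <- pos + off
      old <- substr(v, p, p)
      substr(v, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
  }
  u <- random_dna(150, 0.4)                # unrelated -> own family
  cons <- c(m1 = m, m2 = v, other = u, dup = m)
  g <- group_families(cons, family_threshold = 0.60, variant_threshold = 0.95)
  fam <- setNames(g$family, g$consensus)
  var <- setNames(g$variant, g$consensus)
  expect_equal(fam[["m1"]], fam[["m2"]])
  expect_equal(fam[["m1"]], fam[["dup"]])
  expect_false(fam[["other"]] == fam[["m1"]])
  expect_false(var[["m1"]] == var[["m2"]])
  expect_equal(var[["m1"]], var[["dup"]])
  # rotation / strand invariance: rotating or reverse-complementing any
  # consensus changes no grouping
  cons2 <- c(m1 = rotate_seq(m, 50), m2 = revcomp(v), other = u,
             dup = revcomp(rotate_seq(m, 101)))
  g2 <- group_families(cons2)
  expect_equal(g2$family, g$family)
  expect_equal(g2$variant, g$variant)
})

test_that("infer_parental_signatures flags contributor clades", {
  fams <- c("dI", "dII", "shared")
  pa <- rbind(
    a1 = c(TRUE, FALSE, TRUE), a2 = c(TRUE, FALSE, TRUE),
    b1 = c(FALSE, TRUE, TRUE), b2 = c(FALSE, TRUE, TRUE),
    poly = c(TRUE, TRUE, TRUE))
  colnames(pa) <- fams
  clades <- list(cladeI = c("a1", "a2"), cladeII = c("b1", "b2"))
  r <- infer_parental_signatures(pa, "poly", clades)
  expect_setequal(r$contributors, c("cladeI", "cladeII"))
  expect_equal(r$diagnostics$cladeI, "dI")
  expect_false(r$inconclusive)
  # polyploid sharing only clade-II diagnostics -> single contributor
  pa2 <- pa; pa2["poly", "dI"] <- FALSE
  expect_equal(infer_parental_signatures(pa2, "poly", clades)$contributors,
               "cladeII")
  # no diagnostic satellites at all -> inconclusive, not an error
  pa3 <- pa; pa3[, c("dI", "dII")] <- TRUE
  r3 <- infer_parental_signatures(pa3, "poly", clades)
  expect_true(r3$inconclusive)
  expect_length(r3$contributors, 0)
})
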