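# Circular assembly, long-repeat detection, anchor synteny.

test_that("assemble_circular reconstructs a circular template exactly", {
  set.seed(41)
  pt <- random_dna(20000, 0.36)
  reads <- pe_reads(pt, 50, circular = TRUE, error_rate = 0)
  asm <- assemble_circular(reads, k = 25)
  expect_true(asm$is_circular)
  expect_identical(asm$seq, normalize_sequence(pt, circular = TRUE))
  # k-mer depth ~ base coverage x (read_len - k + 1) / read_len
  expect_equal(asm$mean_depth, 50 * (150 - 25 + 1) / 150, tolerance = 0.1)
  # rotation invariance: reads from a rotated template assemble to the
  # same normalized contig
  asm2 <- assemble_circular(pe_reads(rotate_seq(pt, 7321), 50, circular = TRUE),
                            k = 25)
  expect_identical(asm2$seq, asm$seq)
  # errors tolerated via the depth threshold
  asm3 <- assemble_circular(pe_reads(pt, 50, circular = TRUE,
                                     error_rate = 0.01), k = 25)
  expect_true(asm3$is_circular)
  expect_identical(asm3$seq, asm$seq)
})

test_that("a linearized template yields is_circular = FALSE", {
  set.seed(43)
  pt <- random_dna(20000, 0.36)
  asm <- assemble_circular(pe_reads(pt, 50, circular = FALSE), k = 25)
  expect_false(asm$is_circular)
  # near-full length minus the low-coverage ramp at the ends
  expect_gt(nchar(asm$seq), 19000)
})

test_that("an internal repeat >= k causes branching, not a false circle", {
  set.seed(47)
  core <- random_dna(8000, 0.4)
  dup <- random_dna(600, 0.4)
  tmpl <- paste0(substr(core, 1, 3000), dup, substr(core, 3001, 6000), dup,
                 substr(core, 6001, 8000))
  asm <- suppressMessages(
    assemble_circular(pe_reads(tmpl, 50, circular = TRUE), k = 25))
  expect_gt(asm$n_branch, 0)
  expect_gt(nrow(asm$fragments), 1)
  expect_false(any(asm$fragments$is_circular &
                     nchar(asm$fragments$seq) > 3000))
  # insufficient depth is an explicit failure
  expect_error(assemble_circular(pe_reads(core, 50)[1:3], k = 25,
                                 depth_threshold = 10), "insufficient depth")
})

test_that("find_long_repeats enforces the >500 bp and >95% identity rules", {
  set.seed(53)
  bg <- random_dna(30000, 0.4)
  dup600 <- random_dna(600, 0.4)
  s600 <- paste0(substr(bg, 1, 5000), dup600, substr(bg, 5001, 20000), dup600,
                 substr(bg, 20001, 30000))
  r <- find_long_repeats(s600)
  expect_equal(nrow(r), 1L)
  expect_gte(r$identity, 0.99)
  expect_equal(r$orientation, "+")
  # X-drop extension may add a couple of chance-matching boundary bases
  expect_true(r$length >= 600L && r$length <= 610L)
  expect_lte(abs(r$start1 - 5000L), 5L)  # 0-based
  # 499-bp exact duplicate -> below the length threshold (flanking bases
  # pinned to differ between the copies so the construct is exactly 499)
  dup499 <- random_dna(499, 0.4)
  s499 <- paste0(substr(bg, 1, 4999), "A", dup499, "A",
                 substr(bg, 5002, 19999), "C", dup499, "C",
                 substr(bg, 20002, 30000))
  expect_equal(nrow(find_long_repeats(s499)), 0L)
  # 600-bp copy at ~4% scattered mismatches -> identity ~ 0.96
  dup_mm <- skimploid:::jc_mutate_cpp(dup600, 0.04)
  s_mm <- paste0(substr(bg, 1, 5000), dup600, substr(bg, 5001, 20000), dup_mm,
                 substr(bg, 20001, 30000))
  r_mm <- find_long_repeats(s_mm)
  expect_equal(nrow(r_mm), 1L)
  expect_equal(r_mm$identity, 0.96, tolerance = 0.015)
  # ~6% divergence -> below the identity threshold
  dup_bad <- skimploid:::jc_mutate_cpp(dup600, 0.062)
  s_bad <- paste0(substr(bg, 1, 5000), dup600, substr(bg, 5001, 20000),
                  dup_bad, substr(bg, 20001, 30000))
  expect_equal(nrow(find_long_repeats(s_bad)), 0L)
})

test_that("find_long_repeats sees inverted repeats and is strand-symmetric", {
  set.seed(59)
  bg <- random_dna(20000, 0.4)
  dup <- random_dna(700, 0.4)
  s <- paste0(substr(bg, 1, 4000), dup, substr(bg, 4001, 12000), revcomp(dup),
              substr(bg, 12001, 20000))
  r <- find_long_repeats(s)
  expect_equal(nrow(r), 1L)
  expect_equal(r$orientation, "-")
  # reverse-complementing the whole sequence preserves the repeat call
  r2 <- find_long_repeats(revcomp(s))
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$length, r$length)
  expect_equal(r2$identity, r$identity)
})

test_that("synteny_blocks chains unique anchors into collinear runs", {
  set.seed(61)
  A <- random_dna(12000, 0.4)
  # A == B -> one full-length forward block
  b1 <- synteny_blocks(A, A)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$orientation, "+")
  expect_equal(b1$startA, 0L)
  expect_equal(b1$endA, 12000L)
  # middle segment reverse-complemented -> 3 blocks, middle one "-"
  B <- paste0(substr(A, 1, 4000), revcomp(substr(A, 4001, 8000)),
              substr(A, 8001, 12000))
  b2 <- synteny_blocks(A, B)
  expect_equal(nrow(b2), 3L)
  expect_equal(b2$orientation[order(b2$startA)], c("+", "-", "+"))
  # swapping A and B preserves the block count and flips coordinates
  b2s <- synteny_blocks(B, A)
  expect_equal(nrow(b2s), 3L)
  expect_setequal(b2s$orientation, b2$orientation)
  # unrelated random sequences share no unique 21-mers
  expect_equal(nrow(synteny_blocks(A, random_dna(8000, 0.4))), 0L)
})
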