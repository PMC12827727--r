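test_that("partition strings parse, canonicalize and round-trip", {
  p <- parse_partition("(0,1),(2),(3)", 4)
  expect_identical(p$blocks, list(c(0L, 1L), 2L, 3L))
  expect_identical(format(p), "(0,1),(2),(3)")

  micro <- parse_partition("(0),(1),(2),(3)", 4)
  expect_identical(micro$blocks, as.list(0:3))
  expect_identical(format(discrete_partition(4)), "(0),(1),(2),(3)")

  # non-canonical input canonicalizes: blocks sorted by smallest member
  q <- parse_partition("(3),(2,1),(0)", 4)
  expect_identical(format(q), "(0),(1,2),(3)")
  expect_identical(format(parse_partition(format(q), 4)), format(q))

  expect_error(parse_partition("(0,0),(1)", 2), "duplicate")
  expect_error(parse_partition("(0),(1)", 3), "cover")
  expect_error(parse_partition("(0),(3)", 2), "out of range")
  expect_error(parse_partition("0,1),(2", 3), "malformed")
})

test_that("coarse-graining aggregates rows and stays stochastic", {
  cb <- cycle_block_8()
  # identity partition leaves the TPM unchanged
  id <- coarse_grain_tpm(cb, discrete_partition(8))
  expect_equal(unclass(id), unclass(cb), ignore_attr = TRUE)

  # two-block uniform block model lumps to the 2x2 identity
  macro <- coarse_grain_tpm(two_block_8(), parse_partition("(0,1,2,3),(4,5,6,7)", 8))
  expect_equal(unclass(macro), diag(2), ignore_attr = TRUE)
  expect_tpm_valid(macro)

  # merging only the uniform block gives a macrostate with a p = 1 self-loop
  m <- coarse_grain_tpm(cb, parse_partition("(0),(1),(2),(3),(4,5,6,7)", 8))
  expect_equal(unclass(m)[5, 5], 1)
  expect_tpm_valid(m)
})

test_that("refinement ordering matches the coarse-graining lattice", {
  f <- parse_partition("(0,1),(2),(3)", 4)
  c1 <- parse_partition("(0,1,2),(3)", 4)
  expect_true(is_refinement(f, c1))
  expect_true(is_refinement(f, f))
  expect_false(is_refinement(parse_partition("(0,1),(2,3)", 4),
                             parse_partition("(0,2),(1,3)", 4)))
  expect_error(is_refinement(f, discrete_partition(5)), "different")
})

test_that("partition enumeration counts Bell numbers and respects the guard", {
  bell <- c(1, 1, 2, 5, 15, 52, 203, 877, 4140)
  for (n in 0:8) {
    parts <- enumerate_partitions(n)
    expect_length(parts, bell[n + 1])
    expect_equal(anyDuplicated(vapply(parts, format, character(1))), 0L)
  }
  expect_error(enumerate_partitions(11), "guard")
})

test_that("dynamical consistency accepts lumpable partitions and rejects others", {
  # equivalency classes (identical rows) are exactly lumpable
  res <- consistency_check(two_block_8(), parse_partition("(0,1,2,3),(4,5,6,7)", 8),
                           tol = 1e-10, horizon = 10)
  expect_true(res$consistent)
  expect_lte(res$max_error, 1e-12)

  id <- consistency_check(cycle_block_8(), discrete_partition(8))
  expect_true(id$consistent)
  expect_equal(id$max_error, 0)

  # merging states with different block-level outflows diverges at t = 1
  tm <- tpm(rbind(c(1, 0, 0), c(0, 0, 1), c(0, 0, 1)))
  bad <- consistency_check(tm, parse_partition("(0,1),(2)", 3))
  expect_false(bad$consistent)
  expect_gt(bad$max_error, 0.1)
})

test_that("partial merges of an equivalency class stay consistent at any horizon", {
  cb <- cycle_block_8()
  for (lab in c("(0),(1),(2),(3),(4,5),(6),(7)",
                "(0),(1),(2),(3),(4,5,6),(7)",
                "(0),(1),(2),(3),(4,5,6,7)")) {
    res <- consistency_check(cb, parse_partition(lab, 8), tol = 1e-10, horizon = 10)
    expect_true(res$consistent)
  }
})

test_that("distributions lump blockwise and stationary laws commute with lumping", {
  u <- uniform_intervention(4)
  got <- coarsen_distribution(u, parse_partition("(0,1),(2),(3)", 4))
  expect_equal(got$weights, c(0.5, 0.25, 0.25))

  point <- intervention(c(0, 0, 1, 0))
  expect_equal(coarsen_distribution(point, parse_partition("(0,1),(2,3)", 4))$weights,
               c(0, 1))

  # stationary of the block model, coarsened, is stationary for the macro TPM
  bm <- two_block_8()
  part <- parse_partition("(0,1,2,3),(4,5,6,7)", 8)
  pi_macro <- coarsen_distribution(stationary_distribution(bm), part)$weights
  M <- unclass(coarse_grain_tpm(bm, part))
  expect_equal(drop(pi_macro %*% M), pi_macro, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("two-step coarse-graining composes exactly along fixture chains", {
  cb <- cycle_block_8()
  p1 <- parse_partition("(0),(1),(2),(3),(4,5),(6,7)", 8)
  p2 <- parse_partition("(0),(1),(2),(3),(4,5,6,7)", 8)
  step1 <- coarse_grain_tpm(cb, p1)
  # induced partition of p1's blocks under p2: merge its last two blocks
  induced <- parse_partition("(0),(1),(2),(3),(4,5)", 6)
  expect_equal(unclass(coarse_grain_tpm(step1, induced)),
               unclass(coarse_grain_tpm(cb, p2)), ignore_attr = TRUE)
})
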