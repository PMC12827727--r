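test_that("sufficiency reads transition probabilities directly", {
  copy <- make_permutation(2)               # self-loops with p = 1
  expect_equal(sufficiency(copy, 1, 1), 1)
  u4 <- uniform_tpm(4)
  for (c in 0:3) for (e in 0:3) expect_equal(sufficiency(u4, c, e), 0.25)
  tm <- tpm(rbind(c(0.7, 0.1, 0.1, 0.1), matrix(0.25, 3, 4)))
  expect_equal(sufficiency(tm, 0, 0), 0.7)
  expect_error(sufficiency(tm, 4, 0), "out of range")
})

test_that("necessity measures how irreplaceable a cause is", {
  perm <- make_permutation(2, c(1, 0))
  expect_equal(necessity(perm, 0, 1), 1)    # no other state leads to 1
  expect_equal(necessity(perm, 1, 0), 1)

  for (n in c(3, 5, 8)) {
    u <- uniform_tpm(n)
    expect_equal(necessity(u, 0, 0), 1 - 1 / n, tolerance = 1e-12)
  }

  # hand case: rows (1,0,0), (1,0,0), (0,0,1); P(e0 | not c0) = (1+0)/2
  tm <- tpm(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  expect_equal(necessity(tm, 0, 0), 0.5)

  expect_error(necessity(tpm(matrix(1)), 0, 0), "1-state")
  expect_error(necessity(perm, 0, 1, pc = intervention(c(1, 0))), "all mass")
})

test_that("system-wide sufficiency and necessity average over transitions", {
  perm <- make_permutation(8, c(1:7, 0))
  expect_equal(system_sufficiency(perm), 1)
  expect_equal(system_necessity(perm), 1)

  u4 <- uniform_tpm(4)
  expect_equal(system_sufficiency(u4), 0.25, tolerance = 1e-12)
  expect_equal(system_necessity(u4), 0.75, tolerance = 1e-12)

  # every cause leads to state 0: fully sufficient, not at all necessary
  sink <- tpm(rbind(c(1, 0), c(1, 0)))
  expect_equal(system_sufficiency(sink), 1)
  expect_equal(system_necessity(sink), 0)
})

test_that("determinism and degeneracy coefficients match hand computations", {
  perm <- make_permutation(8, c(1:7, 0))
  expect_equal(determinism_coefficient(perm), 1)
  expect_equal(degeneracy_coefficient(perm), 0, tolerance = 1e-12)

  u8 <- uniform_tpm(8)
  expect_equal(determinism_coefficient(u8), 0, tolerance = 1e-12)

  # 4-cycle + uniform 4-block: (4*1 + 4*(1 - 2/3)) / 8 = 2/3; effects uniform
  cb <- cycle_block_8()
  expect_equal(determinism_coefficient(cb), 2 / 3, tolerance = 1e-12)
  expect_equal(degeneracy_coefficient(cb), 0, tolerance = 1e-12)

  sink <- tpm(rbind(c(1, 0), c(1, 0)))
  expect_equal(degeneracy_coefficient(sink), 1)
  expect_equal(specificity_coefficient(sink), 0)
})

test_that("combined CP scores and their invariants hold on reference systems", {
  for (tm in list(make_permutation(4, c(1, 2, 3, 0)), uniform_tpm(4),
                  cycle_block_8(), two_block_8())) {
    s <- cp_scores(tm)
    expect_equal(s$specificity, 1 - s$degeneracy)
    expect_equal(s$cp_info, s$effectiveness, tolerance = 1e-12)
    expect_equal(s$ei, s$effectiveness * log2(s$n_states), tolerance = 1e-9)
    expect_true(all(c(s$suff_sys, s$nec_sys, s$determinism, s$degeneracy)
                    >= -1e-12))
    expect_true(all(c(s$suff_sys, s$nec_sys, s$determinism, s$degeneracy)
                    <= 1 + 1e-12))
  }
  expect_equal(cp_scores(make_permutation(5, c(1:4, 0)))$cp_primitive, 1)
  expect_equal(cp_scores(uniform_tpm(5))$cp_primitive, 0, tolerance = 1e-12)
  expect_equal(cp_scores(uniform_tpm(5))$cp_info, 0, tolerance = 1e-12)
  expect_equal(cp_scores(cycle_block_8())$cp_info, 2 / 3, tolerance = 1e-12)
})

test_that("CP equals 1 on permutations and 0 on uniform TPMs for n in 2..16", {
  for (n in 2:16) {
    perm <- make_permutation(n, c(seq_len(n - 1), 0))
    expect_equal(cp_scores(perm)$cp_primitive, 1, tolerance = 1e-12)
    expect_equal(cp_scores(perm)$cp_info, 1, tolerance = 1e-12)
    u <- uniform_tpm(n)
    expect_equal(cp_scores(u)$cp_primitive, 0, tolerance = 1e-12)
    expect_equal(cp_scores(u)$cp_info, 0, tolerance = 1e-12)
  }
})

test_that("effective information matches hand values and 1-state convention", {
  expect_equal(effective_information(make_permutation(8, c(1:7, 0))), 3)
  expect_equal(effective_information(uniform_tpm(8)), 0, tolerance = 1e-12)
  expect_equal(effective_information(two_block_8()), 1, tolerance = 1e-12)
  expect_equal(effective_information(tpm(matrix(1))), 0)
})

test_that("effective information equals directly computed mutual information", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    tm <- make_random_tpm(n, concentration = sample(c(0.3, 1, 3), 1))
    w <- uniform_intervention(n)$weights
    expect_equal(effective_information(tm, uniform_intervention(n)),
                 mi_oracle(tm, w), tolerance = 1e-9)
    # also under a random intervention distribution
    g <- rgamma(n, 1); w2 <- g / sum(g)
    pc <- intervention(w2)
    expect_equal(effective_information(tm, pc), mi_oracle(tm, w2),
                 tolerance = 1e-9)
  }
})

test_that("blending toward uniform never increases determinism or sufficiency", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    tm <- make_random_tpm(n, concentration = 0.5)
    U <- matrix(1 / n, n, n)
    lambdas <- seq(0, 1, by = 0.2)
    det_tr <- suff_tr <- numeric(length(lambdas))
    for (i in seq_along(lambdas)) {
      tm_l <- tpm((1 - lambdas[i]) * unclass(tm) + lambdas[i] * U)
      det_tr[i] <- determinism_coefficient(tm_l)
      suff_tr[i] <- system_sufficiency(tm_l)
    }
    expect_true(all(diff(det_tr) <= 1e-12))
    expect_true(all(diff(suff_tr) <= 1e-12))
  }
})

test_that("degeneracy depends on rows only through the effect mixture", {
  # two TPMs with permuted rows under uniform P(C) share P(E), hence degeneracy
  set.seed(3)
  tm <- make_random_tpm(6)
  perm_rows <- unclass(tm)[sample(6), ]
  expect_equal(degeneracy_coefficient(tpm(perm_rows)),
               degeneracy_coefficient(tm), tolerance = 1e-12)
})
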