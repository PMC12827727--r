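# Shared fixture systems and independent oracles.

cycle_block_8 <- function() make_cycle_plus_block(4, 4)
two_block_8 <- function() make_block_model(c(4, 4))
uniform_tpm <- function(n) tpm(matrix(1 / n, n, n))

# Independent mutual-information oracle: I(C; E) computed directly from the
# joint distribution p(c, e) = pc(c) * P(e | c), never via the
# effectiveness * log2(n) decomposition it is used to check.
mi_oracle <- function(tm, weights) {
  P <- unclass(tm)
  joint <- weights * P                  # rows scaled by pc(c)
  pe <- colSums(joint)
  total <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (joint[i, j] > 0) {
        total <- total + joint[i, j] * log2(joint[i, j] / (weights[i] * pe[j]))
      }
    }
  }
  unname(total)
}

# Entropy oracle by direct summation (base-2), for cross-checking.
entropy_oracle <- function(p) {
  s <- 0
  for (x in p) if (x > 0) s <- s - x * log2(x)
  s
}

expect_tpm_valid <- function(tm) {
  expect_s3_class(tm, "tpm")
  expect_true(all(abs(rowSums(unclass(tm)) - 1) < 1e-12))
  expect_true(all(unclass(tm) >= 0 & unclass(tm) <= 1))
  expect_false(anyDuplicated(rownames(tm)) > 0)
}

fixture_families <- function() {
  list(
    block_4_4 = two_block_8(),
    block_2x4 = make_block_model(c(2, 2, 2, 2)),
    cycle_block_4_4 = cycle_block_8(),
    cycle_block_1_2 = make_cycle_plus_block(1, 2),
    mesoscale_4_4 = make_mesoscale_variant(c(4, 4), c(0.7, 0.1, 0.1, 0.1)),
    nested_pairs = make_nested_blocks(0.95),
    permutation_8 = make_permutation(8, c(1:7, 0)),
    uniform_6 = uniform_tpm(6)
  )
}
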