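test_that("left kernel basis handles the mitosis, full-rank and zero matrices", {
  A <- stoichiometric_matrix(get_fixture("mitosis_z1")$network)
  kb <- left_kernel_basis(A)
  expect_equal(kb$d, 1L)
  expect_equal(unname(kb$num[1, ] / kb$den[1, ]), c(1, 1, 1))
  expect_equal(kb$pivots, 1L)

  full <- stoichiometric_matrix(parse_network(c("r1: A -> 0", "r2: B -> 0")))
  expect_equal(left_kernel_basis(full)$d, 0L)

  zero <- structure(list(mat = matrix(0L, 2, 3), rank = 0L),
                    class = "stoich_matrix")
  kbz <- left_kernel_basis(zero)
  expect_equal(kbz$num / kbz$den, diag(2))
  expect_equal(kbz$pivots, c(1L, 2L))
})

test_that("kernel basis is a Gauss-reduced (RREF) basis of the left kernel", {
  for (seed in 1:25) {
    rn <- random_network(seed)
    A <- stoichiometric_matrix(rn$network)
    kb <- left_kernel_basis(A)
    expect_equal(kb$d, nrow(A$mat) - A$rank)
    if (kb$d == 0) next
    W <- kb$num / kb$den
    expect_true(all(abs(W %*% A$mat) == 0))           # each w . A = 0
    expect_true(all(diff(kb$pivots) > 0))             # pivots increasing
    for (r in seq_len(kb$d)) {
      expect_equal(W[r, kb$pivots[r]], 1)             # leading entries 1
      expect_true(all(W[-r, kb$pivots[r]] == 0))      # pivot cols elsewhere 0
    }
  }
})

test_that("the mitosis polynomials match the published 5- and 3-term forms", {
  net <- get_fixture("mitosis_z1")$network
  A <- stoichiometric_matrix(net)
  p1 <- injectivity_polynomial(A, get_fixture("mitosis_z1")$influence)
  p2 <- injectivity_polynomial(A, get_fixture("mitosis_z2")$influence)
  expect_identical(format_polynomial(p1), GOLDEN_P_Z1)
  expect_identical(format_polynomial(p2), GOLDEN_P_Z2)
  expect_true(all(abs(p1$num) == 1 & p1$den == 1))
  expect_equal(p1$degree, 2L)
})

test_that("wrong-sign terms and verdicts follow the sign classification", {
  rep1 <- fixture_report("mitosis_z1")
  ws <- wrong_sign_terms(rep1$polynomial, rep1$s)
  expect_setequal(ws$monomial, c("1.1|3.3", "2.2|3.3"))
  expect_true(all(ws$num == -1))
  expect_equal(injectivity_verdict(rep1$polynomial), "INCONCLUSIVE")

  rep2 <- fixture_report("mitosis_z2")
  expect_equal(nrow(wrong_sign_terms(rep2$polynomial, rep2$s)), 0)
  expect_equal(injectivity_verdict(rep2$polynomial), "INJECTIVE")

  # rank-1 network with an all-zero influence: determinant vanishes
  net <- parse_network("r1: A -> B")
  zero_tab <- matrix("0", 2, 1, dimnames = list(c("A", "B"), "r1"))
  p0 <- injectivity_polynomial(stoichiometric_matrix(net),
                               influence_from_table(net, zero_tab))
  expect_equal(n_terms(p0), 0)
  expect_equal(injectivity_verdict(p0), "DEGENERATE")
  expect_equal(nrow(wrong_sign_terms(p0, 1)), 0)
})

test_that("zeroing an influence entry commutes with substituting gamma = 0", {
  fx1 <- get_fixture("mitosis_z1")
  A <- stoichiometric_matrix(fx1$network)
  p1 <- injectivity_polynomial(A, fx1$influence)
  # Z1 with entry (3,3) zeroed is exactly Z2
  expect_identical(
    format_polynomial(injectivity_polynomial(A, zero_influence(fx1$influence, 3, 3))),
    format_polynomial(dsrloops:::poly_zero_gamma(p1, 3, 3)))

  for (seed in 1:10) {
    rn <- random_network(seed)
    A <- stoichiometric_matrix(rn$network)
    p <- injectivity_polynomial(A, rn$influence)
    nz <- which(rn$influence$sign != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(nz))) {
      Zk <- zero_influence(rn$influence, nz[k, 1], nz[k, 2])
      expect_identical(
        format_polynomial(injectivity_polynomial(A, Zk)),
        format_polynomial(dsrloops:::poly_zero_gamma(p, nz[k, 1], nz[k, 2])),
        label = sprintf("seed %d entry (%d,%d)", seed, nz[k, 1], nz[k, 2]))
    }
  }
})

test_that("the memoized expansion equals the naive permutation-sum oracle", {
  for (nm in c("mitosis_z1", "mitosis_z2", "michaelis_menten")) {
    fx <- get_fixture(nm)
    A <- stoichiometric_matrix(fx$network)
    expect_identical(
      format_polynomial(injectivity_polynomial(A, fx$influence)),
      oracle_poly_string(A, fx$influence), label = nm)
  }
  for (seed in 1:30) {
    rn <- random_network(seed)
    A <- stoichiometric_matrix(rn$network)
    expect_identical(
      format_polynomial(injectivity_polynomial(A, rn$influence)),
      oracle_poly_string(A, rn$influence),
      label = sprintf("seed %d", seed))
  }
})

test_that("every stored monomial has s factors with distinct species and reactions", {
  for (seed in 1:30) {
    rn <- random_network(seed)
    A <- stoichiometric_matrix(rn$network)
    p <- injectivity_polynomial(A, rn$influence)
    tt <- poly_terms(p)
    for (key in tt$monomial) {
      f <- dsrloops:::mono_factors(key)
      expect_equal(nrow(f), A$rank)
      expect_false(anyDuplicated(f[, 1]) > 0)
      expect_false(anyDuplicated(f[, 2]) > 0)
      expect_true(all(rn$influence$sign[f] != 0))
    }
  }
})

test_that("a dimension mismatch between A and Z is rejected", {
  A <- stoichiometric_matrix(get_fixture("mitosis_z1")$network)
  Zother <- get_fixture("michaelis_menten")$influence
  expect_error(injectivity_polynomial(A, Zother), "dimension mismatch")
})
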