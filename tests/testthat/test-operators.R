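test_that("canonical anticommutation relations hold to machine precision", {
  for (L in 1:2) {
    lat <- lattice_spec(L)
    ann <- all_ladders(lat, dagger = FALSE)
    cre <- all_ladders(lat, dagger = TRUE)
    I <- Matrix::Diagonal(lat$dim)
    for (n1 in names(ann)) {
      for (n2 in names(ann)) {
        # {x_i, x_j^dag} = delta_ij * identity
        ac <- ann[[n1]] %*% cre[[n2]] + cre[[n2]] %*% ann[[n1]]
        if (n1 == n2) expect_equal(max_abs(ac - I), 0)
        else expect_equal(max_abs(ac), 0)
        # {x_i, x_j} = 0 (includes nilpotency when i = j)
        expect_equal(max_abs(ann[[n1]] %*% ann[[n2]] +
                               ann[[n2]] %*% ann[[n1]]), 0)
      }
    }
  }
})

test_that("creation operator is the adjoint of annihilation", {
  lat <- lattice_spec(2)
  for (sp in c("a", "b")) {
    A <- ladder_operator(sp, 3, FALSE, lat)
    Ad <- ladder_operator(sp, 3, TRUE, lat)
    expect_equal(max_abs(Matrix::t(A) - Ad), 0)
  }
  expect_error(ladder_operator("a", 5, FALSE, lat), "invalid cell")
})

test_that("one-cell construction reproduces the four-state basis", {
  lat <- lattice_spec(1)
  vac <- vacuum_state(lat)
  ad <- ladder_operator("a", 1, TRUE, lat)
  bd <- ladder_operator("b", 1, TRUE, lat)
  # basis order: phi_00, phi_10, phi_01, phi_11 (human bit first)
  phi10 <- as.vector(ad %*% Re(vac))
  phi01 <- as.vector(bd %*% Re(vac))
  phi11 <- as.vector(ad %*% (bd %*% Re(vac)))
  basis <- cbind(Re(vac), phi10, phi01, phi11)
  expect_equal(unname(as.matrix(crossprod(basis))), diag(4))  # orthonormal
  expect_equal(which(phi10 != 0), encode_occupation(1, 0, lat) + 1L)
  expect_equal(which(phi01 != 0), encode_occupation(0, 1, lat) + 1L)
  expect_equal(which(phi11 != 0), encode_occupation(1, 1, lat) + 1L)
})

test_that("number operators are diagonal with occupation-bit eigenvalues", {
  lat <- lattice_spec(2)
  n_a2 <- number_operator("a", 2, lat)
  d <- Matrix::diag(n_a2)
  for (idx in c(0L, 5L, 37L, 255L)) {
    occ <- decode_occupation(idx, lat)
    expect_equal(d[idx + 1L], occ$m_a[2])
  }
  # half of all basis states occupy any given mode
  expect_equal(sum(d), lat$dim / 2)
  # annihilates the vacuum
  expect_equal(max_abs(n_a2 %*% Re(vacuum_state(lat))), 0)
})

test_that("vacuum is annihilated by every ladder operator", {
  lat <- lattice_spec(2)
  vac <- vacuum_state(lat)
  expect_equal(sqrt(sum(Mod(vac)^2)), 1)
  for (op in all_ladders(lat, dagger = FALSE))
    expect_equal(max_abs(op %*% Re(vac)), 0)
  d <- densities_from_state(vac, lat)
  expect_equal(d$n_a, rep(0, 4))
  expect_equal(d$n_b, rep(0, 4))
})

test_that("ladder operators are exactly sparse", {
  lat <- lattice_spec(2)
  for (op in all_ladders(lat))
    expect_lte(Matrix::nnzero(op), lat$dim / 2)
})
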