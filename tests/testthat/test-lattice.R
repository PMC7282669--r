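test_that("sequences carry the canonical hydrophobicity flags", {
  s <- peptide_sequence("TFTFTFT")
  expect_length(s, 7L)
  expect_equal(sum(is_hydrophobic(s)), 3L)
  expect_equal(is_hydrophobic(peptide_sequence("tstnq")), rep(FALSE, 5))
  all9 <- peptide_sequence(paste(fibrilMC:::HYDROPHOBIC_SET, collapse = ""))
  expect_true(all(is_hydrophobic(all9)))
  expect_error(peptide_sequence("TFX"), "position 3")
})

test_that("the seed is a valid 8-chain double sheet with buried core", {
  sys <- build_seed(peptide_sequence("TFTFTFT"), n_layers = 4)
  expect_equal(sum(vapply(sys$chains, `[[`, logical(1), "frozen")), 8L)
  expect_true(validate_system(sys))
  # free chains start dissociated
  op <- order_params(sys)
  expect_identical(op$c_ext, 0L)
  expect_identical(op$c_h_exposed, 6L)
  expect_error(build_seed(peptide_sequence("TFTFTFT"), box = 8), "box")
})

test_that("reference states reproduce the printed order-parameter constants", {
  sys <- build_seed(peptide_sequence("TFTFTFT"))
  fib <- reference_fibrillar_state(sys)
  mono <- reference_monomeric_state(sys)
  expect_identical(count_external_contacts(fib), 21L)
  expect_identical(count_external_contacts(mono), 0L)
  expect_identical(count_exposed_hydrophobic(fib), 0L)
  expect_identical(count_exposed_hydrophobic(mono), 6L)
  expect_equal(order_params(fib)$native_fraction, 1)
  # the layer decomposition: 7 intra-layer + 14 contacts to the seed layer
  expect_identical(count_exposed_hydrophobic(mono) -
                     count_exposed_hydrophobic(fib), 6L)
})

test_that("an all-polar sequence exposes no hydrophobic contacts anywhere", {
  sys <- build_seed(peptide_sequence("TTTTTTT"))
  expect_identical(count_exposed_hydrophobic(sys), 0L)
  expect_identical(
    count_exposed_hydrophobic(reference_fibrillar_state(sys)), 0L)
})

test_that("two free chains side by side far from the seed make 7 contacts", {
  s <- peptide_sequence("TFTFTFT")
  ch1 <- fibrilMC:::new_chain(cbind(1:7, 2L, 2L), rep(4L, 7),
                              rep(FALSE, 7), FALSE)
  ch2 <- fibrilMC:::new_chain(cbind(1:7, 3L, 2L), rep(4L, 7),
                              rep(FALSE, 7), FALSE)
  sys <- lattice_system(s, list(ch1, ch2), box = 20)
  expect_identical(count_external_contacts(sys), 7L)
})

test_that("contacts are invariant under rigid translation of the system", {
  sys <- reference_fibrillar_state(build_seed(peptide_sequence("TFTFTFT")))
  shifted <- sys
  for (i in seq_along(shifted$chains))
    shifted$chains[[i]]$pos <- shifted$chains[[i]]$pos +
      rep(c(1L, -2L, 1L), each = 7)
  validate_system(shifted)
  expect_identical(order_params(shifted), order_params(sys))
})

test_that("validation rejects broken geometry", {
  sys <- build_seed(peptide_sequence("TFTFTFT"))
  bad <- sys
  bad$chains[[9]]$pos[3, ] <- bad$chains[[9]]$pos[1, ]  # overlap
  expect_error(validate_system(bad), "same lattice site|connectivity")
  bad2 <- sys
  bad2$chains[[9]]$pos[7, 1] <- bad2$chains[[9]]$pos[7, 1] + 3L
  expect_error(validate_system(bad2), "connectivity")
})

test_that("trajectory snapshots round-trip through the text format", {
  sys <- reference_fibrillar_state(build_seed(peptide_sequence("TFTFTFT")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(sys, path)
  back <- read_trajectory(path)
  expect_equal(back$box, sys$box)
  expect_identical(order_params(back), order_params(sys))
  for (i in seq_along(sys$chains)) {
    expect_equal(back$chains[[i]]$pos, sys$chains[[i]]$pos)
    expect_equal(back$chains[[i]]$dir, sys$chains[[i]]$dir)
    expect_equal(back$chains[[i]]$beta, sys$chains[[i]]$beta)
  }
})
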