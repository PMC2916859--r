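# Dynamic cross-correlation maps.

test_that("self-correlation is one and planted copies give +/-1", {
  set.seed(41)
  base <- matrix(rnorm(12, sd = 10), 4, 3)
  frames <- lapply(1:200, function(f) {
    s <- rnorm(3)
    fr <- base
    fr[1, ] <- fr[1, ] + s
    fr[2, ] <- fr[2, ] + s        # identical displacement
    fr[3, ] <- fr[3, ] - s        # negated displacement
    fr[4, ] <- fr[4, ] + rnorm(3) # independent
    fr
  })
  ens <- ensemble_from_frames(frames)
  cm <- covariance_map(ens, 1:4, fit_sel = NULL, window = 1)
  expect_equal(diag(cm$matrix), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cm$matrix[1, 2], 1, tolerance = 1e-10)
  expect_equal(cm$matrix[1, 3], -1, tolerance = 1e-10)
  expect_equal(max(abs(cm$matrix - t(cm$matrix))), 0, tolerance = 1e-12)
})

test_that("independent jitter decorrelates at large n", {
  set.seed(42)
  base <- matrix(rnorm(18, sd = 10), 6, 3)
  frames <- lapply(1:5000, function(f) base + matrix(rnorm(18), 6, 3))
  cm <- covariance_map(ensemble_from_frames(frames), 1:6, fit_sel = NULL,
                       window = 1)
  off <- cm$matrix[upper.tri(cm$matrix)]
  expect_lt(max(abs(off)), 0.1)
})

test_that("zero-variance atoms are marked undefined, not zero", {
  base <- matrix(rnorm(9, sd = 5), 3, 3)
  frames <- lapply(1:50, function(f) {
    fr <- base
    fr[1:2, ] <- fr[1:2, ] + matrix(rnorm(6), 2, 3)
    fr  # atom 3 static
  })
  cm <- covariance_map(ensemble_from_frames(frames), 1:3, fit_sel = NULL,
                       window = 1)
  expect_true(all(is.na(cm$matrix[3, ])))
  expect_true(all(is.na(cm$matrix[, 3])))
  expect_false(anyNA(cm$matrix[1:2, 1:2]))
})

test_that("the map matches bio3d's dccm on a common fixture", {
  set.seed(43)
  top <- simple_topology(5)
  xyz <- matrix(rnorm(40 * 15), 40, 15)
  ens <- ensemble(top, sweep(xyz, 2, rep(10 * (1:5), each = 3), "+"))
  cm <- covariance_map(ens, 1:5, fit_sel = NULL, window = 1)
  ref <- bio3d::dccm(ens$xyz, ncore = 1)
  expect_equal(unclass(cm$matrix), unclass(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("submap extracts labelled ranges and degenerates to 1x1", {
  gen <- fixture_small()
  sel <- select_atoms(gen$ensemble, chain_id = "C", atom_name = "CA")
  cm <- covariance_map(gen$ensemble, sel, fit_sel = NULL, window = 1)
  full <- submap(cm, rows = cm$residue_number)
  expect_equal(full$matrix, cm$matrix)
  one <- submap(cm, rows = 120)
  expect_equal(dim(one$matrix), c(1, 1))
  expect_equal(as.numeric(one$matrix), 1)
  sub <- submap(cm, rows = 100:140, cols = 170:190)
  expect_equal(unname(sub$matrix),
               unname(cm$matrix[cm$residue_number %in% 100:140,
                                cm$residue_number %in% 170:190,
                                drop = FALSE]))
  expect_error(submap(cm, rows = 900:950), "no residues")
})

test_that("correlation maps are invariant under rigid motion with fitting", {
  gen <- fixture_small()
  sel <- select_atoms(gen$ensemble, chain_id = "C", atom_name = "CA")
  fit <- select_atoms(gen$ensemble, chain_id = "A", atom_name = "C3'")
  cm1 <- covariance_map(gen$ensemble, sel, fit_sel = fit, window = 1)
  cm2 <- covariance_map(random_rigid_transform(gen$ensemble), sel,
                        fit_sel = fit, window = 1)
  expect_equal(cm1$matrix, cm2$matrix, tolerance = 1e-8)
})
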