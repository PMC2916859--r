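# Superposition, RMSD/RMSF, average structures and the organizational
# angle/dihedral.

test_that("kabsch recovers identity and rigid transforms exactly", {
  set.seed(31)
  x <- matrix(rnorm(24, sd = 5), ncol = 3)
  sp <- kabsch(x, x)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)

  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  y <- sweep(x %*% t(R), 2, c(4, -2, 7), "+")
  sp2 <- kabsch(x, y)
  expect_lt(sp2$rmsd, 1e-6)
  expect_equal(apply_superposition(x, sp2), y, tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch RMSD matches the quaternion-method oracle", {
  set.seed(32)
  for (i in 1:20) {
    x <- matrix(rnorm(15, sd = 3), ncol = 3)
    y <- matrix(rnorm(15, sd = 3), ncol = 3)
    expect_equal(kabsch(x, y)$rmsd, oracle_quaternion_rmsd(x, y),
                 tolerance = 1e-6)
  }
})

test_that("kabsch rejects degenerate geometry", {
  expect_error(kabsch(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "degenerate")
})

test_that("rmsd series are zero for static ensembles and match brute force", {
  fr <- matrix(rnorm(30, sd = 6), 10, 3)
  ens <- ensemble_from_frames(rep(list(fr), 4))
  rs <- rmsd_series(ens, fit_sel = 1:10)
  expect_equal(rs$rmsd, rep(0, 4), tolerance = 1e-10)

  set.seed(33)
  frames <- replicate(5, fr + matrix(rnorm(30, sd = 0.5), 10, 3),
                      simplify = FALSE)
  ens2 <- ensemble_from_frames(frames)
  rs2 <- rmsd_series(ens2, fit_sel = 1:6, measure_sel = 7:10)
  brute <- vapply(1:5, function(f) {
    sp <- kabsch(frames[[f]][1:6, ], frames[[1]][1:6, ])
    moved <- apply_superposition(frames[[f]][7:10, ], sp)
    sqrt(mean(rowSums((moved - frames[[1]][7:10, ])^2)))
  }, numeric(1))
  expect_equal(rs2$rmsd, brute, tolerance = 1e-10)
  # measure = fit reproduces the kabsch fit rmsd
  rs3 <- rmsd_series(ens2, fit_sel = 1:10)
  kr <- vapply(1:5, function(f)
    kabsch(frames[[f]], frames[[1]])$rmsd, numeric(1))
  expect_equal(rs3$rmsd, kr, tolerance = 1e-10)
})

test_that("rmsf is zero for a static ensemble and recovers sigma*sqrt(3)", {
  fr <- matrix(rnorm(12, sd = 5), 4, 3)
  static <- ensemble_from_frames(rep(list(fr), 6))
  expect_equal(rmsf_profile(static, 1:4, window = 1)$rmsf, rep(0, 4),
               tolerance = 1e-10)

  set.seed(34)
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(5, 5, 5))
  sigma <- 0.4
  frames <- replicate(5000, {
    fr <- base; fr[4, ] <- fr[4, ] + rnorm(3, 0, sigma); fr
  }, simplify = FALSE)
  ens <- ensemble_from_frames(frames)
  pr <- rmsf_profile(ens, 1:4, window = 1, fit_sel = 1:3)
  expect_equal(pr$rmsf[4], sigma * sqrt(3), tolerance = 0.05)
  # rigid motion of every frame changes nothing
  moved <- random_rigid_transform(ens)
  pr2 <- rmsf_profile(moved, 1:4, window = 1, fit_sel = 1:3)
  expect_equal(pr2$rmsf, pr$rmsf, tolerance = 1e-6)
})

test_that("average structure means fitted frames", {
  fr <- matrix(rnorm(15, sd = 4), 5, 3)
  static <- ensemble_from_frames(rep(list(fr), 3))
  expect_equal(average_structure(static, 1, fit_sel = 1:5), fr,
               tolerance = 1e-10)
  # two frames displaced symmetrically about a midpoint, no fitting
  d <- matrix(rnorm(15), 5, 3)
  ens <- ensemble_from_frames(list(fr + d, fr - d))
  expect_equal(average_structure(ens, 1, fit_sel = NULL), fr,
               tolerance = 1e-10)
})

test_that("angles and dihedrals match oracles and sign conventions", {
  expect_equal(vector_angle(c(1, 0, 0), c(0, 0, 0), c(-2, 0, 0)), 180)
  expect_equal(vector_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # cis arrangement -> 0
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                              c(1, 0, 1)), 0)
  set.seed(35)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(vector_angle(p[1, ], p[2, ], p[3, ]),
                 oracle_angle(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # mirror reflection flips the dihedral sign but not the angle
    m <- p; m[, 3] <- -m[, 3]
    expect_equal(dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ]),
                 -dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    expect_equal(vector_angle(m[1, ], m[2, ], m[3, ]),
                 vector_angle(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
  }
})

test_that("org geometry reproduces the planted template descriptor", {
  tpl <- fixture_template()
  for (q in c("Q1", "Q2")) {
    og <- org_geometry(tpl$ensemble, tpl$map, q, window = 1)
    expect_equal(og$avg_structure_angle, 105, tolerance = 1e-6)
    expect_equal(og$avg_structure_dihedral, 25, tolerance = 1e-6)
    expect_true(all(og$series$angle >= 0 & og$series$angle <= 180))
  }
  # angles are rigid-motion invariant
  gen <- fixture_small()
  moved <- random_rigid_transform(gen$ensemble)
  o1 <- org_geometry(gen$ensemble, gen$map, "Q1", window = 1)
  o2 <- org_geometry(moved, gen$map, "Q1", window = 1)
  expect_equal(o1$series$angle, o2$series$angle, tolerance = 1e-8)
  expect_equal(o1$series$dihedral, o2$series$dihedral, tolerance = 1e-8)
})
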