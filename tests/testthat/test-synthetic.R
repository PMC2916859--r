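# Template construction and planted-truth generation.

test_that("the template carries every mapped atom exactly once per monomer", {
  tpl <- fixture_template()
  ens <- tpl$ensemble
  for (q in names(tpl$map$quarters)) {
    qmap <- tpl$map$quarters[[q]]
    roster <- list(c(qmap$residues$lys120, "NZ"),
                   c(qmap$residues$arg280, "NH1"),
                   c(qmap$residues$arg280, "NH2"),
                   c(qmap$residues$arg248, "NE"),
                   c(qmap$residues$arg273, "NH1"),
                   c(qmap$residues$glu281, "OE1"),
                   c(qmap$residues$gly112, "CA"),
                   c(qmap$residues$ser269, "CA"))
    for (r in roster)
      expect_length(select_atoms(ens, chain_id = qmap$protein_chain,
                                 residue_number = as.integer(r[1]),
                                 atom_name = r[2]), 1)
  }
  expect_s3_class(ens, "ensemble")
  expect_equal(n_frames(ens), 1L)
})

test_that("the template starts bonded at position 2 and straight", {
  tpl <- fixture_template()
  fp <- lys120_fingerprint(tpl$ensemble, tpl$map, window = 1)
  pos2 <- fp[fp$contact == "K120-pos2-local", "occupancy"]
  expect_equal(pos2, c(100, 100))
  expect_lt(bend_angle(tpl$ensemble)$angle, 3)
  expect_error(build_template("GGGC"), "10 bases")
  expect_error(build_template("GGGCATGCCX"), "invalid character")
})

test_that("probability extremes generate all-or-nothing occupancies", {
  tpl <- fixture_template()
  all_on <- generate_ensemble(tpl, planted_truth(
    n_frames = 150, lys120 = c(1, 1, 1), arg280 = 1,
    saltbridge = c(A = 1, B = 1, C = 1, D = 1), arg248 = c(1, 1),
    seed = 71))
  fp <- lys120_fingerprint(all_on$ensemble, all_on$map, window = 1)
  contacted <- fp[fp$note == "", ]
  # bonded draws exceed the cutoff with probability < 1e-3 (documented
  # distribution leakage); at 150 frames per contact that is at most a
  # frame or two
  expect_true(all(contacted$occupancy >= 99))
  sb <- saltbridge_network(all_on$ensemble, all_on$map, window = 1)
  expect_true(all(sb$occupancy >= 99))

  all_off <- generate_ensemble(tpl, planted_truth(
    n_frames = 150, lys120 = c(0, 0, 0), arg280 = 0,
    saltbridge = c(A = 0, B = 0, C = 0, D = 0), arg248 = c(0, 0),
    seed = 72))
  fp0 <- lys120_fingerprint(all_off$ensemble, all_off$map, window = 1)
  expect_true(all(fp0$occupancy == 0))
  sb0 <- saltbridge_network(all_off$ensemble, all_off$map, window = 1)
  expect_true(all(sb0$occupancy == 0))
  r248 <- arg248_distances(all_off$ensemble, all_off$map, window = 1)
  for (q in names(r248)) for (m in names(r248[[q]]))
    expect_equal(occupancy(r248[[q]][[m]], 3.5), 0)
})

test_that("bonded/unbonded distance leakage across the cutoff is < 0.1%", {
  tpl <- fixture_template()
  gen <- generate_ensemble(tpl, planted_truth(
    n_frames = 2000, lys120 = c(1, 1, 1), arg280 = 1, seed = 73))
  fp <- lys120_fingerprint(gen$ensemble, gen$map, window = 1)
  contacted <- fp[fp$note == "", ]
  expect_true(all(contacted$occupancy >= 99.9))
})

test_that("identical seeds are bit-identical on disk, distinct seeds differ", {
  tpl <- fixture_template()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  t5 <- planted_truth(n_frames = 5, seed = 81)
  p1 <- write_ensemble_bundle(generate_ensemble(tpl, t5), d1)
  p2 <- write_ensemble_bundle(generate_ensemble(tpl, t5), d2)
  p3 <- write_ensemble_bundle(
    generate_ensemble(tpl, planted_truth(n_frames = 5, seed = 82)), d3)
  for (k in c("pdb", "mapping", "truth"))
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])))
  expect_false(identical(unname(tools::md5sum(p1[["pdb"]])),
                         unname(tools::md5sum(p3[["pdb"]]))))
})

test_that("generated bundles round-trip losslessly at PDB precision", {
  gen <- fixture_small()
  d <- withr::local_tempdir()
  paths <- write_ensemble_bundle(gen, d)
  back <- read_multimodel_pdb(paths[["pdb"]])
  expect_lt(max(abs(back$xyz - gen$ensemble$xyz)), 1e-3 + 1e-9)
  map <- read_mapping(paths[["mapping"]])
  expect_equal(names(map$quarters), names(gen$map$quarters))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$n_frames, gen$truth$n_frames)
})

test_that("invalid truth records are rejected", {
  expect_error(planted_truth(lys120 = c(0, 1.2, 0)), "probabilities")
  expect_error(planted_truth(sigma = 0), "sigma")
  expect_error(planted_truth(bonded_mean = 4), "bonded mean")
  expect_error(planted_truth(n_frames = 0), "frame")
})

test_that("coupled disruption realizes the requested joint statistics", {
  tpl <- fixture_template()
  get_series <- function(gen) {
    k <- attr(lys120_fingerprint(gen$ensemble, gen$map, window = 1),
              "series")$Q1_K120_pos2_local
    r <- arg280_contact(gen$ensemble, gen$map, window = 1)$series$Q1$min_pair
    list(k = k, r = r)
  }
  full <- coupled_disruption_scenario(tpl, p_joint = 1, n_frames = 400,
                                      seed = 91)
  s <- get_series(full)
  cc <- cooccupancy_correlation(s$k, s$r)
  # perfectly coupled: co-disruption equals the single-contact fraction
  single <- mean(s$k$distance > 3.5)
  expect_equal(cc$co_disruption_fraction, single)
  expect_equal(cc$co_disruption_fraction, full$truth$realized_co_disruption)

  indep <- coupled_disruption_scenario(tpl, p_joint = 0, n_frames = 2000,
                                       seed = 92)
  s0 <- get_series(indep)
  cc0 <- cooccupancy_correlation(s0$k, s0$r)
  # independence: joint fraction near the product of the marginals
  expect_lt(abs(cc0$co_disruption_fraction -
                  indep$truth$expected_co_disruption), 0.03)
  expect_equal(cc0$co_disruption_fraction,
               indep$truth$realized_co_disruption)
})
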