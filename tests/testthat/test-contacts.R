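# Distance series, occupancies, bond modes and contact correlation.

test_that("distance series apply the minimum-pair rule", {
  top <- simple_topology(3, atom_name = c("NZ", "O6", "N7"))
  fr <- rbind(c(0, 0, 0), c(3, 0, 0), c(5, 0, 0))
  ens <- ensemble_from_frames(list(fr, fr, fr), top)
  cd <- contact_definition("t", donor = 1L, acceptor = 2L)
  ds <- distance_series(ens, cd, window = 1)
  expect_equal(ds$distance, rep(3, 3))

  fr2 <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(0, 5, 0))
  ens2 <- ensemble_from_frames(list(fr2), top)
  cd2 <- contact_definition("t2", donor = 1L, acceptor = c(2L, 3L))
  expect_equal(distance_series(ens2, cd2, window = 1)$distance, 2.8)
})

test_that("distance series equal the brute-force all-pairs oracle", {
  set.seed(5)
  top <- simple_topology(6)
  frames <- replicate(10, matrix(rnorm(18, sd = 4), 6, 3), simplify = FALSE)
  ens <- ensemble_from_frames(frames, top)
  cd <- contact_definition("r", donor = c(1L, 2L), acceptor = c(4L, 5L, 6L))
  ds <- distance_series(ens, cd, window = 1)
  expect_equal(ds$distance, oracle_min_dist(ens, c(1, 2), 4:6, 1:10))
})

test_that("occupancy handles boundaries, emptiness and the <= rule", {
  expect_equal(occupancy(rep(2.9, 10), 3.5), 100)
  expect_equal(occupancy(rep(4.2, 10), 3.5), 0)
  expect_equal(occupancy(c(3.5, 3.5001), 3.5), 50)  # boundary counts bonded
  expect_equal(occupancy(c(3.5, 3.6), 3.5, boundary = "<"), 0)
  expect_error(occupancy(numeric(0), 3.5), "empty")
})

test_that("occupancy is monotone non-decreasing in the cutoff", {
  set.seed(8)
  d <- runif(500, 2, 7)
  cuts <- seq(2, 7, by = 0.25)
  occ <- vapply(cuts, function(ct) occupancy(d, ct), numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("occupancy is invariant under global rigid motion", {
  gen <- fixture_small()
  moved <- random_rigid_transform(gen$ensemble)
  for (e in list(gen$ensemble, moved)) {
    fp <- lys120_fingerprint(e, gen$map, window = 1)
    if (!exists("ref_fp", inherits = FALSE)) ref_fp <- fp$occupancy
    expect_equal(fp$occupancy, ref_fp)
  }
  sb1 <- saltbridge_network(gen$ensemble, gen$map, window = 1)
  sb2 <- saltbridge_network(moved, gen$map, window = 1)
  expect_equal(sb1$occupancy, sb2$occupancy)
})

test_that("pipeline occupancies equal brute-force counts on small fixtures", {
  gen <- fixture_small()
  ens <- gen$ensemble; map <- gen$map
  qmap <- map$quarters$Q1
  nz <- select_atoms(ens, chain_id = "C", residue_number = 120,
                     atom_name = "NZ")
  site <- qmap$positions$p2$local
  acc <- select_atoms(ens, chain_id = site$chain,
                      residue_number = site$resno,
                      atom_name = major_groove_acceptors(site$base))
  brute <- oracle_occupancy(oracle_min_dist(ens, nz, acc, 1:20), 3.5)
  fp <- lys120_fingerprint(ens, map, window = 1)
  expect_identical(
    fp$occupancy[fp$quarter == "Q1" & fp$contact == "K120-pos2-local"],
    brute)
})

test_that("bond modes follow the three-centered / two-centered rules", {
  expect_equal(classify_mode(c(O6 = 2.8, N7 = 3.1), "G"), "three_centered")
  expect_equal(classify_mode(c(O6 = 2.8, N7 = 4.0), "G"), "two_centered")
  expect_equal(classify_mode(c(O4 = 3.0), "T"), "two_centered")
  expect_equal(classify_mode(c(N7 = 4.2), "A"), "none")
  expect_equal(classify_mode(c(N7 = 3.5), "A"), "two_centered")
  expect_error(classify_mode(c(N7 = 3.0), "X"), "unknown base")
})

test_that("cytosine rows are emitted as zero with an annotation", {
  gen <- fixture_small()
  fp <- lys120_fingerprint(gen$ensemble, gen$map, window = 1)
  crows <- fp[fp$base == "C", ]
  expect_true(nrow(crows) > 0)
  expect_true(all(crows$occupancy == 0))
  expect_true(all(grepl("no major-groove acceptor", crows$note)))
})

test_that("contact correlation reports r and co-disruption", {
  a <- c(3, 4, 5, 3, 6)
  expect_equal(cooccupancy_correlation(a, a)$pearson_r, 1)
  expect_equal(cooccupancy_correlation(a, -a + 9)$pearson_r, -1)
  cc <- cooccupancy_correlation(a, a, cutoff = 3.5)
  expect_equal(cc$co_disruption_fraction, 3 / 5)
  z <- cooccupancy_correlation(rep(4, 5), a)
  expect_true(is.na(z$pearson_r))
  expect_equal(z$co_disruption_fraction, 3 / 5)
  expect_error(cooccupancy_correlation(a, a[-1]), "equal length")
})

test_that("mapping registration errors name the offending contact", {
  gen <- fixture_small()
  map <- gen$map
  map$quarters$Q1$positions$p2$local$base <- "A"  # contradicts topology G
  expect_error(lys120_fingerprint(gen$ensemble, map, window = 1),
               "registration error")
  map2 <- gen$map
  map2$quarters$Q1$residues$lys120 <- 999
  expect_error(lys120_fingerprint(gen$ensemble, map2, window = 1),
               "mapping error")
})
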