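# Shared fixtures, built in code and cached across test files (the
# 2000-frame recovery ensemble is the expensive one).

.fixtures <- new.env(parent = emptyenv())

# Minimal topology for hand-built ensembles.
simple_topology <- function(n, atom_name = "CA", chain = "A") {
  data.frame(serial = seq_len(n), atom_name = atom_name,
             residue_name = "ALA", residue_number = seq_len(n),
             chain_id = chain, element = substr(atom_name, 1, 1),
             stringsAsFactors = FALSE)
}

# Ensemble from a list of natoms x 3 coordinate matrices.
ensemble_from_frames <- function(frames, topology = NULL) {
  if (is.null(topology)) topology <- simple_topology(nrow(frames[[1]]))
  xyz <- t(vapply(frames, function(fr) as.numeric(t(fr)),
                  numeric(3 * nrow(frames[[1]]))))
  ensemble(topology, xyz)
}

fixture_template <- function() {
  if (is.null(.fixtures$tpl)) .fixtures$tpl <- build_template()
  .fixtures$tpl
}

# Recovery ensemble: planted probabilities spanning {0, 0.15, 0.5, 0.87,
# 1.0} across the Lys120/Arg280 contacts and a published-shaped
# salt-bridge row; 2000 frames.
recovery_truth <- function() {
  planted_truth(
    n_frames = 2000,
    lys120 = list(Q1 = c(0, 0.15, 0.5), Q2 = c(1.0, 0.87, 0)),
    arg280 = list(Q1 = 0.87, Q2 = 1.0),
    saltbridge = list(Q1 = c(A = 1.0, B = 0.0, C = 0.96, D = 0.91),
                      Q2 = c(A = 0.5, B = 0.15, C = 0.87, D = 0.0)),
    arg248 = c(0.8, 0.3),
    seed = 42)
}

fixture_recovery <- function() {
  if (is.null(.fixtures$recovery))
    .fixtures$recovery <- generate_ensemble(fixture_template(),
                                            recovery_truth())
  .fixtures$recovery
}

# Small generated ensemble with default truth (20 frames) for oracle
# equality and I/O tests.
fixture_small <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generate_ensemble(
      fixture_template(), planted_truth(n_frames = 20, seed = 7))
  .fixtures$small
}
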