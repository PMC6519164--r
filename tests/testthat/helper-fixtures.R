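# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# short sequence for operator-level tests
fix_seq_short <- function(nt = 40) {
  sequence_params(mrf_flip_angle_schedule(nt, n_lobes = 2, peak_deg = 60))
}

# small motion-free brain simulation (matrix 64, Nt 300)
fix_sim_small <- function() {
  fixture("sim_small", function() {
    seqp <- sequence_params(mrf_flip_angle_schedule(300, n_lobes = 5))
    maps <- brain_phantom(64, 320)
    traj <- golden_radial(300, 64, 64)
    coils <- simulate_coil_maps(4, 64)
    vals <- unique(data.frame(t1 = maps$t1_ms[maps$mask], t2 = maps$t2_ms[maps$mask]))
    dict <- build_dictionary(sort(unique(vals$t1)), sort(unique(vals$t2)),
                             seqp, slice_profile(5))
    kd <- simulate_mrf_kspace(maps, seqp, dict, traj, coils, NULL)
    list(seq = seqp, maps = maps, traj = traj, coils = coils, dict = dict,
         cdict = compress_dictionary(dict, 5), kdata = kd)
  })
}

parametric_maps_for_tests <- function() {
  structure(list(t1_ms = matrix(runif(64, 300, 2000), 8),
                 t2_ms = matrix(runif(64, 20, 200), 8),
                 m0_magnitude = matrix(runif(64), 8),
                 match_correlation = matrix(runif(64), 8)),
            class = "parametric_maps")
}
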