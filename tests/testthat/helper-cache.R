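# Heavy simulations shared between property and acceptance tests are run
# once per session and cached.  Seeds are fixed so the suite is
# deterministic.

.hd_test_cache <- new.env(parent = emptyenv())

.cached <- function(key, fn) {
  if (!exists(key, envir = .hd_test_cache))
    assign(key, fn(), envir = .hd_test_cache)
  get(key, envir = .hd_test_cache)
}

cached_scene <- function() .cached("scene", default_scene)

# Default-protocol dose curve: levels 1e2..1e5, 20 replicates ("dozens of
# times"), ~15 s.
cached_curve <- function() .cached("curve", function() {
  simulate_dose_curve(cached_scene(), c(100, 1000, 1e4, 1e5),
                      replicates = 20, seed = 1)
})

cached_fits <- function() .cached("fits", function() {
  fit_all_fingers(cached_curve()$points)
})

# High-statistics merged tally (4e6 decays) for the exposure-ordering
# significance check; ~25 s.
cached_big_tally <- function() .cached("big_tally", function() {
  set.seed(101)
  merge_tallies(lapply(1:4, function(i)
    run_histories(1e6, cached_scene())))
})
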