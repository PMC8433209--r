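# Shared fixtures, all generated in code. Expensive objects (the 64 px
# benchmark and a trained network) are memoised so several test files can
# reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

ref_geom <- function() cell_geometry()          # 35 um oocyte, vb 0.19
ref_cpa <- function() cpa_properties("EG")
ref_params <- function() membrane_params(0.8, 0.25)

# trajectory of the reference 1.5 M EG step, 61 samples over 600 s
ref_trajectory <- function() memo("ref_traj", {
  simulate_2p(ref_params(), ref_geom(), perfusion_env(m_cpa = 1.5),
              ref_cpa(), seq(0, 600, by = 10))
})

# small-canvas benchmark for network tests (declared scale-down of the
# 256 px benchmark; same generator)
bench64 <- function() memo("bench64", {
  make_benchmark(seed = 11, n_train = 200, n_val = 25, image_size = 64,
                 noise_sigma = 10)
})

trained_net64 <- function() memo("net64", {
  net <- build_network(net_spec(depth = 2, base_filters = 8,
                                input_size = 64), seed = 1)
  train_network(net, bench64()$train, bench64()$val, epochs = 10,
                seed = 2, lr = 2e-3)
})

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.eps)), tol)
}
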