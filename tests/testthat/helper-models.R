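# Shared fixtures, built once per test run.  Model construction is cheap
# (milliseconds); simulations are cached because several test files reuse
# the same runs.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

sym_model <- function() cached("sym_model", lung_model())

asym_model <- function(area = 4, f_c = 1.75)
  cached(sprintf("asym_%d_%s", area, f_c),
         lung_model(asymmetry = asymmetry_spec(area, f_c)))

# full-protocol symmetric run (50 breaths)
sym_run_200 <- function() cached("sym_run_200", {
  simulate_washout(assemble(sym_model()), snapshot_times = c(2, 4))
})

# one asymmetric run with lung-unit snapshots
asym_run <- function(area = 4, f_c = 1.75, duration = 200) {
  key <- sprintf("run_%d_%s_%s", area, f_c, duration)
  cached(key, {
    m <- asym_model(area, f_c)
    part <- partition_lung_units(m)
    res <- simulate_washout(
      assemble(m), duration = duration,
      snapshot_times = c(2, lu_sample_times(part, m$pattern$T, duration)))
    list(model = m, partition = part, result = res,
         report = washout_report(res, part))
  })
}

# hand-built two-node transport system (volumes V, one link of resistance R,
# optional flows), for closed-form oracles
two_compartment_system <- function(V = 1, R = 2, Q = 0, T_breath = 4) {
  structure(list(
    ids = c("A", "B"), parent = c(0L, 1L),
    G = c(0, 1 / R), Q_in = c(Q, Q), Q_alv = c(0, Q),
    V_base = c(V, V), inlet = c(insp = 0, exp = 0),
    T = T_breath, Q_hat = Q, duration = T_breath,
    model = NULL), class = "transport_system")
}
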