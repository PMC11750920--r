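# Tracer transport on the AU network, in the electrical RC-network form:
# compartment volume = capacitance, diffusive link = resistor, convective
# transport = upwind-switched controlled current sources, inlet = voltage
# source behind a blocking resistor.

#' Tracer/carrier gas pair
#'
#' @param name Gas-pair label.
#' @param D Binary molecular diffusion coefficient in cm^2/s.
#' @return A `gas` object.
#' @export
gas <- function(name, D) {
  stopifnot(is.finite(D), D > 0)
  structure(list(name = name, D = D), class = "gas")
}

#' Helium tracer in nitrogen carrier (D = 0.6 cm^2/s)
#' @rdname gas
#' @export
gas_he_n2 <- function() gas("He-N2", 0.6)

#' Rectangular breathing pattern
#'
#' Flow magnitude is constant within each half-period: the first half of
#' every breath is inspiration (positive flow), the second expiration.
#'
#' @param T_breath Breath period in s.
#' @param Q_hat Peak tracheal flow magnitude in cm^3/s.
#' @param duration Total simulated time in s.
#' @return A `breathing_pattern` object; tidal volume is
#'   `Q_hat * T_breath / 2` (500 ml with the defaults).
#' @export
breathing_pattern <- function(T_breath = 4, Q_hat = 250, duration = 200) {
  stopifnot(T_breath > 0, Q_hat >= 0, duration > 0)
  structure(list(T = T_breath, Q_hat = Q_hat, duration = duration,
                 V_T = Q_hat * T_breath / 2),
            class = "breathing_pattern")
}

#' Assemble the tracer-transport system
#'
#' Extracts from a fully built model the arrays the integrator needs:
#' parent wiring, diffusive link conductances (the inlet link carries the
#' blocking resistance), peak entrance flows, peak alveolar flows and
#' end-expiratory volumes, plus the inlet boundary mole fractions per
#' breathing phase (pure tracer during inspiration, pure carrier during
#' expiration).
#'
#' @param model A `lung_model` with flows and resistances computed.
#' @param gas Gas pair; defaults to the model's.
#' @param pattern Breathing pattern; defaults to the model's.
#' @return A `transport_system` object.
#' @export
assemble <- function(model, gas = model$gas, pattern = model$pattern) {
  stopifnot(inherits(model, "lung_model"))
  if (is.null(model$aus$Q_in) || is.null(model$aus$R_D))
    stop("compute flows and resistances before assembling")
  if (!is.null(gas) && !identical(gas$D, model$gas$D)) {
    model <- peclet(diffusive_resistances(model, gas$D))
    model$gas <- gas
  }
  aus <- model$aus
  if (any(aus$parent[-1] < 1L)) stop("disconnected AU in the network")
  structure(list(
    ids = aus$id,
    parent = aus$parent,          # 1-based, 0 = inlet node
    G = 1 / aus$R_D,              # diffusive conductances, cm^3/s
    Q_in = aus$Q_in,              # peak entrance flows (magnitudes)
    Q_alv = aus$Q_alv,            # peak alveolar flows (magnitudes)
    V_base = aus$V,               # end-expiratory volumes
    inlet = c(insp = 1, exp = 0), # boundary tracer mole fractions
    T = pattern$T, Q_hat = pattern$Q_hat, duration = pattern$duration,
    model = model),
    class = "transport_system")
}

#' Integrate the washout
#'
#' Fixed-step explicit integration of the expanded balance
#' `V dchi/dt = in - out - chi dV/dt`, with upwind convective fluxes, Fick
#' diffusive fluxes on every link and linear within-phase volume ramps of
#' the alveolated AUs.  The default scheme is Heun's explicit trapezoidal
#' rule (second order); plain explicit Euler is available as
#' `scheme = "euler"`.  Flow reversals fall exactly on step boundaries (the
#' half-period must be an integer number of steps), and each step is
#' integrated entirely inside one smooth phase segment, so the scheme keeps
#' its order across the rectangular-flow switches.  The run aborts with a
#' diagnostic if any mole fraction leaves `[0, 1]` by more than `tol`,
#' which indicates an unstable step size.
#'
#' @param system A `transport_system` from [assemble()].
#' @param duration Simulated time in s (defaults to the pattern's).
#' @param dt Step size in s.
#' @param snapshot_times Times at which the full per-AU state (mole
#'   fractions and volumes) is recorded.
#' @param chi0 Initial tracer mole fraction per AU (default 0 everywhere:
#'   the lung starts filled with pure carrier gas).
#' @param scheme `"heun"` (default) or `"euler"`.
#' @param tol Out-of-bounds tolerance for the stability guard.
#' @return A `simulation_result`: mouth-trace time grid and tracer mole
#'   fraction at the first TU compartment, total tracer volume and
#'   cumulative boundary influx on the same grid, plus the requested state
#'   snapshots.
#' @export
simulate_washout <- function(system, duration = system$duration, dt = 5e-4,
                             snapshot_times = numeric(0), chi0 = NULL,
                             scheme = c("heun", "euler"), tol = 1e-6) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(system, "transport_system"))
  n <- length(system$parent)
  if (is.null(chi0)) chi0 <- numeric(n)
  stopifnot(length(chi0) == n)
  half <- system$T / 2
  sph <- round(half / dt)
  if (sph < 1 || abs(sph * dt - half) > 1e-9 * half)
    stop("step size must divide the half-period so flow switches land on steps")
  # startup guard: dt must resolve the fastest RC times of the network
  # (per-node loss rate = entrance flow plus all attached link conductances)
  loss <- system$G
  for (i in seq_along(system$parent)[-1])
    loss[system$parent[i]] <- loss[system$parent[i]] + system$G[i]
  rate <- (abs(system$Q_in) + loss) / system$V_base
  if (dt * max(rate) >= 2)
    stop(sprintf(
      "dt = %g exceeds the explicit stability bound (max rate %.3g 1/s)",
      dt, max(rate)))
  out <- euler_washout(as.integer(system$parent) - 1L, as.numeric(system$G),
                       as.numeric(system$Q_in), as.numeric(system$Q_alv),
                       as.numeric(system$V_base), as.numeric(system$T),
                       as.numeric(system$inlet[["insp"]]),
                       as.numeric(system$inlet[["exp"]]),
                       as.numeric(duration), as.numeric(dt),
                       as.numeric(chi0), as.numeric(snapshot_times),
                       as.numeric(tol), if (scheme == "heun") 2L else 1L)
  structure(list(
    time = out$time, mouth = out$mouth,
    mass = out$mass, boundary = out$boundary,
    snapshot_times = snapshot_times,
    chi = out$chi, V = out$V,        # one row per snapshot time, one col per AU
    dt = dt, T = system$T, duration = duration,
    scheme = if (scheme == "heun") "explicit Heun (expanded form)"
             else "explicit Euler (expanded form)",
    system = system),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Washout simulation: %.0f s at dt = %g s (%d AUs, %s)\n",
    x$duration, x$dt, length(x$system$parent), x$scheme))
  cat(sprintf("  breaths: %d, end-tidal N2: %.4f\n",
              floor(x$duration / x$T), 1 - x$mouth[length(x$mouth)]))
  invisible(x)
}

#' Write simulation output as CSV
#'
#' `write_mouth_csv` writes the compact mouth trace (time, tracer and
#' carrier mole fractions, flow direction); `write_state_csv` writes the
#' long-format per-AU snapshots.
#'
#' @param result A `simulation_result`.
#' @param path Output file.
#' @param every Keep every `every`-th mouth sample.
#' @return The path, invisibly.
#' @export
write_mouth_csv <- function(result, path, every = 10L) {
  idx <- seq(1L, length(result$time), by = every)
  t <- result$time[idx]
  phase_in_breath <- t %% result$T
  utils::write.csv(data.frame(
    time_s = t,
    chi_He = result$mouth[idx],
    chi_N2 = 1 - result$mouth[idx],
    flow_direction = ifelse(phase_in_breath < result$T / 2, "insp", "exp")),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mouth_csv
#' @export
write_state_csv <- function(result, path) {
  if (!length(result$snapshot_times)) stop("no snapshots recorded")
  long <- do.call(rbind, lapply(seq_along(result$snapshot_times), function(k) {
    data.frame(time_s = result$snapshot_times[k],
               au_id = result$system$ids,
               chi_He = result$chi[k, ],
               volume_ml = result$V[k, ])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
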