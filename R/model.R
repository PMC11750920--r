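# Network construction: trachea unit (TU) + branched segment unit (SU).
#
# The SU is split into 6 areas a = 0..5, area a holding 2^a parallel elements
# (AEs).  Each element is a serial chain of m_AU(a) airway units (AUs); one AU
# lumps the 2^(z-a) anatomically identical airways of global generation z that
# fall into its element.  The TU (generations 0-3) is a serial tube of n_tu
# identical AUs.  Total AU count with the default layout: 10 + 1 + 20 + 4 + 8
# + 16 + 192 = 251.

#' Area layout of the segment unit
#'
#' @param m_AU Integer vector of AUs per element for areas 0-5.  The default
#'   `c(1, 10, 1, 1, 1, 6)` maps area 0 to generation 4, area 1 to 5-14,
#'   areas 2-4 to 15-17 and area 5 to 18-23.
#' @return An object of class `area_layout`.
#' @export
area_layout <- function(m_AU = c(1L, 10L, 1L, 1L, 1L, 6L)) {
  m_AU <- as.integer(m_AU)
  if (length(m_AU) != 6L || any(m_AU < 1L))
    stop("layout needs 6 positive per-area AU counts")
  if (sum(m_AU) != 20L)
    stop("per-area AU counts must cover the 20 generations 4-23")
  structure(list(m_AU = m_AU), class = "area_layout")
}

#' Global generation of an AU position
#'
#' Maps area `a` and within-element position `zp` to the global airway
#' generation: `4 + zp + sum(m_AU[areas < a])`.
#'
#' @param a Area index 0-5.
#' @param zp Position within the element, `0 <= zp < m_AU(a)`.
#' @param layout Area layout.
#' @return Integer generation index.
#' @export
generation_of <- function(a, zp, layout = area_layout()) {
  off <- c(0L, cumsum(layout$m_AU))
  as.integer(4L + zp + off[a + 1L])
}

#' Build the symmetric lung network
#'
#' Wires the trachea unit and the branched segment unit from a scaled
#' morphometry table.  All per-AU quantities are per element: an SU AU's
#' volume, cross-section and alveolar count aggregate the `2^(z-a)` parallel
#' airways of its generation that belong to its element.
#'
#' @param scaled Scaled morphometry table (generations 0-23).
#' @param d_alv Alveolar diameter in cm.
#' @param layout Area layout, see [area_layout()].
#' @param n_tu Number of serial TU compartments (default 10; fewer increase
#'   numerical smearing of the inspired front).
#' @return A `lung_model` object.
#' @export
build_symmetric <- function(scaled, d_alv, layout = area_layout(),
                            n_tu = 10L) {
  scaled <- .check_weibel(scaled)
  if (!identical(scaled$z, 0:23))
    stop("scaled table must cover generations 0-23")
  n_tu <- as.integer(n_tu)
  stopifnot(n_tu >= 1L)
  v_alv1 <- pi / 6 * d_alv^3
  m_AU <- layout$m_AU

  # trachea unit: n_tu identical serial compartments
  tu_idx <- scaled$z <= 3
  V03 <- sum(2^scaled$z[tu_idx] * pi / 4 *
               scaled$d_cm[tu_idx]^2 * scaled$l_cm[tu_idx])
  l_tu <- sum(scaled$l_cm[tu_idx]) / n_tu
  V_tu <- V03 / n_tu
  A_tu <- V_tu / l_tu

  n_su <- sum(2^(0:5) * m_AU)
  n <- n_tu + n_su
  aus <- data.frame(
    id = character(n), unit = character(n),
    a = NA_integer_, e = NA_integer_, zp = NA_integer_, z = NA_integer_,
    l = NA_real_, A = NA_real_, d = NA_real_,
    V_air = NA_real_, V_alv = NA_real_, V = NA_real_,
    m_alv = NA_real_, f_tot = 1, parent = NA_integer_, x = NA_real_,
    stringsAsFactors = FALSE)

  aus$id[1:n_tu] <- paste0("TU-", seq_len(n_tu))
  aus$unit[1:n_tu] <- "TU"
  aus$l[1:n_tu] <- l_tu
  aus$A[1:n_tu] <- A_tu
  aus$d[1:n_tu] <- sqrt(4 * A_tu / pi)
  aus$V_air[1:n_tu] <- V_tu
  aus$V_alv[1:n_tu] <- 0
  aus$V[1:n_tu] <- V_tu
  aus$m_alv[1:n_tu] <- 0
  aus$parent[1:n_tu] <- 0:(n_tu - 1L)          # 0 = model inlet
  aus$x[1:n_tu] <- seq_len(n_tu) * l_tu

  # segment unit, ordered area-major, element-major, chain position last
  row <- n_tu
  first_of <- matrix(NA_integer_, nrow = 6, ncol = 32)  # row index of (a,e,zp=0)
  for (a in 0:5) {
    for (e in 0:(2^a - 1L)) {
      for (zp in 0:(m_AU[a + 1L] - 1L)) {
        row <- row + 1L
        z <- generation_of(a, zp, layout)
        n_aw <- 2^(z - a)
        d_s <- scaled$d_cm[scaled$z == z]
        l_s <- scaled$l_cm[scaled$z == z]
        m_alv <- n_aw * scaled$m_alv_air[scaled$z == z]
        V_air <- n_aw * pi / 4 * d_s^2 * l_s
        A <- V_air / l_s
        aus$id[row] <- sprintf("SU-(%d,%d,%d)", a, e, zp)
        aus$unit[row] <- "SU"
        aus$a[row] <- a; aus$e[row] <- e; aus$zp[row] <- zp; aus$z[row] <- z
        aus$l[row] <- l_s
        aus$A[row] <- A
        aus$d[row] <- sqrt(4 * A / pi)  # equivalent bundle diameter
        aus$V_air[row] <- V_air
        aus$V_alv[row] <- m_alv * v_alv1
        aus$V[row] <- V_air + aus$V_alv[row]
        aus$m_alv[row] <- m_alv
        if (zp == 0L) first_of[a + 1L, e + 1L] <- row
        aus$parent[row] <-
          if (zp > 0L) row - 1L
          else if (a == 0L) n_tu
          else first_of[a, e %/% 2L + 1L] + m_AU[a] - 1L
      }
    }
  }

  model <- structure(list(aus = aus, layout = layout, n_tu = n_tu,
                          d_alv = d_alv, asymmetry = NULL,
                          pattern = NULL, gas = NULL),
                     class = "lung_model")
  model$aus$x <- .axial_positions(model)
  model
}

# Cumulative axial coordinate: TU compartments at k * l_TU; the SU chain is
# anchored at the exit of the (n_tu - 1)'th TU compartment and advances by
# midpoint-to-midpoint distances 0.5 * (l_parent + l_own).  Reporting-only.
.axial_positions <- function(model) {
  aus <- model$aus
  x <- numeric(nrow(aus))
  for (i in seq_len(nrow(aus))) {
    p <- aus$parent[i]
    if (aus$unit[i] == "TU") {
      x[i] <- i * aus$l[i]
    } else if (p <= model$n_tu && aus$unit[p] == "TU") {
      x[i] <- x[p] - 0.5 * aus$l[p] + 0.5 * aus$l[i]
    } else {
      x[i] <- x[p] + 0.5 * (aus$l[p] + aus$l[i])
    }
  }
  x
}

#' Asymmetry specification
#'
#' Volume factors applied at one area `a*`: even elements of the area get
#' `f_c`, odd elements `2 - f_c` (sibling pairs always sum to 2, conserving
#' the total lung volume); every descendant element inherits its ancestor's
#' factor.  `f_c = 1` reproduces the symmetric model.
#'
#' @param area Area where the asymmetry is applied, 1-5.
#' @param f_c Volume factor in (0, 2).
#' @return An `asymmetry_spec` object.
#' @export
asymmetry_spec <- function(area, f_c) {
  area <- as.integer(area)
  if (is.na(area) || area < 1L || area > 5L)
    stop("asymmetry area must be in 1..5")
  if (!is.finite(f_c) || f_c <= 0 || f_c >= 2)
    stop("asymmetry factor must lie strictly between 0 and 2")
  structure(list(area = area, f_c = f_c), class = "asymmetry_spec")
}

#' Transform a symmetric model into an asymmetric one
#'
#' Scales each AU by its inherited factor product `f_tot`: volumes and
#' alveolar counts by `f_tot`, lengths by `f_tot^(1/3)`, cross-sections by
#' `f_tot^(2/3)`.  The total lung volume is unchanged because sibling
#' factors sum to 2.  Flows, resistances and Peclet numbers are recomputed
#' if the input model carried them.
#'
#' @param model A `lung_model`.
#' @param spec An [asymmetry_spec()].
#' @return The transformed `lung_model`.
#' @export
apply_asymmetry <- function(model, spec) {
  stopifnot(inherits(model, "lung_model"), inherits(spec, "asymmetry_spec"))
  aus <- model$aus
  f_tot <- rep(1, nrow(aus))
  sel <- aus$unit == "SU" & aus$a >= spec$area
  e_star <- aus$e[sel] %/% 2L^(aus$a[sel] - spec$area)
  f_tot[sel] <- ifelse(e_star %% 2L == 0L, spec$f_c, 2 - spec$f_c)

  aus$f_tot <- f_tot
  aus$V_air <- aus$V_air * f_tot
  aus$V_alv <- aus$V_alv * f_tot
  aus$V <- aus$V * f_tot
  aus$m_alv <- aus$m_alv * f_tot
  aus$l <- aus$l * f_tot^(1 / 3)
  aus$A <- aus$A * f_tot^(2 / 3)
  aus$d <- aus$d * f_tot^(1 / 3)
  model$aus <- aus
  model$asymmetry <- spec
  model$aus$x <- .axial_positions(model)
  if (!is.null(model$pattern)) model <- compute_flows(model, model$pattern)
  if (!is.null(model$gas)) {
    model <- diffusive_resistances(model, model$gas$D)
    model <- peclet(model)
    if (!is.null(model$aus$tau_D)) model <- time_constants(model)
  }
  model
}

#' Peak convective flows of every AU
#'
#' The rectangular tracheal flow is generated by the synchronous volume
#' change of all alveoli: each alveolus contributes
#' `Q_alv = Q_hat_TU / total alveoli`; an AU's alveolar peak flow is
#' `m_alv * Q_alv` and its entrance flow `Q_in` is the sum of the alveolar
#' flows of its whole subtree (itself included).
#'
#' @param model A `lung_model`.
#' @param pattern A [breathing_pattern()].
#' @return The model with columns `Q_alv` and `Q_in` added (cm^3/s, peak
#'   magnitudes).
#' @export
compute_flows <- function(model, pattern = breathing_pattern()) {
  stopifnot(inherits(model, "lung_model"))
  aus <- model$aus
  M_tot <- sum(aus$m_alv)
  if (M_tot <= 0) stop("degenerate model: no alveoli")
  Q_alv <- aus$m_alv * pattern$Q_hat / M_tot
  Q_in <- Q_alv
  for (i in rev(seq_len(nrow(aus)))) {      # children come after parents
    p <- aus$parent[i]
    if (p > 0L) Q_in[p] <- Q_in[p] + Q_in[i]
  }
  model$aus$Q_alv <- Q_alv
  model$aus$Q_in <- Q_in
  model$pattern <- pattern
  model
}

#' Diffusive link resistances
#'
#' Each non-root AU `N` owns the resistance of the link to its parent `M`:
#' `R_D = 0.5 * (l_N + l_M) / (D * A_N)` with `A_N` the AU's own per-element
#' cross-section.  Within the TU the half-lengths collapse to `l_TU`.  The
#' model-inlet link of the first TU compartment is overridden with the
#' blocking value 1e100 s/cm^3 so the stepwise inlet concentration cannot
#' diffuse into the mouth signal; its geometric half-length is kept
#' separately for the Peclet number.
#'
#' @param model A `lung_model` with flows computed.
#' @param D Binary molecular diffusion coefficient in cm^2/s.
#' @param blocking Inlet-link resistance override in s/cm^3.
#' @return The model with columns `delta` (link half-length sum, cm) and
#'   `R_D` (s/cm^3) added.
#' @export
diffusive_resistances <- function(model, D = 0.6, blocking = 1e100) {
  stopifnot(inherits(model, "lung_model"), D > 0)
  aus <- model$aus
  l_parent <- ifelse(aus$parent > 0L, aus$l[pmax(aus$parent, 1L)], aus$l)
  delta <- 0.5 * (aus$l + l_parent)
  R_D <- delta / (D * aus$A)
  R_D[1] <- blocking
  model$aus$delta <- delta
  model$aus$R_D <- R_D
  model$gas <- gas(if (!is.null(model$gas)) model$gas$name else "He-N2", D)
  model
}

#' Entrance Peclet numbers
#'
#' `Pe = Q_in * 0.5 * (l_N + l_M) / (D * A_N)`: the ratio of peak convective
#' to diffusive transport at each AU entrance.  `Pe = 1` marks the
#' transition between the convection- and diffusion-dominated zones.
#'
#' @param model A `lung_model` with flows and resistances computed.
#' @return The model with a `Pe` column added.
#' @export
peclet <- function(model) {
  stopifnot(inherits(model, "lung_model"))
  if (is.null(model$aus$Q_in) || is.null(model$aus$delta))
    stop("compute flows and resistances first")
  model$aus$Pe <- model$aus$Q_in * model$aus$delta / (model$gas$D * model$aus$A)
  model
}

#' First diffusion-dominated generation
#'
#' Walks one root-to-tip path (element 0 throughout) and returns the first
#' global generation whose entrance Peclet number falls below 1, or
#' `NA_integer_` if convection dominates everywhere.
#'
#' @param model A `lung_model` with Peclet numbers computed.
#' @return Integer generation index or `NA`.
#' @export
transition_generation <- function(model) {
  stopifnot(!is.null(model$aus$Pe))
  path <- model$aus[model$aus$unit == "SU" & model$aus$e == 0L, ]
  path <- path[order(path$z), ]
  hit <- which(path$Pe < 1)
  if (!length(hit)) return(NA_integer_)
  path$z[hit[1]]
}

#' Diffusive and convective time constants
#'
#' RC products of the network: `tau_D = R_D * V` and `tau_c = V / Q_in`
#' (end-expiratory volumes).  Under an asymmetry `tau_c` is invariant
#' because volume and flow are factorized identically, while `tau_D` scales
#' with `f_tot^(2/3)` times a mixed-length bracket of the two link ends.
#'
#' @param model A `lung_model` with flows and resistances computed.
#' @return The model with `tau_D` and `tau_c` columns (s).
#' @export
time_constants <- function(model) {
  stopifnot(!is.null(model$aus$R_D), !is.null(model$aus$Q_in))
  model$aus$tau_D <- model$aus$R_D * model$aus$V
  model$aus$tau_c <- model$aus$V / model$aus$Q_in
  model
}

#' Partition the model into lung units around an asymmetry area
#'
#' `LU0` is the shared proximal region (TU plus all areas above `area`);
#' `LU1` collects the subtrees rooted at the even elements of `area` and
#' `LU2` those at the odd elements.  `dt_LU0 = V_LU0 / Q_hat_TU` is the
#' convective transit time through the shared region.
#'
#' @param model A `lung_model`.
#' @param area Area at which the partition splits, 1-5.  Defaults to the
#'   model's asymmetry area.
#' @return A `lu_partition` object with per-AU labels, `V_LU0` (cm^3) and
#'   `dt_LU0` (s).
#' @export
partition_lung_units <- function(model, area = NULL) {
  stopifnot(inherits(model, "lung_model"))
  if (is.null(area)) {
    if (is.null(model$asymmetry)) stop("no asymmetry area to partition at")
    area <- model$asymmetry$area
  }
  area <- as.integer(area)
  stopifnot(area >= 1L, area <= 5L)
  aus <- model$aus
  label <- rep("LU0", nrow(aus))
  sel <- aus$unit == "SU" & aus$a >= area
  e_star <- aus$e[sel] %/% 2L^(aus$a[sel] - area)
  label[sel] <- ifelse(e_star %% 2L == 0L, "LU1", "LU2")
  V_LU0 <- sum(aus$V[label == "LU0"])
  Q <- if (!is.null(model$pattern)) model$pattern$Q_hat else 250
  structure(list(area = area, label = label, V_LU0 = V_LU0,
                 dt_LU0 = V_LU0 / Q),
            class = "lu_partition")
}

#' Total and dead-space volumes of a model
#'
#' @param model A `lung_model`.
#' @return A list with `V_total` (ml), `V_dead` (TU plus the non-alveolated
#'   SU areas 0-3, ml) and `dt_dead` (dead-space transit time at the model's
#'   breathing pattern, s).
#' @export
lung_volumes <- function(model) {
  stopifnot(inherits(model, "lung_model"))
  aus <- model$aus
  dead <- aus$unit == "TU" | aus$a <= 3L
  Q <- if (!is.null(model$pattern)) model$pattern$Q_hat else 250
  list(V_total = sum(aus$V), V_dead = sum(aus$V[dead]),
       dt_dead = sum(aus$V[dead]) / Q)
}

#' Build a complete lung model in one call
#'
#' Runs the full construction pipeline: alveolar diameter and scaling from
#' the morphometry table to the target volume, symmetric network assembly,
#' optional asymmetry, peak flows, diffusive resistances and Peclet numbers.
#'
#' @param V_L Target (end-expiratory) lung volume in ml.
#' @param asymmetry `NULL` for the symmetric model or an [asymmetry_spec()].
#' @param gas Tracer/carrier gas pair, see [gas()].
#' @param pattern Breathing pattern, see [breathing_pattern()].
#' @param table Base morphometry table at the reference volume.
#' @param layout Area layout.
#' @param n_tu Number of serial TU compartments.
#' @return A `lung_model` with all derived columns populated.
#' @export
#' @examples
#' m <- lung_model()
#' lung_volumes(m)
lung_model <- function(V_L = 3000, asymmetry = NULL, gas = gas_he_n2(),
                       pattern = breathing_pattern(), table = weibel_table(),
                       layout = area_layout(), n_tu = 10L) {
  d_alv <- alveolar_diameter(V_L)
  V_LW <- unscaled_total_volume(table, d_alv)
  deficit <- V_LW - V_L
  s <- scaling_factor(table, deficit)
  model <- build_symmetric(scaled_table(table, s), d_alv, layout, n_tu)
  model$s <- s
  model$V_LW <- V_LW
  model$V_L <- V_L
  model <- compute_flows(model, pattern)
  model <- diffusive_resistances(model, gas$D)
  model$gas <- gas
  model <- peclet(model)
  model <- time_constants(model)
  if (!is.null(asymmetry)) model <- apply_asymmetry(model, asymmetry)
  model
}

#' @export
print.lung_model <- function(x, ...) {
  vol <- lung_volumes(x)
  cat("Lung model:", nrow(x$aus), "airway units (",
      x$n_tu, "TU +", nrow(x$aus) - x$n_tu, "SU )\n")
  cat(sprintf("  total volume %.1f ml, dead space %.1f ml\n",
              vol$V_total, vol$V_dead))
  if (!is.null(x$s))
    cat(sprintf("  scaling factor s = %.4f, d_alv = %.1f um\n",
                x$s, 1e4 * x$d_alv))
  if (is.null(x$asymmetry)) cat("  symmetric\n")
  else cat(sprintf("  asymmetric: area %d, f_c = %.2f\n",
                   x$asymmetry$area, x$asymmetry$f_c))
  if (!is.null(x$aus$Pe)) {
    tg <- transition_generation(x)
    cat("  Pe = 1 transition at generation", tg, "\n")
  }
  invisible(x)
}

#' Export the model as JSON
#'
#' One record per AU with geometry, inherited factor, wiring, link
#' resistance and peak entrance flow.
#'
#' @param model A `lung_model`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_model_json <- function(model, path) {
  stopifnot(inherits(model, "lung_model"))
  aus <- model$aus
  keep <- intersect(c("id", "unit", "a", "e", "zp", "z", "l", "A", "d",
                      "V_air", "V_alv", "V", "m_alv", "f_tot", "parent",
                      "x", "Q_alv", "Q_in", "delta", "R_D", "Pe"),
                    names(aus))
  obj <- list(
    n_tu = model$n_tu,
    scaling_factor = model$s,
    d_alv_cm = model$d_alv,
    asymmetry = if (is.null(model$asymmetry)) NULL else
      list(area = model$asymmetry$area, f_c = model$asymmetry$f_c),
    aus = aus[, keep])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
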