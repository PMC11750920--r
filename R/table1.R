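# Reference per-element geometry, flows, Peclet numbers and diffusional
# resistances of the symmetric He-N2 model (D = 0.6 cm^2/s), used as a
# regression surface for the model builder.  `l` and `x` in cm, `A` in
# cm^2, `Q` in cm^3/s, `R_D` in s/cm^3.  The TU row lists the per-
# compartment values; the inlet link carries the blocking resistance.
.table1_reference <- function() {
  su <- data.frame(
    z = 4:23,
    a = c(0L, rep(1L, 10L), 2L, 3L, 4L, rep(5L, 6L)),
    l = c(1.161, 0.980, 0.827, 0.697, 0.588, 0.496, 0.419, 0.353, 0.298,
          0.251, 0.212, 0.179, 0.151, 0.127, 0.107, 0.091, 0.077, 0.065,
          0.054, 0.046),
    x = c(19.06, 20.13, 21.03, 21.79, 22.43, 22.98, 23.43, 23.82, 24.15,
          24.42, 24.65, 24.85, 25.01, 25.15, 25.27, 25.37, 25.45, 25.52,
          25.58, 25.63),
    A = c(2.094, 1.304, 1.665, 2.181, 2.928, 4.030, 5.687, 8.229, 12.207,
          18.567, 28.953, 23.145, 18.970, 15.941, 13.735, 24.265, 43.952,
          81.624, 155.416, 303.400),
    Q = c(250, rep(125, 10), 62.5, 31.25, 15.625, 7.795, 7.740, 7.576,
          7.027, 5.929, 3.733),
    Pe = c(309.074, 171.045, 112.990, 72.800, 45.749, 28.041, 16.763,
           9.774, 5.559, 3.083, 1.668, 0.880, 0.453, 0.227, 0.111, 0.053,
           0.024, 0.010, 0.004, 0.001),
    R_D = c(1.24, 1.37, 9.04e-1, 5.82e-1, 3.66e-1, 2.24e-1, 1.34e-1,
            7.82e-2, 4.45e-2, 2.47e-2, 1.33e-2, 1.41e-2, 1.45e-2, 1.46e-2,
            1.43e-2, 6.81e-3, 3.17e-3, 1.44e-3, 6.38e-4, 2.76e-4))
  tu <- data.frame(z = NA_integer_, a = NA_integer_, l = 1.945, x = NA_real_,
                   A = 2.43525, Q = 250, Pe = 332.780, R_D = 1.33)
  list(tu = tu, su = su, inlet_R = 1e100)
}

#' Reproduce the reference per-element table
#'
#' Recomputes length, axial position, cross-section, peak entrance flow,
#' Peclet number and diffusional resistance for the TU and for every
#' generation along one root-to-tip path of the symmetric He-N2 model, and
#' compares them with the embedded reference values.  Printed reference
#' values are rounded, so each comparison uses the larger of `tol`
#' (relative) and half a unit in the last printed digit.
#'
#' @param model Optional prebuilt symmetric `lung_model`; the default
#'   builds one.
#' @param tol Relative tolerance (default 1 %).
#' @param path Optional CSV output mirroring the reference columns.
#' @return A data.frame with computed and reference columns and a logical
#'   `pass` per row/quantity; overall result in `attr(, "pass")`.
#' @export
reproduce_table1 <- function(model = NULL, tol = 0.01, path = NULL) {
  if (is.null(model)) model <- lung_model()
  stopifnot(is.null(model$asymmetry))
  ref <- .table1_reference()
  aus <- model$aus

  path_aus <- aus[aus$unit == "SU" & aus$e == 0L, ]
  path_aus <- path_aus[order(path_aus$z), ]
  cmp <- data.frame(
    row = c("TU", sprintf("z=%d", path_aus$z)),
    l = c(aus$l[2], path_aus$l),
    x = c(NA, path_aus$x),
    A = c(aus$A[2], path_aus$A),
    Q = c(aus$Q_in[1], path_aus$Q_in),
    Pe = c(aus$Pe[1], path_aus$Pe),
    R_D = c(aus$R_D[2], path_aus$R_D))
  ref_all <- rbind(ref$tu[, c("l", "x", "A", "Q", "Pe", "R_D")],
                   ref$su[, c("l", "x", "A", "Q", "Pe", "R_D")])

  half_ulp <- function(x) {
    # half a unit in the last printed decimal of the reference value
    s <- format(x, scientific = FALSE, trim = TRUE)
    dec <- ifelse(grepl("\\.", s), nchar(sub(".*\\.", "", s)), 0L)
    0.5 * 10^(-dec)
  }
  out <- cmp
  for (q in c("l", "x", "A", "Q", "Pe", "R_D")) {
    refv <- ref_all[[q]]
    band <- pmax(tol * abs(refv), half_ulp(refv))
    out[[paste0(q, "_ref")]] <- refv
    out[[paste0(q, "_pass")]] <- is.na(refv) | abs(cmp[[q]] - refv) <= band
  }
  out$inlet_R <- c(aus$R_D[1], rep(NA, nrow(path_aus)))
  pass <- all(unlist(out[grep("_pass$", names(out))]), na.rm = TRUE) &&
    aus$R_D[1] >= 1e99
  attr(out, "pass") <- pass
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
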