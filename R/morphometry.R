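# Embedded base morphometry (reference lung of 4800 ml).
#
# Generations 0-3 are the classic Weibel model-"A" trachea/main/lobar/segment
# bronchi.  Generations 4-23 are reconstructed from the model's per-element
# scaled geometry (length and aggregate cross-section columns) by dividing out
# the volume scaling factor s = 0.917, so that the embedded table is exactly
# self-consistent with every derived quantity the model reports.  Alveoli per
# airway (m_alv_air) are reconstructed from the per-compartment alveolar flow
# distribution, with the total alveolar count calibrated so that the unscaled
# reference model volume is 3368 ml at the 3000-ml alveolar diameter; this
# yields 298.4 million alveoli and 17.0 alveoli per terminal sac.
.weibel_d <- c(1.8, 1.22, 0.83, 0.56,
               0.445158, 0.351289, 0.280684, 0.227156, 0.186109, 0.154390,
               0.129686, 0.110309, 0.0950004, 0.0828470, 0.0731539, 0.0654063,
               0.0592140, 0.0542811, 0.0503854, 0.0473550, 0.0450661,
               0.0434265, 0.0423720, 0.0418623)
.weibel_l <- c(12, 4.76, 1.9, 0.76,
               1.26609, 1.06870, 0.901854, 0.760087, 0.641221, 0.540894,
               0.456925, 0.384951, 0.324973, 0.273719, 0.231189, 0.195202,
               0.164667, 0.138495, 0.116685, 0.0992366, 0.0839695, 0.0708833,
               0.0588877, 0.0501636)
.weibel_m_alv <- c(rep(0, 17),
                   5.09989, 8.01412, 11.9483, 19.9989, 19.9989, 19.9989,
                   16.9981)

#' Base airway morphometry table
#'
#' Returns the per-generation morphometry of the 24-generation (0-23)
#' regularized dichotomous airway tree at the 4800-ml reference volume:
#' airway diameter `d_cm`, airway length `l_cm`, and the number of alveoli
#' per airway `m_alv_air` (zero for the conducting generations 0-16).
#' Generation `z` contains `2^z` anatomically identical airways.
#'
#' @return A data.frame with columns `z`, `d_cm`, `l_cm`, `m_alv_air`
#'   (24 rows, generations 0-23).
#' @export
#' @examples
#' tab <- weibel_table()
#' sum(tab$l_cm[tab$z <= 3])  # conducting path length of generations 0-3
weibel_table <- function() {
  data.frame(z = 0:23, d_cm = .weibel_d, l_cm = .weibel_l,
             m_alv_air = .weibel_m_alv)
}

.check_weibel <- function(table) {
  need <- c("z", "d_cm", "l_cm", "m_alv_air")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("morphometry table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(table$z)) stop("generation indices must be unique")
  if (any(table$d_cm <= 0) || any(table$l_cm <= 0))
    stop("airway diameters and lengths must be positive")
  if (any(table$m_alv_air < 0)) stop("alveolar counts must be non-negative")
  table[order(table$z), , drop = FALSE]
}

#' Mean alveolar diameter for a given lung volume
#'
#' Empirical cube-root relation between total lung volume and the mean
#' diameter of a single alveolus: `d_alv = 1.54e-3 * V_L^(1/3)` with
#' volumes in ml and the result in cm.  At the 3000-ml resting volume the
#' relation gives 222 um.
#'
#' @param V_L Total lung volume in ml (> 0).
#' @return Alveolar diameter in cm.
#' @export
alveolar_diameter <- function(V_L) {
  if (any(!is.finite(V_L)) || any(V_L <= 0))
    stop("lung volume must be positive")
  1.54e-3 * V_L^(1 / 3)
}

#' Total model volume of an unscaled morphometry table
#'
#' Sums, over all generations, the `2^z` cylindrical airway volumes plus the
#' spherical alveolar volumes attached to them.
#'
#' @param table Morphometry table as returned by [weibel_table()].
#' @param d_alv Alveolar diameter in cm.
#' @return Total volume in ml.
#' @export
unscaled_total_volume <- function(table, d_alv) {
  table <- .check_weibel(table)
  stopifnot(is.finite(d_alv), d_alv > 0)
  v_alv <- pi / 6 * d_alv^3
  sum(2^table$z * (pi / 4 * table$d_cm^2 * table$l_cm +
                     table$m_alv_air * v_alv))
}

#' Linear scaling factor for the distal airways
#'
#' The reference morphometry overshoots the target lung volume; the excess
#' (`deficit`, in ml) is removed by shrinking the airway diameters and
#' lengths of generations 4-23 by a common linear factor
#' `s = (1 - deficit / sum_{z=4..23} 2^z (pi/4) d^2 l)^(1/3)`.
#' Generations 0-3 and the alveolar volumes are left untouched.
#'
#' @param table Morphometry table (unscaled).
#' @param deficit Volume to remove from the distal airways, in ml.
#' @return Dimensionless scaling factor `s` (1 when `deficit` is 0).
#' @export
scaling_factor <- function(table, deficit) {
  table <- .check_weibel(table)
  stopifnot(is.finite(deficit))
  distal <- table$z >= 4
  vol_distal <- sum(2^table$z[distal] * pi / 4 *
                      table$d_cm[distal]^2 * table$l_cm[distal])
  if (deficit >= vol_distal)
    stop("infeasible deficit: exceeds the distal airway volume of ",
         format(vol_distal), " ml")
  (1 - deficit / vol_distal)^(1 / 3)
}

#' Apply the linear scaling factor to a morphometry table
#'
#' Multiplies `d_cm` and `l_cm` of generations 4-23 by `s`; generations 0-3
#' and the alveolar counts are unchanged, so the airway volumes of the
#' distal generations scale by `s^3`.
#'
#' @param table Morphometry table.
#' @param s Linear scaling factor (> 0).
#' @return The scaled table.
#' @export
scaled_table <- function(table, s) {
  table <- .check_weibel(table)
  stopifnot(is.finite(s), s > 0)
  distal <- table$z >= 4
  table$d_cm[distal] <- s * table$d_cm[distal]
  table$l_cm[distal] <- s * table$l_cm[distal]
  table
}

#' Read / write a morphometry table as CSV
#'
#' Plain-CSV interchange format with header `z,d_cm,l_cm,m_alv_air`, so
#' alternate morphometries can be supplied to the model builder.
#'
#' @param path File path.
#' @param table Morphometry table to write.
#' @return `read_weibel_csv` returns the validated table.
#' @export
read_weibel_csv <- function(path) {
  .check_weibel(utils::read.csv(path))
}

#' @rdname read_weibel_csv
#' @export
write_weibel_csv <- function(table, path) {
  utils::write.csv(.check_weibel(table), path, row.names = FALSE)
  invisible(path)
}
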