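#' Export the transport system as a SPICE-dialect netlist
#'
#' One capacitor per AU (value: end-expiratory volume), one resistor per
#' diffusive link (value: link resistance; the inlet link carries the
#' blocking resistance), five phase-switched voltage-controlled current
#' sources per AU for the convective transfers (inflow from the parent,
#' outflow to the parent, and one per child in each direction), and the
#' inlet voltage source driving the boundary mole fraction.  Node names
#' carry the AU labels.
#'
#' @param system A `transport_system` from [assemble()].
#' @param path Optional output file; when `NULL` the netlist is returned as
#'   a character vector of lines.
#' @return The lines invisibly (and written to `path` if given).
#' @export
export_netlist <- function(system, path = NULL) {
  stopifnot(inherits(system, "transport_system"))
  n <- length(system$parent)
  node <- gsub("[^A-Za-z0-9]", "_", system$ids)
  pnode <- ifelse(system$parent > 0L, node[pmax(system$parent, 1L)], "INLET")
  fmt <- function(x) trimws(formatC(x, digits = 6, format = "g"))

  lines <- c(
    "* compartmental washout network (RC electrical analogy)",
    sprintf("* %d airway units, breath period %g s, peak flow %g cm3/s",
            n, system$T, system$Q_hat),
    "* units: V ~ mole fraction, C ~ cm3, R ~ s/cm3, I ~ cm3/s",
    sprintf("Vinlet INLET 0 PULSE(%g %g 0 0 0 %g %g)",
            system$inlet[["insp"]], system$inlet[["exp"]],
            system$T / 2, system$T))
  for (i in seq_len(n)) {
    lines <- c(lines,
               sprintf("C_%s %s 0 %s", node[i], node[i], fmt(system$V_base[i])))
  }
  for (i in seq_len(n)) {
    lines <- c(lines,
               sprintf("R_%s %s %s %s", node[i], pnode[i], node[i],
                       fmt(1 / system$G[i])))
  }
  for (i in seq_len(n)) {
    kids <- which(system$parent == i)
    # convective sources: gain = peak flow, switched by breathing phase
    lines <- c(
      lines,
      sprintf("Gin_%s 0 %s %s 0 %s  * inspiration: carries parent fraction",
              node[i], node[i], pnode[i], fmt(system$Q_in[i])),
      sprintf("Gout_%s %s 0 %s 0 %s  * expiration: drains own fraction",
              node[i], node[i], node[i], fmt(system$Q_in[i])))
    for (k in kids) {
      lines <- c(
        lines,
        sprintf("Gcin_%s_%s 0 %s %s 0 %s  * expiration: receives child",
                node[i], node[k], node[i], node[k], fmt(system$Q_in[k])))
    }
    if (length(kids)) {
      # one lumped source drains the AU toward its children on inspiration
      lines <- c(
        lines,
        sprintf("Gcout_%s %s 0 %s 0 %s  * inspiration: feeds children",
                node[i], node[i], node[i], fmt(sum(system$Q_in[kids]))))
    }
  }
  lines <- c(lines, ".end")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
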