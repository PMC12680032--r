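#' Single-cell density from buoyant mass and volume
#'
#' A cell of volume \eqn{V} immersed in a fluid of density
#' \eqn{\rho_{fluid}} has buoyant mass
#' \eqn{m_b = V(\rho - \rho_{fluid}) = m(1 - \rho_{fluid}/\rho)},
#' so its density is \eqn{\rho = \rho_{fluid} + m_b / V}. Units are fixed:
#' pg for mass, um^3 for volume, g/cm^3 for density, using the identity
#' 1 pg/um^3 = 1 g/cm^3. The default fluid density is that of the
#' dextran-supplemented measurement buffer, 1.005 g/cm^3.
#'
#' @param buoyant_mass Buoyant mass in pg (may be negative for cells less
#'   dense than the fluid).
#' @param volume Cell volume in um^3, strictly positive.
#' @param fluid_density Fluid density in g/cm^3 (default 1.005).
#' @return Cell density in g/cm^3.
#' @seealso [total_mass()], [density_table()]
#' @export
#' @examples
#' cell_density(50, 1000)        # 1.055 g/cm^3
#' cell_density(0, 1000)         # neutrally buoyant: fluid density
cell_density <- function(buoyant_mass, volume, fluid_density = 1.005) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be finite and positive", call. = FALSE)
  }
  if (any(fluid_density <= 0)) {
    stop("fluid_density must be positive", call. = FALSE)
  }
  fluid_density + buoyant_mass / volume
}

#' Total cell mass from density and volume
#'
#' @param density Cell density in g/cm^3, strictly positive.
#' @param volume Cell volume in um^3, strictly positive.
#' @return Total mass \eqn{m = \rho V} in pg.
#' @export
total_mass <- function(density, volume) {
  if (any(!is.finite(density)) || any(density <= 0)) {
    stop("density must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("volume must be finite and positive", call. = FALSE)
  }
  density * volume
}

#' Buoyant mass from total mass and density
#'
#' Inverse relation \eqn{m_b = m (1 - \rho_{fluid}/\rho)}; used to check
#' the density round trip.
#'
#' @param mass Total mass in pg.
#' @param density Cell density in g/cm^3.
#' @param fluid_density Fluid density in g/cm^3 (default 1.005).
#' @return Buoyant mass in pg.
#' @export
buoyant_mass <- function(mass, density, fluid_density = 1.005) {
  if (any(density <= 0)) stop("density must be positive", call. = FALSE)
  mass * (1 - fluid_density / density)
}

#' Median/IQR summary of a measurement distribution
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the convention is recorded in the output so
#' downstream tables are self-describing.
#'
#' @param values Numeric vector of measurements (n >= 1, finite).
#' @return A list of class `distribution_summary` with `n`, `median`, `q1`,
#'   `q3`, `iqr` and `quantile_type`.
#' @export
summarize_masses <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop("cannot summarize an empty vector", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 iqr = q[3] - q[1], quantile_type = 7L),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("n = %d; median = %.4g; IQR = %.4g [q1 = %.4g, q3 = %.4g]\n",
              x$n, x$median, x$iqr, x$q1, x$q3))
  invisible(x)
}

#' Per-cell density table from an SMR event table
#'
#' Applies [cell_density()] and [total_mass()] to every event row that
#' carries a volume.
#'
#' @param events An `smr_events` table with a `volume` column.
#' @param fluid_density Fluid density in g/cm^3 (default 1.005).
#' @return A data frame with columns `cell_id`, `buoyant_mass_pg`,
#'   `volume_um3`, `fluid_density`, `cell_density`, `total_mass_pg`.
#' @export
density_table <- function(events, fluid_density = 1.005) {
  if (!"volume" %in% names(events)) {
    stop("events table has no volume column; density requires volume",
         call. = FALSE)
  }
  keep <- !is.na(events$volume)
  ev <- events[keep, , drop = FALSE]
  rho <- cell_density(ev$buoyant_mass, ev$volume, fluid_density)
  data.frame(cell_id = ev$cell_id,
             buoyant_mass_pg = ev$buoyant_mass,
             volume_um3 = ev$volume,
             fluid_density = fluid_density,
             cell_density = rho,
             total_mass_pg = total_mass(rho, ev$volume),
             row.names = NULL)
}
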