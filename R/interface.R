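## Electrode-electrolyte interface physics. The double layer of a metal
## microelectrode in electrolyte is modeled as a constant-phase-angle
## (CPA) pseudocapacitance Z_CPA = K (j w)^(-beta) in parallel with an
## overpotential-independent charge-transfer resistance
## R_CT = R T / (n F I0); both are expressed per unit area, giving the
## surface admittance y = g + j b (S/m^2) that enters the Robin boundary
## condition -sigma dphi/dn = y (phi - phi_metal).

#' Constant-phase-angle parameters
#'
#' @param K CPA magnitude in Ohm m^2 s^-beta (default 1.57, platinum-type
#'   microelectrode).
#' @param beta phase exponent in `(0, 1]` (default 0.91); `beta = 1` is an
#'   ideal capacitor with C = 1/K per area.
#' @return object of class `cpa_params`.
#' @export
cpa_params <- function(K = 1.57, beta = 0.91) {
  stopifnot(K > 0, beta > 0, beta <= 1)
  structure(list(K = K, beta = beta), class = "cpa_params")
}

#' Charge-transfer parameters
#'
#' Defaults: body temperature, two electrons per molecule, exchange
#' current density 0.1 A/m^2 (platinum-order). The printed interface
#' impedances of typical recording microelectrodes are CPA-dominated and
#' insensitive to these values.
#'
#' @param T_kelvin temperature (K).
#' @param n electrons per molecule.
#' @param j0 exchange current density (A/m^2).
#' @return object of class `charge_transfer_params`.
#' @export
charge_transfer_params <- function(T_kelvin = 310, n = 2, j0 = 0.1) {
  stopifnot(T_kelvin > 0, n > 0, j0 > 0)
  structure(list(R = 8.314, T_kelvin = T_kelvin, n = n, F = 96485,
                 j0 = j0), class = "charge_transfer_params")
}

#' Electrode-electrolyte interface model
#'
#' @param mode `"parallel"` (CPA and charge transfer in parallel, the
#'   pseudocapacitive interface), `"nonfaradaic"` (CPA alone, infinite
#'   transfer resistance) or `"faradaic"` (charge transfer alone, purely
#'   resistive).
#' @param cpa a [cpa_params()].
#' @param ct a [charge_transfer_params()].
#' @param fixed_frequency optional frequency (Hz): the "equivalent RC"
#'   variant. The parallel network is reduced to a resistance and a
#'   capacitance at this frequency; the returned admittance then follows
#'   that fixed RC network, whose capacitive reactance still varies with
#'   frequency.
#' @return object of class `interface_model`.
#' @export
interface_model <- function(mode = c("parallel", "nonfaradaic", "faradaic"),
                            cpa = cpa_params(), ct = charge_transfer_params(),
                            fixed_frequency = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("parallel", "nonfaradaic") && is.null(cpa))
    stop("mode '", mode, "' requires cpa parameters")
  if (mode %in% c("parallel", "faradaic") && is.null(ct))
    stop("mode '", mode, "' requires charge-transfer parameters")
  if (!is.null(fixed_frequency)) stopifnot(fixed_frequency > 0)
  structure(list(mode = mode, cpa = cpa, ct = ct,
                 fixed_frequency = fixed_frequency),
            class = "interface_model")
}

#' CPA interface impedance per unit area
#'
#' `Z_CPA = K (j w)^(-beta)`: magnitude `K w^-beta`, constant phase
#' `-beta pi / 2`.
#'
#' @param cpa a [cpa_params()].
#' @param f frequency (Hz), strictly positive (the CPA element diverges at
#'   DC; DC paths must use the faradaic branch).
#' @return complex impedance-area (Ohm m^2), vectorized over `f`.
#' @export
cpa_impedance_area <- function(cpa, f) {
  stopifnot(inherits(cpa, "cpa_params"))
  if (any(f <= 0))
    stop("CPA impedance diverges at f = 0; use the faradaic/DC path")
  w <- 2 * pi * f
  cpa$K * w^(-cpa$beta) * exp(-1i * pi * cpa$beta / 2)
}

#' Charge-transfer resistance per unit area
#'
#' `R_CT = R T / (n F j0)` with `j0` the exchange current density, i.e.
#' the per-area form of the exchange current.
#'
#' @param ct a [charge_transfer_params()].
#' @return resistance-area in Ohm m^2.
#' @export
charge_transfer_resistance_area <- function(ct = charge_transfer_params()) {
  stopifnot(inherits(ct, "charge_transfer_params"))
  ct$R * ct$T_kelvin / (ct$n * ct$F * ct$j0)
}

#' Interface surface admittance y = g + j b
#'
#' Per-area admittance of the interface network at frequency `f`:
#' parallel mode `1/Z_CPA + 1/R_CT`, nonfaradaic `1/Z_CPA`, faradaic
#' `1/R_CT` (real). With `fixed_frequency` set, the parallel network is
#' first reduced at that frequency to an equivalent parallel R-C
#' (`1/R = Re y(f0)`, `C = Im y(f0) / w0`), and the result is
#' `1/R + j w C` at the requested `f`.
#'
#' @param model an [interface_model()].
#' @param f frequency (Hz), vectorized. `f = 0` is allowed only when a
#'   faradaic path exists (faradaic mode, parallel mode, or fixed-frequency
#'   RC), where the DC admittance is the conductive branch alone.
#' @return complex surface admittance (S/m^2).
#' @export
surface_admittance <- function(model, f) {
  stopifnot(inherits(model, "interface_model"))
  f <- as.numeric(f)
  gct <- if (!is.null(model$ct)) 1 / charge_transfer_resistance_area(model$ct)
         else 0
  if (!is.null(model$fixed_frequency)) {
    y0 <- surface_admittance(
      interface_model(model$mode, model$cpa, model$ct), model$fixed_frequency)
    gg <- Re(y0); cc <- Im(y0) / (2 * pi * model$fixed_frequency)
    return(complex(real = gg, imaginary = 2 * pi * f * cc))
  }
  switch(model$mode,
    faradaic = complex(real = rep(gct, length(f)), imaginary = 0),
    nonfaradaic = {
      if (any(f <= 0)) stop("nonfaradaic interface has no DC path (f = 0)")
      1 / cpa_impedance_area(model$cpa, f)
    },
    parallel = {
      y <- complex(real = rep(gct, length(f)), imaginary = 0)
      pos <- f > 0
      y[pos] <- y[pos] + 1 / cpa_impedance_area(model$cpa, f[pos])
      y
    })
}

#' Lumped electrode interface impedance
#'
#' `Z = 1 / (area * y(f))` for an electrode of the given wetted surface
#' area.
#'
#' @param model an [interface_model()].
#' @param area electrode surface area (m^2).
#' @param f frequency (Hz).
#' @return complex impedance (Ohm), vectorized over `f`.
#' @export
electrode_impedance <- function(model, area, f) {
  stopifnot(area > 0)
  1 / (area * surface_admittance(model, f))
}

#' Lateral (slant) surface area of a cone
#'
#' For conical recording electrodes bonded to a substrate: the wetted
#' surface is the lateral area `pi r sqrt(r^2 + h^2)` (base excluded).
#'
#' @param base_diameter cone base diameter (m).
#' @param height cone height (m).
#' @return area (m^2).
#' @export
cone_lateral_area <- function(base_diameter, height) {
  stopifnot(base_diameter >= 0, height >= 0)
  r <- base_diameter / 2
  pi * r * sqrt(r^2 + height^2)
}
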