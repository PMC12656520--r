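# Michel-Kaufmann (1973) calibration of PEG-6000 osmotic solutions.
# Their regression gives the water potential of a solution in bars as a
# polynomial in PEG concentration C (g per litre of water) and temperature
# T (degC):
#   psi[bar] = -1.18e-2 C - 1.18e-4 C^2 + 2.67e-4 C T + 8.39e-7 C^2 T
# Potentials are returned in MPa (1 MPa = 10 bar).

mk_coef <- c(c1 = -1.18e-2, c2 = -1.18e-4, ct1 = 2.67e-4, ct2 = 8.39e-7)

#' Water potential of a PEG-6000 solution
#'
#' Evaluates the Michel-Kaufmann polynomial for the osmotic potential of
#' polyethylene glycol 6000 dissolved in water.
#'
#' @param concentration grams of PEG-6000 per litre of water (>= 0);
#'   vectorized.
#' @param temperature solution temperature in degC, within 0-50; vectorized
#'   (recycled against \code{concentration}).
#' @return Water potential in MPa (<= 0 over the calibrated range).
#' @examples
#' peg_potential(119.6, 25)  # about -0.2 MPa
#' @export
peg_potential <- function(concentration, temperature) {
  if (any(concentration < 0)) abort_data("concentration must be >= 0 g/L")
  if (any(temperature < 0 | temperature > 50)) {
    abort_data("temperature outside the calibrated range 0-50 degC")
  }
  C <- concentration
  T <- temperature
  bar <- mk_coef[["c1"]] * C + mk_coef[["c2"]] * C^2 +
    mk_coef[["ct1"]] * C * T + mk_coef[["ct2"]] * C^2 * T
  bar / 10
}

#' PEG-6000 concentration producing a target water potential
#'
#' Inverts the Michel-Kaufmann polynomial by bracketed root-finding on
#' [0, 600] g/L, to an accuracy of 1e-9 MPa in the achieved potential.
#' Outside that bracket (potentials more negative than the calibration
#' supports at the given temperature) the function errors rather than
#' extrapolates.
#'
#' @param psi target water potential in MPa (<= 0); vectorized.
#' @param temperature solution temperature in degC; vectorized (recycled).
#' @return Concentration in g PEG-6000 per litre of water.
#' @examples
#' peg_concentration(-0.2, 25)  # about 119.6 g/L
#' @export
peg_concentration <- function(psi, temperature) {
  if (any(psi > 0)) abort_data("psi must be <= 0 MPa")
  n <- max(length(psi), length(temperature))
  psi <- rep_len(psi, n)
  temperature <- rep_len(temperature, n)
  vapply(seq_len(n), function(i) {
    if (psi[i] == 0) return(0)
    f <- function(C) peg_potential(C, temperature[i]) - psi[i]
    lo <- f(0)
    hi <- f(600)
    if (sign(lo) == sign(hi)) {
      abort_convergence(sprintf(
        "no PEG concentration in [0, 600] g/L gives %g MPa at %g degC",
        psi[i], temperature[i]))
    }
    stats::uniroot(f, c(0, 600), tol = 1e-12)$root
  }, 0)
}

#' Grid of PEG-6000 concentrations over water potentials and temperatures
#'
#' Tabulates [peg_concentration()] over a grid, the layout used to prepare
#' osmotic solutions for a temperature x water-potential germination trial
#' (temperatures as rows, potentials as columns).
#'
#' @param psi water potentials in MPa (<= 0).
#' @param temperature temperatures in degC.
#' @return Numeric matrix (g/L) with temperatures as rows and potentials as
#'   columns, dimnames set accordingly.
#' @examples
#' peg_table(c(-0.2, -0.4), c(20, 25))
#' @export
peg_table <- function(psi, temperature) {
  if (any(psi > 0)) abort_data("psi must be <= 0 MPa")
  m <- outer(temperature, psi,
             function(tt, pp) peg_concentration(pp, tt))
  dimnames(m) <- list(temperature = as.character(temperature),
                      psi_MPa = as.character(psi))
  m
}
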