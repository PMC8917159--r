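# Internal unit system: length in um, time in ms, pressure in Pa.
# Derived: velocity um/ms (= mm/s), viscosity Pa*ms, 2D flux um^2/ms (per unit depth).

#' Unit conversion helpers
#'
#' The package works internally in micrometres, milliseconds and pascals, so
#' velocities are in um/ms (numerically equal to mm/s) and dynamic viscosities
#' in Pa*ms. These helpers convert the field's customary units into and out of
#' that system.
#'
#' @param x numeric vector of values to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mmHg_to_Pa(4.8)      # physiological network pressure drop
#' Pa_to_dyn_cm2(4)     # WSS conversion, 1 Pa = 10 dyn/cm^2
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322387415

#' @rdname units
#' @export
Pa_to_dyn_cm2 <- function(x) x * 10

#' @rdname units
#' @export
dyn_cm2_to_Pa <- function(x) x / 10

#' @rdname units
#' @export
Pa_s_to_model <- function(x) x * 1000 # Pa*s -> Pa*ms

#' @rdname units
#' @export
nL_s_to_um3_ms <- function(x) x * 1000 # 1 nL/s = 1e6 um^3 / 1e3 ms

#' Per-unit-depth flux for the 2D flow core
#'
#' A volumetric flow rate in nL/s is mapped to the plane-flow flux (um^2/ms)
#' by dividing by an effective out-of-plane depth, taken as the vessel
#' diameter of the port where the condition is imposed.
#'
#' @param q_nl_s volumetric flow rate in nL/s.
#' @param depth_um effective depth in um (normally the port diameter).
#' @return flux per unit depth in um^2/ms.
#' @export
nL_s_to_flux2d <- function(q_nl_s, depth_um) nL_s_to_um3_ms(q_nl_s) / depth_um

# default fluid / membrane constants (model units)
.rbc_const <- list(
  mu_plasma = 1.2,   # 0.0012 Pa*s
  mu_interior = 6.0, # 0.006 Pa*s
  rho = 1e-3,        # 1000 kg/m^3 in Pa*ms^2/um^2
  Gs_normal = 5.0,   # 5e-6 N/m = 5 Pa*um
  kappa_b = 0.2      # 2e-19 J = 0.2 Pa*um^3
)
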