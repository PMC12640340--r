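#' Bilayer model for protein-loaded liposome SAXS
#'
#' Parameter container for the scattering model of a unilamellar bilayer
#' with embedded protein plus a small core-shell micelle population:
#' tail (hydrophobic half-layer) length `L_t`, headgroup length `L_h`,
#' protein volume fraction `x`, interface roughness `R`, lamellar and
#' micellar scales `C1`, `C2` and a constant background `B`.
#'
#' @param L_t tail (hydrophobic half-layer) length [Angstrom]
#' @param L_h headgroup layer length [Angstrom]
#' @param x protein volume fraction in the bilayer, in \[0, 1\]
#' @param R interface roughness [Angstrom], applied as exp(-R^2 q^2) damping
#' @param C1 lamellar scale (arbitrary units)
#' @param C2 micelle scale (arbitrary units)
#' @param B constant background (units of I(q))
#' @param slds fixed component SLDs, an [sld_set()]
#' @return Object of class `bilayer_model`.
#' @examples
#' m <- bilayer_model(L_t = 14.3, L_h = 6.65, x = 0.03, R = 5.37)
#' @export
bilayer_model <- function(L_t = 14.3, L_h = 6.65, x = 0, R = 0,
                          C1 = 1, C2 = 0, B = 0, slds = sld_set()) {
  stopifnot(inherits(slds, "sld_set"))
  if (L_t <= 0 || L_h <= 0) stop("L_t and L_h must be positive", call. = FALSE)
  if (x < 0 || x > 1) stop("x must lie in [0, 1]", call. = FALSE)
  if (R < 0) stop("roughness R must be non-negative", call. = FALSE)
  if (C1 < 0 || C2 < 0) stop("scales C1, C2 must be non-negative", call. = FALSE)
  structure(list(L_t = L_t, L_h = L_h, x = x, R = R,
                 C1 = C1, C2 = C2, B = B, slds = slds),
            class = "bilayer_model")
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat("Bilayer model:\n")
  cat(sprintf("  L_t = %.3f A, L_h = %.3f A, x = %.4g, R = %.3f A\n",
              x$L_t, x$L_h, x$x, x$R))
  cat(sprintf("  C1 = %.4g, C2 = %.4g, B = %.4g\n", x$C1, x$C2, x$B))
  invisible(x)
}

#' Lamellar (flat bilayer sheet) scattering intensity
#'
#' Thin-sheet intensity of a symmetric three-slab bilayer with effective
#' inner/outer contrasts set by the protein fraction:
#' \deqn{I_{lam}(q) = \frac{4\pi}{q^4 (L_h + L_t)}
#'   \left(\Delta\rho_o\,(\sin(q(L_h+L_t)) - \sin(q L_t)) +
#'         \Delta\rho_i \sin(q L_t)\right)^2}
#' This is a per-unit-area sheet intensity: the overall vesicle radius does
#' not enter, and the curve diverges as \eqn{q^{-2}} at low q.
#'
#' @param q momentum transfer values \[1/Angstrom\], strictly positive
#' @param model a [bilayer_model()] (only `L_t`, `L_h`, `x`, `slds` are used)
#' @return Numeric vector of intensities, same length as `q`.
#' @examples
#' q <- exp(seq(log(0.004), log(0.35), length.out = 50))
#' lamellar_intensity(q, bilayer_model())
#' @export
lamellar_intensity <- function(q, model) {
  stopifnot(inherits(model, "bilayer_model"))
  if (any(q <= 0)) stop("q must be strictly positive", call. = FALSE)
  ec <- effective_slds(model$x, model$slds)
  d <- model$L_t + model$L_h
  amp <- ec$drho_o * (sin(q * d) - sin(q * model$L_t)) +
    ec$drho_i * sin(q * model$L_t)
  4 * pi / (q^4 * d) * amp^2
}

# sphere form-factor amplitude F(u) = 3 (sin u - u cos u) / u^3, F(0) = 1.
# Two-term series below u = 1e-4 avoids catastrophic cancellation.
.sphere_amp <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  out[small] <- 1 - u[small]^2 / 10
  ub <- u[!small]
  out[!small] <- 3 * (sin(ub) - ub * cos(ub)) / ub^3
  out
}

#' Spherical core-shell micelle scattering intensity
#'
#' Standard core-shell sphere form factor used for the residual lipid
#' aggregates: a tail-like core of radius `core_radius` and a head-like
#' shell of thickness `shell_thickness`,
#' \deqn{I(q) = \left[(\rho_c - \rho_{sh}) V_c F(qR_c) +
#'   (\rho_{sh} - \rho_s) V_{tot} F(qR_{tot})\right]^2}
#' with \eqn{F(u) = 3(\sin u - u\cos u)/u^3}.
#'
#' @param q momentum transfer values \[1/Angstrom\]
#' @param core_radius core radius [Angstrom], > 0
#' @param shell_thickness shell thickness [Angstrom], >= 0
#' @param rho_core,rho_shell,rho_s core, shell and solvent SLDs
#'   \[1/Angstrom^2\]
#' @return Numeric vector of intensities, same length as `q`.
#' @examples
#' micelle_intensity(0.05, 14.3, 6.65, 8.7e-6, 11.8e-6, 9.46e-6)
#' @export
micelle_intensity <- function(q, core_radius, shell_thickness,
                              rho_core, rho_shell, rho_s) {
  if (core_radius <= 0) stop("core_radius must be positive", call. = FALSE)
  if (shell_thickness < 0)
    stop("shell_thickness must be non-negative", call. = FALSE)
  if (any(q < 0)) stop("q must be non-negative", call. = FALSE)
  r_tot <- core_radius + shell_thickness
  v_c <- 4 / 3 * pi * core_radius^3
  v_tot <- 4 / 3 * pi * r_tot^3
  amp <- (rho_core - rho_shell) * v_c * .sphere_amp(q * core_radius) +
    (rho_shell - rho_s) * v_tot * .sphere_amp(q * r_tot)
  amp^2
}

#' Combined liposome + micelle model intensity
#'
#' Full model curve: roughness-damped lamellar and micellar terms plus a
#' constant background,
#' \deqn{I_{fin}(q) = C_1 I_{lam}(q) e^{-R^2 q^2} +
#'       C_2 I_{mc}(q) e^{-R^2 q^2} + B.}
#' The micelle inherits its geometry and SLDs from the bilayer: core radius
#' `L_t`, shell thickness `L_h`, core SLD `rho_t`, shell SLD `rho_h`
#' (the aggregates are lipid-only; no protein term).
#'
#' @param q strictly positive, strictly increasing momentum-transfer grid
#'   \[1/Angstrom\]
#' @param model a [bilayer_model()]
#' @return Numeric vector of model intensities.
#' @examples
#' q <- exp(seq(log(0.004), log(0.35), length.out = 100))
#' m <- bilayer_model(x = 0.03, R = 5.37, C2 = 5e-7, B = 1e-11)
#' combined_intensity(q, m)
#' @export
combined_intensity <- function(q, model) {
  stopifnot(inherits(model, "bilayer_model"))
  if (any(q <= 0)) stop("q must be strictly positive", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE))
    stop("q must be strictly increasing", call. = FALSE)
  damp <- exp(-model$R^2 * q^2)
  i_lam <- lamellar_intensity(q, model)
  i_mc <- micelle_intensity(q, model$L_t, model$L_h,
                            model$slds$rho_t, model$slds$rho_h,
                            model$slds$rho_s)
  model$C1 * i_lam * damp + model$C2 * i_mc * damp + model$B
}
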