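# Independent numerical oracles used across the test files. These never
# call the package's closed-form model code paths: the lamellar oracle is a
# cosine transform of the step SLD profile by adaptive quadrature, the
# micelle oracle a radial Fourier integral, and the protein-SLD oracle an
# explicit per-atom electron count.

# thin-sheet intensity of the symmetric step profile:
# I(q) = pi/(q^2 d) * A(q)^2, A(q) = 2 * int_0^d drho(z) cos(qz) dz
oracle_lamellar <- function(q, L_t, L_h, x, slds = sld_set()) {
  rho_i <- x * slds$rho_p + (1 - x) * slds$rho_t
  rho_o <- x * slds$rho_s + (1 - x) * slds$rho_h
  d <- L_t + L_h
  vapply(q, function(qi) {
    # integrate each constant slab separately so the quadrature never sees
    # the step discontinuity
    A <- 2 * (stats::integrate(function(z) (rho_i - slds$rho_s) *
                                 cos(qi * z), 0, L_t,
                               rel.tol = 1e-11)$value +
                stats::integrate(function(z) (rho_o - slds$rho_s) *
                                  cos(qi * z), L_t, d,
                                rel.tol = 1e-11)$value)
    pi / (qi^2 * d) * A^2
  }, numeric(1))
}

# core-shell sphere: I(q) = [4 pi int_0^R drho(r) r^2 sin(qr)/(qr) dr]^2
oracle_micelle <- function(q, core_radius, shell_thickness,
                           rho_core, rho_shell, rho_s) {
  r_tot <- core_radius + shell_thickness
  vapply(q, function(qi) {
    f <- function(r, drho) drho * r^2 * sin(qi * r) / (qi * r)
    A <- 4 * pi * (stats::integrate(f, 0, core_radius,
                                    drho = rho_core - rho_s,
                                    rel.tol = 1e-11)$value +
                     stats::integrate(f, core_radius, r_tot,
                                      drho = rho_shell - rho_s,
                                      rel.tol = 1e-11)$value)
    A^2
  }, numeric(1))
}

# per-atom electron-count oracle for polyglycine: each Gly residue in-chain
# is C2 H3 N O; the chain termini add one water (H2 O)
oracle_polyglycine_sld <- function(n, volume_per_gly = 60.1,
                                   water_volume = 29.9) {
  electrons <- n * (2 * 6 + 3 * 1 + 1 * 7 + 1 * 8) + (2 * 1 + 8)
  volume <- n * volume_per_gly + water_volume
  2.818e-5 * electrons / volume
}

# shared fixture: small noiseless series + the generating parameter vector
truth_par <- function(n = 4) {
  c(L_t = 14.3, L_h = 6.65, R = 5.37,
    stats::setNames(c(0, 0.0094, 0.012, 0.030)[seq_len(n)],
                    sprintf("x_%d", seq_len(n))),
    stats::setNames(rep(1, n), sprintf("C1_%d", seq_len(n))),
    stats::setNames(rep(5e-7, n), sprintf("C2_%d", seq_len(n))),
    stats::setNames(rep(1e-11, n), sprintf("B_%d", seq_len(n))))
}
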