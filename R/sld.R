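#' X-ray scattering length densities of the bilayer components
#'
#' Container for the four fixed X-ray scattering length densities (SLDs)
#' entering the bilayer model: solvent, lipid alkyl tails, PC headgroups and
#' the embedded protein. Defaults are the literature values used for soy PC
#' liposomes with reconstituted AqpZ in phosphate-buffered saline.
#'
#' @param rho_s solvent SLD [1/Angstrom^2]
#' @param rho_t lipid-tail SLD [1/Angstrom^2]
#' @param rho_h lipid-headgroup SLD [1/Angstrom^2]
#' @param rho_p protein SLD [1/Angstrom^2]
#' @return An object of class `sld_set`: a named list with the four SLDs.
#' @examples
#' sld_set()
#' @export
sld_set <- function(rho_s = 9.46e-6, rho_t = 8.7e-6,
                    rho_h = 11.8e-6, rho_p = 11.7e-6) {
  vals <- c(rho_s = rho_s, rho_t = rho_t, rho_h = rho_h, rho_p = rho_p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all X-ray SLDs must be finite and positive", call. = FALSE)
  structure(as.list(vals), class = "sld_set")
}

#' @export
print.sld_set <- function(x, ...) {
  cat("X-ray scattering length densities [1/A^2]:\n")
  for (nm in names(x)) cat(sprintf("  %-6s %.3e\n", nm, x[[nm]]))
  invisible(x)
}

#' Effective bilayer SLDs at a given protein volume fraction
#'
#' The hydrophobic (inner) region of the bilayer is a volume-weighted mix of
#' lipid tails and embedded protein; the hydrophilic (outer) region mixes
#' headgroups with solvent that fills the space above and below an embedded
#' protein:
#' \deqn{\rho_i = x\,\rho_p + (1-x)\,\rho_t, \qquad
#'       \rho_o = x\,\rho_s + (1-x)\,\rho_h.}
#'
#' @param x protein volume fraction in the bilayer, in \[0, 1\]
#' @param slds an [sld_set()]
#' @return A list of class `effective_contrasts` with elements `rho_i`,
#'   `rho_o` (effective SLDs) and `drho_i`, `drho_o` (contrasts to solvent).
#' @examples
#' effective_slds(0.03)
#' @export
effective_slds <- function(x, slds = sld_set()) {
  stopifnot(inherits(slds, "sld_set"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop("protein volume fraction x must be a single value in [0, 1]",
         call. = FALSE)
  rho_i <- x * slds$rho_p + (1 - x) * slds$rho_t
  rho_o <- x * slds$rho_s + (1 - x) * slds$rho_h
  structure(list(rho_i = rho_i, rho_o = rho_o,
                 drho_i = rho_i - slds$rho_s,
                 drho_o = rho_o - slds$rho_s),
            class = "effective_contrasts")
}

# Residue-level composition of the 20 standard amino acids within a peptide
# chain (one water removed): columns C, H, N, O, S.
.residue_formula <- matrix(c(
  3, 5, 1, 1, 0,   # A
  6, 12, 4, 1, 0,  # R
  4, 6, 2, 2, 0,   # N
  4, 5, 1, 3, 0,   # D
  3, 5, 1, 1, 1,   # C
  5, 8, 2, 2, 0,   # Q
  5, 7, 1, 3, 0,   # E
  2, 3, 1, 1, 0,   # G
  6, 7, 3, 1, 0,   # H
  6, 11, 1, 1, 0,  # I
  6, 11, 1, 1, 0,  # L
  6, 12, 2, 1, 0,  # K
  5, 9, 1, 1, 1,   # M
  9, 9, 1, 1, 0,   # F
  5, 7, 1, 1, 0,   # P
  3, 5, 1, 2, 0,   # S
  4, 7, 1, 2, 0,   # T
  11, 10, 2, 1, 0, # W
  9, 9, 1, 2, 0,   # Y
  5, 9, 1, 1, 0    # V
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  c("C", "H", "N", "O", "S")))

# electrons per residue in-chain
.residue_electrons <- drop(.residue_formula %*% c(6, 1, 7, 8, 16))

#' Amino-acid residue volumes
#'
#' Per-residue partial volumes (Zamyatnin 1972) in cubic Angstrom, used to
#' convert a protein's electron content into an X-ray scattering length
#' density. The table can be replaced by any named vector covering the
#' residues present in a sequence.
#'
#' @return Named numeric vector of residue volumes \[Angstrom^3\], one-letter
#'   codes as names.
#' @examples
#' residue_volumes()[["G"]]
#' @export
residue_volumes <- function() {
  c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
    Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
    S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
}

# classical electron radius [Angstrom]
.r_e <- 2.818e-5

#' X-ray SLD of a protein from its amino-acid sequence
#'
#' Computes the X-ray scattering length density of a (dry) protein as
#' total electrons times the classical electron radius divided by the summed
#' residue volumes. Chain termini contribute one extra water (10 electrons,
#' ~30 Angstrom^3).
#'
#' @param sequence one-letter amino-acid string (standard 20 residues)
#' @param volumes named vector of per-residue volumes \[Angstrom^3\];
#'   defaults to [residue_volumes()]
#' @param termini add the terminal H2O contribution? Default `TRUE`.
#' @return SLD \[1/Angstrom^2\].
#' @examples
#' sld_from_sequence("GGGGGGGGGG")
#' sld_from_sequence(aqpz_his_sequence())
#' @export
sld_from_sequence <- function(sequence, volumes = residue_volumes(),
                              termini = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string", call. = FALSE)
  aa <- strsplit(toupper(gsub("[ \t\n]", "", sequence)), "")[[1]]
  if (length(aa) == 0L) stop("empty sequence", call. = FALSE)
  bad <- which(!(aa %in% names(.residue_electrons) & aa %in% names(volumes)))
  if (length(bad) > 0L)
    stop(sprintf("unknown residue code '%s' at position %d",
                 aa[bad[1L]], bad[1L]), call. = FALSE)
  electrons <- sum(.residue_electrons[aa])
  volume <- sum(volumes[aa])
  if (termini) {
    electrons <- electrons + 10  # H2O
    volume <- volume + 29.9      # bulk-water molecular volume
  }
  .r_e * electrons / volume
}

#' Reconstructed AqpZ-His amino-acid sequence
#'
#' The Escherichia coli aquaporin-Z sequence (UniProt P60844) with a
#' C-terminal hexahistidine tag appended. This is a reconstructed stand-in
#' for the exact expression construct, which is not distributed with the
#' package; the plain-text copy lives in
#' `inst/extdata/aqpz_his_reconstructed.fasta`.
#'
#' @return One-letter amino-acid string (237 residues).
#' @export
aqpz_his_sequence <- function() {
  paste0(
    "MFRKLAAECFGTFWLVFGGCGSAVLAAGFPELGIGFAGVALAFGLTVLTMAFAVGHISGGHFNPAVTIGLWA",
    "GGRFPAKEVVGYVIAQVVGGIVAAALLYLIASGKTGFDAAASGFASNGYGEHSPGGYSMLSALVVELVLSAG",
    "FLLVIHGATDKFAPAGFAPIAIGLALTLIHLISIPVTNTSVNPARSTAVAIFQGGWALEQLWFFWVVPIVGG",
    "IIGGLIYRTLLEKRD",
    "HHHHHH")
}
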