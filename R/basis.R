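#' @useDynLib mpsvqe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gaussian basis-set library (subset needed for the systems treated here).
# Exponents/coefficients are the standard published values; coefficients refer
# to normalized primitives and every contracted shell is renormalized at
# expansion time. Cartesian (6d) components are used for d shells.
.basis_library <- list(
  "sto-3g" = list(
    H = list(
      list(l = 0L,
           exps  = c(3.42525091, 0.62391373, 0.16885540),
           coefs = c(0.15432897, 0.53532814, 0.44463454))
    ),
    C = list(
      list(l = 0L,
           exps  = c(71.6168370, 13.0450960, 3.5305122),
           coefs = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0L,
           exps  = c(2.9412494, 0.6834831, 0.2222899),
           coefs = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1L,
           exps  = c(2.9412494, 0.6834831, 0.2222899),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    )
  ),
  "6-31g" = list(
    H = list(
      list(l = 0L,
           exps  = c(18.7311370, 2.8253937, 0.6401217),
           coefs = c(0.03349460, 0.23472695, 0.81375733)),
      list(l = 0L, exps = 0.1612778, coefs = 1.0)
    ),
    C = list(
      list(l = 0L,
           exps  = c(3047.5249, 457.36951, 103.94869, 29.210155, 9.2866630, 3.1639270),
           coefs = c(0.0018347, 0.0140373, 0.0688426, 0.2321844, 0.4679413, 0.3623120)),
      list(l = 0L,
           exps  = c(7.8682724, 1.8812885, 0.5442493),
           coefs = c(-0.1193324, -0.1608542, 1.1434564)),
      list(l = 1L,
           exps  = c(7.8682724, 1.8812885, 0.5442493),
           coefs = c(0.0689991, 0.3164240, 0.7443083)),
      list(l = 0L, exps = 0.1687144, coefs = 1.0),
      list(l = 1L, exps = 0.1687144, coefs = 1.0)
    )
  ),
  "cc-pvdz" = list(
    H = list(
      list(l = 0L,
           exps  = c(13.0100, 1.9620, 0.4446, 0.1220),
           coefs = c(0.0196850, 0.1379770, 0.4781480, 0.5012400)),
      list(l = 0L, exps = 0.1220, coefs = 1.0),
      list(l = 1L, exps = 0.7270, coefs = 1.0)
    )
  )
)

# 6-31G(d): 6-31G plus one Cartesian d shell on heavy atoms
.basis_library[["6-31g(d)"]] <- .basis_library[["6-31g"]]
.basis_library[["6-31g(d)"]]$C <- c(
  .basis_library[["6-31g"]]$C,
  list(list(l = 2L, exps = 0.8, coefs = 1.0))
)

.element_numbers <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L,
                      N = 7L, O = 8L, F = 9L, Ne = 10L)

#' List the shells of a molecular system in a given basis
#'
#' Expands element symbols into contracted Gaussian shells centred on the
#' atomic positions (in Bohr).
#'
#' @param symbols character vector of element symbols
#' @param coords_bohr numeric matrix (n_atom x 3) of positions in Bohr
#' @param basis basis-set name (case-insensitive): "STO-3G", "6-31G",
#'   "6-31G(d)", "cc-pVDZ"
#' @return list of shell records (l, center, exps, coefs)
#' @keywords internal
basis_shells <- function(symbols, coords_bohr, basis) {
  key <- tolower(basis)
  if (!key %in% names(.basis_library))
    stop("basis '", basis, "' is not available", call. = FALSE)
  lib <- .basis_library[[key]]
  shells <- list()
  for (i in seq_along(symbols)) {
    el <- symbols[i]
    if (!el %in% names(lib))
      stop("element '", el, "' has no '", basis, "' parameters", call. = FALSE)
    for (sh in lib[[el]]) {
      sh$center <- as.numeric(coords_bohr[i, ])
      shells[[length(shells) + 1L]] <- sh
    }
  }
  shells
}
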