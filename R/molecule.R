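# Molecular systems, geometries, and XYZ input/output.

#' Bohr radius in Angstrom used for unit conversion
#' @keywords internal
.bohr <- 0.52917721092

#' Construct a molecular system
#'
#' A light container for a molecular geometry plus the electronic-structure
#' run parameters (basis, charge, spin multiplicity, optional active space).
#'
#' @param symbols character vector of element symbols
#' @param coords numeric matrix (n_atom x 3), Cartesian positions in Angstrom
#' @param basis Gaussian basis-set name (e.g. "STO-3G", "6-31G(d)", "cc-pVDZ")
#' @param charge total molecular charge
#' @param multiplicity spin multiplicity 2S+1 (only closed-shell singlets are
#'   supported by the restricted mean-field reference)
#' @param active_space optional \code{c(n_electrons, n_spatial_orbitals)}
#' @return an object of class \code{molecular_system}
#' @export
molecular_system <- function(symbols, coords, basis = "STO-3G", charge = 0L,
                             multiplicity = 1L, active_space = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(symbols) == nrow(coords))
  if (!all(symbols %in% names(.element_numbers)))
    stop("unknown element symbol(s): ",
         paste(setdiff(symbols, names(.element_numbers)), collapse = ", "))
  z <- .element_numbers[symbols]
  n_elec <- sum(z) - charge
  if (multiplicity != 1L)
    stop("only singlet spin multiplicities are supported")
  if (!is.null(active_space)) {
    stopifnot(length(active_space) == 2, active_space[1] %% 2 == 0,
              active_space[1] > 0, active_space[2] >= active_space[1] / 2)
  }
  structure(list(symbols = as.character(symbols), coords = coords,
                 basis = basis, charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 n_electrons = as.integer(n_elec),
                 active_space = active_space),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system> %d atoms, %d electrons, basis %s\n",
              length(x$symbols), x$n_electrons, x$basis))
  invisible(x)
}

#' Nuclear repulsion energy (Hartree)
#' @param mol a \code{molecular_system}
#' @export
nuclear_repulsion <- function(mol) {
  z <- unname(.element_numbers[mol$symbols])
  xyz <- mol$coords / .bohr
  e <- 0
  n <- nrow(xyz)
  if (n < 2) return(0)
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      e <- e + z[i] * z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  e
}

#' Read / write XYZ geometry files
#'
#' Standard XYZ: atom count, comment line, then element symbol and Cartesian
#' coordinates in Angstrom.
#'
#' @param path file path
#' @param basis,charge,active_space passed to \code{\link{molecular_system}}
#' @return \code{read_xyz}: a \code{molecular_system}
#' @export
read_xyz <- function(path, basis = "STO-3G", charge = 0L, active_space = NULL) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rec <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  symbols <- vapply(rec, `[`, "", 1L)
  coords <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
  molecular_system(symbols, coords, basis = basis, charge = charge,
                   active_space = active_space)
}

#' @rdname read_xyz
#' @param mol a \code{molecular_system}
#' @param comment comment line content
#' @export
write_xyz <- function(mol, path, comment = "") {
  lines <- c(sprintf("%d", length(mol$symbols)), comment,
             sprintf("%-2s %18.10f %18.10f %18.10f", mol$symbols,
                     mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

# ---- deterministic geometry generators ----------------------------------

#' Hydrogen molecule at a given bond length
#' @param R internuclear distance in Angstrom
#' @param basis basis-set name
#' @param active_space optional active space
#' @export
h2_molecule <- function(R, basis = "STO-3G", active_space = NULL) {
  molecular_system(c("H", "H"),
                   rbind(c(0, 0, 0), c(0, 0, R)),
                   basis = basis, active_space = active_space)
}

#' Alternating hydrogen chain (H2 moieties along z)
#'
#' Collinear chain of H atoms with alternating intra/inter-moiety separations
#' of 0.741441 and 1.322943 Angstrom.
#'
#' @param n_atoms even number of hydrogen atoms
#' @param basis basis-set name
#' @param r_intra,r_inter bond-length alternation in Angstrom
#' @export
h_chain <- function(n_atoms, basis = "STO-3G",
                    r_intra = 0.741441, r_inter = 1.322943) {
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 2L || n_atoms %% 2L != 0L)
    stop("n_atoms must be an even integer >= 2")
  z <- numeric(n_atoms)
  for (i in 2:n_atoms)
    z[i] <- z[i - 1] + if (i %% 2L == 0L) r_intra else r_inter
  molecular_system(rep("H", n_atoms), cbind(0, 0, z), basis = basis)
}

#' Regular hydrogen ring
#' @param n number of atoms (>= 3)
#' @param R nearest-neighbour distance in Angstrom
#' @param basis basis-set name
#' @export
h_ring <- function(n, R, basis = "STO-3G") {
  n <- as.integer(n)
  stopifnot(n >= 3)
  radius <- R / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  molecular_system(rep("H", n), cbind(radius * cos(ang), radius * sin(ang), 0),
                   basis = basis)
}

#' Ethane at a given H-C-C-H dihedral angle
#'
#' Bond lengths R(C-C) = 1.512 A and R(C-H) = 1.153 A with tetrahedral HCC
#' angles; \code{dihedral = 60} is the staggered conformer, \code{0} eclipsed.
#'
#' @param dihedral H-C-C-H dihedral angle in degrees
#' @param basis basis-set name
#' @param active_space optional active space, e.g. \code{c(6, 6)}
#' @param r_cc,r_ch bond lengths in Angstrom
#' @export
ethane <- function(dihedral = 60, basis = "STO-3G", active_space = NULL,
                   r_cc = 1.512, r_ch = 1.153) {
  hcc <- acos(-1 / 3)             # tetrahedral H-C-C angle
  zc <- r_cc / 2
  # carbon 1 at -zc, carbon 2 at +zc along z
  rho <- r_ch * sin(hcc)
  dz <- -r_ch * cos(hcc)          # H displaced away from the other carbon
  sym <- c("C", "C")
  xyz <- rbind(c(0, 0, -zc), c(0, 0, zc))
  for (k in 0:2) {                # hydrogens on carbon 1 (fixed at 0,120,240)
    phi <- 2 * pi * k / 3
    sym <- c(sym, "H")
    xyz <- rbind(xyz, c(rho * cos(phi), rho * sin(phi), -zc - dz))
  }
  for (k in 0:2) {                # hydrogens on carbon 2, rotated by dihedral
    phi <- 2 * pi * k / 3 + dihedral * pi / 180
    sym <- c(sym, "H")
    xyz <- rbind(xyz, c(rho * cos(phi), rho * sin(phi), zc + dz))
  }
  molecular_system(sym, xyz, basis = basis, active_space = active_space)
}
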