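# Pauli strings and qubit Hamiltonians.

# integer op codes used throughout: 0 = I, 1 = X, 2 = Y, 3 = Z
.op_codes <- c(I = 0L, X = 1L, Y = 2L, Z = 3L)
.op_letters <- c("I", "X", "Y", "Z")

#' Construct a Pauli string
#'
#' @param ops named assignment of operators to qubits, either a character
#'   label like \code{"X0 Z1 Y3"} (0-based qubit indices) or an integer vector
#'   of op codes (0=I,1=X,2=Y,3=Z) of length \code{n_qubits}
#' @param n_qubits total number of qubits
#' @return integer vector of op codes with class \code{pauli_string}
#' @export
pauli_string <- function(ops, n_qubits) {
  if (is.character(ops)) {
    v <- integer(n_qubits)
    ops <- trimws(ops)
    if (nzchar(ops)) {
      parts <- strsplit(ops, "\\s+")[[1]]
      for (p in parts) {
        letter <- substr(p, 1, 1)
        q <- as.integer(substr(p, 2, nchar(p)))
        if (!letter %in% c("X", "Y", "Z") || is.na(q) || q < 0 || q >= n_qubits)
          stop("bad Pauli factor '", p, "'")
        if (v[q + 1L] != 0L) stop("duplicate qubit index in '", ops, "'")
        v[q + 1L] <- .op_codes[[letter]]
      }
    }
  } else {
    v <- as.integer(ops)
    stopifnot(length(v) == n_qubits, all(v %in% 0:3))
  }
  structure(v, class = "pauli_string")
}

#' @export
format.pauli_string <- function(x, ...) pauli_label(unclass(x))

#' @export
print.pauli_string <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# label from an op-code vector
pauli_label <- function(v) {
  nz <- which(v != 0L)
  if (!length(nz)) return("I")
  paste0(.op_letters[v[nz] + 1L], nz - 1L, collapse = " ")
}

# parse character labels into an ops matrix (n_terms x n_qubits)
parse_pauli_labels <- function(labels, n_qubits) {
  m <- matrix(0L, length(labels), n_qubits)
  for (i in seq_along(labels)) {
    lab <- trimws(labels[i])
    if (!nzchar(lab) || lab == "I") next
    parts <- strsplit(lab, "\\s+")[[1]]
    q <- as.integer(substring(parts, 2))
    m[i, q + 1L] <- .op_codes[substring(parts, 1, 1)]
  }
  m
}

#' Construct a qubit Hamiltonian from explicit terms
#'
#' @param ops integer matrix (n_terms x n_qubits) of op codes, or character
#'   vector of labels like \code{"0.17 Z0 Z1"}-style \code{"Z0 Z1"}
#' @param coefs real coefficients, one per term
#' @param offset identity (constant) part, Hartree
#' @param n_qubits number of qubits
#' @return object of class \code{qubit_hamiltonian}
#' @export
qubit_hamiltonian <- function(ops, coefs, offset = 0, n_qubits = NULL) {
  if (is.character(ops)) {
    stopifnot(!is.null(n_qubits))
    ops <- parse_pauli_labels(ops, n_qubits)
  }
  ops <- as.matrix(ops)
  storage.mode(ops) <- "integer"
  stopifnot(nrow(ops) == length(coefs))
  structure(list(ops = ops, coefs = as.numeric(coefs),
                 offset = as.numeric(offset), n_qubits = ncol(ops)),
            class = "qubit_hamiltonian")
}

#' @export
print.qubit_hamiltonian <- function(x, ...) {
  cat(sprintf("<qubit_hamiltonian> %d qubits, %d Pauli terms, offset %.8f\n",
              x$n_qubits, nrow(x$ops), x$offset))
  invisible(x)
}

#' Jordan-Wigner qubit Hamiltonian from molecular integrals
#'
#' Assembles the second-quantized Hamiltonian from the one- and two-electron
#' MO integrals in the interleaved spin-orbital ordering (alpha0, beta0,
#' alpha1, ...), applies the Jordan-Wigner transformation, merges like Pauli
#' strings, and drops terms with |coefficient| below \code{cutoff}.
#'
#' @param ints an \code{\link{integral_set}}
#' @param cutoff coefficient magnitude cutoff in Hartree
#' @return a \code{\link{qubit_hamiltonian}}; the constant part (nuclear
#'   repulsion + frozen core + JW identity component) is in \code{offset}
#' @export
build_qubit_hamiltonian <- function(ints, cutoff = 1e-12) {
  res <- cpp_jw_hamiltonian(ints$h, as.numeric(ints$g), ints$core_energy,
                            cutoff, FALSE)
  if (res$max_imag > 1e-10)
    stop("JW produced non-Hermitian coefficients (max imag ",
         format(res$max_imag), ")")
  ham <- qubit_hamiltonian(parse_pauli_labels(res$labels, res$n_qubits),
                           res$coefs, res$offset)
  ham$n_elec <- ints$n_elec
  ham
}

#' Number of measurement circuits for a qubit Hamiltonian
#'
#' Counts the non-identity Pauli terms; each requires one measurement circuit
#' when the energy is estimated term by term.
#'
#' @param ham a \code{\link{qubit_hamiltonian}}
#' @export
count_measurement_circuits <- function(ham) {
  nrow(ham$ops)
}

#' Hamiltonian term count without materializing the terms
#'
#' @param ints an \code{\link{integral_set}}
#' @param cutoff coefficient magnitude cutoff in Hartree
#' @return number of non-identity Pauli terms after merging
#' @export
count_hamiltonian_terms <- function(ints, cutoff = 1e-12) {
  res <- cpp_jw_hamiltonian(ints$h, as.numeric(ints$g), ints$core_energy,
                            cutoff, TRUE)
  res$n_terms
}

#' Scaling exponent of the Hamiltonian term count for hydrogen chains
#'
#' Builds alternating hydrogen-chain Hamiltonians for the requested atom
#' counts, counts their Pauli terms, and fits the log-log slope of term count
#' versus the number of atoms.
#'
#' The counting convention expresses the Hamiltonian over symmetrically
#' orthogonalized local orbitals with a drop tolerance of 3e-8 Hartree
#' (the convention that reproduces the published measurement-circuit counts
#' for these chains); \code{orbitals = "canonical"} counts in the canonical
#' MO basis instead, where spatial symmetry cancels about half the strings.
#'
#' @param n_atoms_list chain sizes (even atom counts, >= 3 values for a
#'   confident fit)
#' @param basis basis-set name
#' @param cutoff coefficient magnitude cutoff
#' @param orbitals "local" (Loewdin) or "canonical" orbital representation
#' @return list with \code{exponent}, the per-size \code{counts} data frame,
#'   and \code{low_confidence} flag (fewer than 3 sizes)
#' @export
term_count_scaling <- function(n_atoms_list, basis = "STO-3G",
                               cutoff = 3e-8,
                               orbitals = c("local", "canonical")) {
  orbitals <- match.arg(orbitals)
  if (length(n_atoms_list) < 2) stop("need at least 2 chain sizes")
  rows <- list()
  for (n in n_atoms_list) {
    cnt <- tryCatch({
      mol <- h_chain(n, basis = basis)
      ints <- if (orbitals == "local") local_integrals(mol)
              else compute_integrals(mol)
      count_hamiltonian_terms(ints, cutoff)
    }, error = function(e) {
      warning("chain with ", n, " atoms skipped: ", conditionMessage(e))
      NA_real_
    })
    rows[[length(rows) + 1L]] <- data.frame(n_atoms = n, n_terms = cnt)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[!is.na(tab$n_terms), ]
  if (nrow(tab) < 2) stop("fewer than 2 chain sizes succeeded")
  fit <- stats::lm(log(n_terms) ~ log(n_atoms), data = tab)
  list(exponent = unname(stats::coef(fit)[2]), counts = tab,
       low_confidence = nrow(tab) < 3)
}

#' Export a qubit Hamiltonian to a line-oriented text file or JSON
#'
#' Text format: one term per line, \code{coefficient pauli_label}; the
#' identity offset appears with the label \code{I}.
#'
#' @param ham a \code{\link{qubit_hamiltonian}}
#' @param path output file path
#' @param format "text" or "json"
#' @export
write_hamiltonian <- function(ham, path, format = c("text", "json")) {
  format <- match.arg(format)
  labels <- apply(ham$ops, 1, pauli_label)
  if (format == "text") {
    lines <- c(sprintf("%.16e I", ham$offset),
               sprintf("%.16e %s", ham$coefs, labels))
    writeLines(lines, path)
  } else {
    jsonlite::write_json(
      list(n_qubits = ham$n_qubits, offset = ham$offset,
           terms = data.frame(coefficient = ham$coefs, pauli = labels)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a qubit Hamiltonian from the text format of \code{write_hamiltonian}
#' @param path input file path
#' @param n_qubits number of qubits
#' @export
read_hamiltonian <- function(path, n_qubits) {
  lines <- readLines(path)
  sp <- regexpr(" ", lines)
  coefs <- as.numeric(substr(lines, 1, sp - 1))
  labels <- trimws(substring(lines, sp + 1))
  isid <- labels == "I"
  qubit_hamiltonian(parse_pauli_labels(labels[!isid], n_qubits),
                    coefs[!isid], offset = sum(coefs[isid]))
}

#' Exact ground-state (FCI) energy of the qubit Hamiltonian
#'
#' Lowest eigenvalue of the Jordan-Wigner Hamiltonian, computed matrix-free
#' with a Lanczos iteration on the full 2^n space. This equals the full
#' configuration interaction energy of the underlying molecular problem.
#'
#' @param ints an \code{\link{integral_set}}, or a
#'   \code{\link{qubit_hamiltonian}}
#' @param cutoff JW coefficient cutoff when \code{ints} is an integral set
#' @return ground-state energy in Hartree
#' @export
fci_energy <- function(ints, cutoff = 1e-12) {
  ham <- if (inherits(ints, "qubit_hamiltonian")) ints
         else build_qubit_hamiltonian(ints, cutoff)
  if (ham$n_qubits > 20) stop("dense FCI limited to 20 qubits")
  cpp_pauli_ground_state(ham$ops, ham$coefs, ham$offset)$value
}

#' Dense matrix of a qubit Hamiltonian (validation oracle, <= 14 qubits)
#' @param ham a \code{\link{qubit_hamiltonian}}
#' @export
hamiltonian_matrix <- function(ham) {
  stopifnot(ham$n_qubits <= 14)
  dim <- 2^ham$n_qubits
  m <- matrix(0 + 0i, dim, dim)
  for (col in seq_len(dim)) {
    v <- complex(dim); v[col] <- 1
    m[, col] <- cpp_pauli_apply(ham$ops, ham$coefs, ham$offset, v)
  }
  m
}
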