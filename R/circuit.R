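# Quantum circuits: gate records, compilation to adjacent-qubit form,
# matrix resolution, CNOT accounting, and OpenQASM-style export.

#' Gate constructors
#'
#' Build gate records for \code{\link{circuit}}. Qubit indices are 0-based.
#' Rotation gates follow the convention \eqn{R_P(\theta) = \exp(-i \theta P / 2)}.
#' Parameterized rotations carry a parameter index and a linear coefficient:
#' the resolved angle is \code{pcoef * theta[param_id]}.
#'
#' @param q,control,target,a,b qubit indices
#' @param angle fixed rotation angle (radians)
#' @param param_id 1-based index into the circuit's parameter vector
#' @param pcoef linear coefficient applied to the parameter
#' @param mat explicit unitary matrix for \code{gate_u}
#' @name gates
NULL

.gate <- function(name, qubits, angle = NA_real_, param_id = NA_integer_,
                  pcoef = NA_real_, mat = NULL, control = NA_integer_) {
  list(name = name, qubits = as.integer(qubits), angle = angle,
       param_id = as.integer(param_id), pcoef = pcoef, mat = mat,
       control = as.integer(control))
}

#' @rdname gates
#' @export
gate_h <- function(q) .gate("H", q)
#' @rdname gates
#' @export
gate_x <- function(q) .gate("X", q)
#' @rdname gates
#' @export
gate_y <- function(q) .gate("Y", q)
#' @rdname gates
#' @export
gate_z <- function(q) .gate("Z", q)
#' @rdname gates
#' @export
gate_rx <- function(q, angle = NA, param_id = NA, pcoef = 1)
  .gate("RX", q, angle, param_id, pcoef)
#' @rdname gates
#' @export
gate_ry <- function(q, angle = NA, param_id = NA, pcoef = 1)
  .gate("RY", q, angle, param_id, pcoef)
#' @rdname gates
#' @export
gate_rz <- function(q, angle = NA, param_id = NA, pcoef = 1)
  .gate("RZ", q, angle, param_id, pcoef)
#' @rdname gates
#' @export
gate_cnot <- function(control, target) {
  stopifnot(control != target)
  .gate("CNOT", sort(c(control, target)), control = control)
}
#' @rdname gates
#' @export
gate_swap <- function(a, b) {
  stopifnot(a != b)
  .gate("SWAP", sort(c(a, b)))
}
#' @rdname gates
#' @export
gate_u <- function(q, mat) {
  q <- as.integer(q)
  d <- 2^length(q)
  check_unitary(mat, d)
  if (length(q) == 2 && q[1] > q[2]) {
    mat <- .swap4 %*% mat %*% .swap4
    q <- rev(q)
  }
  .gate("U", q, mat = mat)
}

.swap4 <- matrix(c(1, 0, 0, 0,
                   0, 0, 1, 0,
                   0, 1, 0, 0,
                   0, 0, 0, 1), 4, 4)

#' Construct a circuit
#'
#' @param gates list of gate records from the \code{gate_*} constructors
#' @param n_qubits number of qubits
#' @param n_params length of the parameter vector the circuit resolves
#'   against (0 for a parameter-free circuit)
#' @return object of class \code{circuit}
#' @export
circuit <- function(gates, n_qubits, n_params = 0L) {
  for (g in gates) {
    if (any(g$qubits < 0L | g$qubits >= n_qubits))
      stop("gate qubit index out of range")
    if (!is.na(g$param_id) && (g$param_id < 1L || g$param_id > n_params))
      stop("gate parameter index out of range")
  }
  structure(list(gates = gates, n_qubits = as.integer(n_qubits),
                 n_params = as.integer(n_params)),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("<circuit> %d qubits, %d gates, %d parameters, %d CNOTs\n",
              x$n_qubits, length(x$gates), x$n_params, count_cnots(x)))
  invisible(x)
}

# resolve one gate record to its unitary matrix
gate_matrix <- function(g, theta = NULL) {
  ang <- g$angle
  if (!is.na(g$param_id)) {
    if (is.null(theta) || length(theta) < g$param_id)
      stop("parameterized gate without a matching theta vector")
    ang <- g$pcoef * theta[g$param_id]
  }
  switch(g$name,
    H = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    X = matrix(c(0, 1, 1, 0), 2, 2),
    Y = matrix(c(0, 1i, -1i, 0), 2, 2),
    Z = diag(c(1, -1)),
    RX = {
      c2 <- cos(ang / 2); s2 <- sin(ang / 2)
      matrix(c(c2, -1i * s2, -1i * s2, c2), 2, 2)
    },
    RY = {
      c2 <- cos(ang / 2); s2 <- sin(ang / 2)
      matrix(c(c2, s2, -s2, c2), 2, 2)
    },
    RZ = diag(c(exp(-1i * ang / 2), exp(1i * ang / 2))),
    CNOT = if (g$control == g$qubits[1]) {
      matrix(c(1, 0, 0, 0,
               0, 1, 0, 0,
               0, 0, 0, 1,
               0, 0, 1, 0), 4, 4)
    } else {
      matrix(c(1, 0, 0, 0,
               0, 0, 0, 1,
               0, 0, 1, 0,
               0, 1, 0, 0), 4, 4)
    },
    SWAP = .swap4,
    U = g$mat,
    stop("unknown gate '", g$name, "'")
  )
}

# matrices + qubit index table for the MPS engine (adjacent gates only)
circuit_matrices <- function(circ, theta = NULL) {
  ng <- length(circ$gates)
  qubits <- matrix(-1L, ng, 2)
  mats <- vector("list", ng)
  for (k in seq_len(ng)) {
    g <- circ$gates[[k]]
    qubits[k, seq_along(g$qubits)] <- g$qubits
    if (length(g$qubits) == 1L) qubits[k, 2] <- -1L
    m <- gate_matrix(g, theta)
    storage.mode(m) <- "complex"
    mats[[k]] <- m
  }
  list(qubits = qubits, mats = mats)
}

# precompiled form for repeated evaluation: static matrices resolved once,
# parameterized rotations patched per theta
circuit_precompile <- function(circ) {
  ng <- length(circ$gates)
  par_idx <- which(vapply(circ$gates, function(g) !is.na(g$param_id),
                          logical(1)))
  base <- circuit_matrices(circ, theta = rep(0, max(1L, circ$n_params)))
  pinfo <- lapply(par_idx, function(k) {
    g <- circ$gates[[k]]
    list(k = k, name = g$name, pid = g$param_id, pcoef = g$pcoef)
  })
  list(qubits = base$qubits, mats = base$mats, pinfo = pinfo)
}

circuit_resolve <- function(pre, theta) {
  mats <- pre$mats
  for (p in pre$pinfo) {
    ang <- p$pcoef * theta[p$pid]
    m <- switch(p$name,
      RX = {
        c2 <- cos(ang / 2); s2 <- sin(ang / 2)
        matrix(c(c2, -1i * s2, -1i * s2, c2), 2, 2)
      },
      RY = {
        c2 <- cos(ang / 2); s2 <- sin(ang / 2)
        matrix(c(c2, s2, -s2, c2), 2, 2)
      },
      RZ = diag(c(exp(-1i * ang / 2), exp(1i * ang / 2))),
      stop("unsupported parameterized gate"))
    storage.mode(m) <- "complex"
    mats[[p$k]] <- m
  }
  mats
}

#' Compile a circuit to adjacent-qubit form
#'
#' Wraps every long-range two-qubit gate in a there-and-back SWAP ladder so
#' that all two-qubit gates act on nearest-neighbour qubits, as required by
#' the MPS engine; unitarily equivalent to the input circuit.
#'
#' @param circ a \code{\link{circuit}}
#' @param n_qubits optionally override the qubit count
#' @return compiled \code{\link{circuit}}
#' @export
compile_adjacent <- function(circ, n_qubits = circ$n_qubits) {
  out <- list()
  for (g in circ$gates) {
    if (length(g$qubits) == 1L || g$qubits[2] == g$qubits[1] + 1L) {
      out[[length(out) + 1L]] <- g
      next
    }
    a <- g$qubits[1]; b <- g$qubits[2]
    ladder <- if (b - a >= 2) seq(a, b - 2) else integer(0)
    for (s in ladder) out[[length(out) + 1L]] <- gate_swap(s, s + 1L)
    g2 <- g
    g2$qubits <- c(b - 1L, b)
    if (g$name == "CNOT")
      g2$control <- if (g$control == a) b - 1L else b
    out[[length(out) + 1L]] <- g2
    for (s in rev(ladder)) out[[length(out) + 1L]] <- gate_swap(s, s + 1L)
  }
  circuit(out, n_qubits, circ$n_params)
}

#' Count CNOT gates in a circuit
#'
#' SWAP gates count as 3 CNOTs; other gates as 0.
#'
#' @param circ a \code{\link{circuit}}
#' @export
count_cnots <- function(circ) {
  sum(vapply(circ$gates, function(g)
    switch(g$name, CNOT = 1L, SWAP = 3L, 0L), integer(1)))
}

#' Random circuit generator (validation fixture)
#'
#' Draws Haar-random one-qubit unitaries and random two-qubit unitaries on
#' adjacent pairs, plus occasional long-range CNOTs, deterministically from
#' the seed.
#'
#' @param n_qubits number of qubits
#' @param n_gates number of gates
#' @param seed RNG seed
#' @param p_long probability of a long-range CNOT (exercises
#'   \code{\link{compile_adjacent}})
#' @export
random_circuit <- function(n_qubits, n_gates, seed, p_long = 0.1) {
  stopifnot(n_qubits >= 2)
  gates <- withr::with_seed(seed, {
    lapply(seq_len(n_gates), function(k) {
      r <- stats::runif(1)
      if (r < 0.4) {
        gate_u(sample.int(n_qubits, 1) - 1L, haar_unitary(2))
      } else if (r < 0.4 + p_long && n_qubits >= 3) {
        qs <- sort(sample.int(n_qubits, 2) - 1L)
        gate_cnot(qs[1], qs[2])
      } else {
        a <- sample.int(n_qubits - 1, 1) - 1L
        gate_u(c(a, a + 1L), haar_unitary(4))
      }
    })
  })
  circuit(gates, n_qubits)
}

#' Haar-random unitary matrix
#' @param d dimension
#' @export
haar_unitary <- function(d) {
  z <- matrix(stats::rnorm(d * d) + 1i * stats::rnorm(d * d), d, d) / sqrt(2)
  qr_ <- qr(z)
  q <- qr.Q(qr_)
  r <- qr.R(qr_)
  q %*% diag(diag(r) / abs(diag(r)), d)
}

#' Export a circuit as OpenQASM-2-style text
#'
#' @param circ a \code{\link{circuit}}
#' @param theta parameter vector for parameterized rotations
#' @param path optional output file; when NULL the lines are returned
#' @export
write_qasm <- function(circ, theta = NULL, path = NULL) {
  lines <- c("OPENQASM 2.0;", "include \"qelib1.inc\";",
             sprintf("qreg q[%d];", circ$n_qubits))
  for (g in circ$gates) {
    ang <- g$angle
    if (!is.na(g$param_id)) {
      if (is.null(theta)) stop("theta required for parameterized circuit")
      ang <- g$pcoef * theta[g$param_id]
    }
    lines <- c(lines, switch(g$name,
      H = sprintf("h q[%d];", g$qubits),
      X = sprintf("x q[%d];", g$qubits),
      Y = sprintf("y q[%d];", g$qubits),
      Z = sprintf("z q[%d];", g$qubits),
      RX = sprintf("rx(%.16g) q[%d];", ang, g$qubits),
      RY = sprintf("ry(%.16g) q[%d];", ang, g$qubits),
      RZ = sprintf("rz(%.16g) q[%d];", ang, g$qubits),
      CNOT = sprintf("cx q[%d],q[%d];", g$control,
                     setdiff(g$qubits, g$control)),
      SWAP = sprintf("swap q[%d],q[%d];", g$qubits[1], g$qubits[2]),
      U = stop("generic U gates have no QASM form")))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
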