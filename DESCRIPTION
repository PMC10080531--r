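Package: mpsvqe
Title: Matrix-Product-State Emulation of Variational Quantum Eigensolvers for Quantum Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantum-computing emulator for molecular electronic structure built on
    matrix product states (MPS). Provides native Gaussian-integral and restricted
    Hartree-Fock routines, Jordan-Wigner qubit Hamiltonians, unitary coupled cluster
    (UCCSD) and qubit-pool ansatz compilation into one- and two-qubit gate circuits,
    a right-canonical MPS circuit simulator with selectable SVD backends (including a
    one-sided Jacobi kernel), a derivative-free variational quantum eigensolver (VQE)
    driver, and a density matrix embedding theory (DMET) driver with FCI or MPS-VQE
    fragment solvers. Includes deterministic geometry generators (hydrogen
    dissociation grids, alternating hydrogen chains, ethane torsion scans) and dense
    statevector oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minqa,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
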