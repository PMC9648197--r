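#' @useDynLib gwbse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats optimize uniroot
NULL

# atomic units <-> conventional units
HARTREE_EV <- 27.211386
BOHR_ANGSTROM <- 0.529177210903

.elements <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10)

# Bragg-Slater radii (Angstrom), used for the radial-grid scale of each atom
.bragg <- c(H = 0.35, He = 0.31, Li = 1.45, Be = 1.05, B = 0.85, C = 0.70,
            N = 0.65, O = 0.60, F = 0.50, Ne = 0.38)

elementZ <- function(symbols) {
  z <- .elements[symbols]
  if (anyNA(z)) {
    stop("unknown element symbol: ",
         paste(symbols[is.na(z)], collapse = ", "), call. = FALSE)
  }
  unname(z)
}

# symmetric eigendecomposition with eigenvalues in ascending order
.eigAsc <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
}
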