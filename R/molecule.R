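# Molecule construction, XYZ input and the fixture registry.

#' Create a molecule from symbols and coordinates
#'
#' @param symbols character vector of element symbols
#' @param coords numeric matrix (n x 3) of Cartesian positions in Angstrom
#' @param charge integer total charge
#' @param multiplicity spin multiplicity; must be 1 (closed shell)
#' @return a \linkS4class{Molecule}
#' @export
newMolecule <- function(symbols, coords, charge = 0L, multiplicity = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  elementZ(symbols)  # validates symbols with a clear error
  new("Molecule", symbols = symbols, coords = coords,
      charge = as.integer(charge), multiplicity = as.integer(multiplicity))
}

#' Read a molecule from an XYZ file
#'
#' Standard two-header-line XYZ dialect: first line the atom count, second a
#' free-form comment, then one \code{symbol x y z} line per atom (Angstrom).
#'
#' @param path path to the XYZ file
#' @param charge,multiplicity charge state (not encoded in plain XYZ)
#' @return a \linkS4class{Molecule} with atom order preserved
#' @export
loadMolecule <- function(path, charge = 0L, multiplicity = 1L) {
  if (!file.exists(path)) stop("XYZ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n <= 0)
    stop("malformed XYZ: first line must be the atom count", call. = FALSE)
  if (length(lines) < n + 2)
    stop("malformed XYZ: declared ", n, " atoms but file has only ",
         max(0, length(lines) - 2), " atom lines", call. = FALSE)
  body <- lines[3:(2 + n)]
  toks <- strsplit(trimws(body), "\\s+")
  if (any(vapply(toks, length, 1L) < 4))
    stop("malformed XYZ: each atom line needs 'symbol x y z'", call. = FALSE)
  symbols <- vapply(toks, `[[`, "", 1)
  xyz <- t(vapply(toks, function(tk) {
    v <- suppressWarnings(as.numeric(tk[2:4]))
    if (anyNA(v)) stop("coordinate parse failure in XYZ line: ",
                       paste(tk, collapse = " "), call. = FALSE)
    v
  }, numeric(3)))
  newMolecule(symbols, xyz, charge, multiplicity)
}

#' Define an atom-to-fragment partition
#'
#' @param mol a \linkS4class{Molecule}
#' @param mapping named list or character vector assigning a fragment label to
#'   every atom (by 1-based atom index); \code{NULL} puts all atoms in one
#'   fragment "ALL"
#' @return a \linkS4class{FragmentPartition}
#' @export
defineFragments <- function(mol, mapping = NULL) {
  n <- length(mol@symbols)
  if (is.null(mapping)) {
    return(new("FragmentPartition", atomToFragment = rep("ALL", n),
               fragmentLabels = "ALL"))
  }
  if (is.list(mapping)) {
    # list(A = c(1,2), B = c(3,4)) style
    lab <- rep(NA_character_, n)
    for (nm in names(mapping)) lab[mapping[[nm]]] <- nm
    mapping <- lab
  }
  if (length(mapping) != n || anyNA(mapping))
    stop("fragment mapping must cover every atom exactly once; atoms ",
         paste(which(is.na(mapping)), collapse = ", "), " unmapped",
         call. = FALSE)
  new("FragmentPartition", atomToFragment = as.character(mapping),
      fragmentLabels = unique(as.character(mapping)))
}

# ------------------------------------------------------------------ fixtures

.fixtures <- list(
  h2 = list(symbols = c("H", "H"),
            coords = rbind(c(0, 0, 0), c(0, 0, 0.74)),
            basis = "sto-3g"),
  h2_dimer_far = list(
    symbols = c("H", "H", "H", "H"),
    coords = rbind(c(0, 0, 0), c(0, 0, 0.74),
                   c(100, 0, 0), c(100, 0, 0.74)),
    basis = "sto-3g"),
  h2o = list(symbols = c("O", "H", "H"),
             coords = rbind(c(0, 0, 0.1173),
                            c(0, 0.7572, -0.4692),
                            c(0, -0.7572, -0.4692)),
             basis = "6-31g"),
  n2 = list(symbols = c("N", "N"),
            coords = rbind(c(0, 0, 0), c(0, 0, 1.0977)),
            basis = "sto-3g"),
  ethylene = list(
    symbols = c("C", "C", "H", "H", "H", "H"),
    coords = rbind(c(0, 0, 0.6695), c(0, 0, -0.6695),
                   c(0, 0.9289, 1.2321), c(0, -0.9289, 1.2321),
                   c(0, 0.9289, -1.2321), c(0, -0.9289, -1.2321)),
    basis = "sto-3g"),
  formaldehyde = list(
    symbols = c("O", "C", "H", "H"),
    coords = rbind(c(0, 0, 1.2050), c(0, 0, 0),
                   c(0, 0.9429, -0.5876), c(0, -0.9429, -0.5876)),
    basis = "sto-3g")
)

#' Built-in fixture molecules
#'
#' Deterministic hardcoded geometries of small closed-shell molecules used
#' throughout the test-suite and examples, with a recommended primary basis.
#'
#' @param name one of \code{h2, h2_dimer_far, h2o, n2, ethylene, formaldehyde}
#' @return list with elements \code{molecule} (a \linkS4class{Molecule}) and
#'   \code{basis} (recommended primary basis name)
#' @export
makeFixture <- function(name) {
  fx <- .fixtures[[name]]
  if (is.null(fx))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixtures), collapse = ", "), call. = FALSE)
  list(molecule = newMolecule(fx$symbols, fx$coords), basis = fx$basis)
}

#' @rdname makeFixture
#' @export
fixtureNames <- function() names(.fixtures)
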