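# End-to-end driver: geometry -> mean field -> GW quasiparticles -> BSE
# excitons -> analysis report.

#' Run the full GW-BSE workflow on a molecule
#'
#' @param mol a \linkS4class{Molecule}, or path to an XYZ file
#' @param basis primary basis name or \linkS4class{BasisSpec}
#' @param reference mean-field starting point (HF, LDA, PBE, PBEH40);
#'   the default PBEH40 is an effective preconditioner for qsGW
#' @param method quasiparticle scheme: "qsgw", "evgw" or "g0w0"
#' @param config settings from \code{gwConfig}
#' @param fragments optional atom->fragment assignment (see
#'   \code{defineFragments})
#' @param nRoots number of excitons (overrides config)
#' @param verbose print per-iteration progress lines
#' @return list with \code{meanField}, \code{qp}, \code{excitons},
#'   \code{report}
#' @export
runGWBSE <- function(mol, basis = NULL, reference = "PBEH40",
                     method = c("qsgw", "evgw", "g0w0"),
                     config = gwConfig(), fragments = NULL,
                     nRoots = config$nRoots, verbose = FALSE) {
  method <- match.arg(method)
  if (is.character(mol)) mol <- loadMolecule(mol)
  if (is.null(basis)) basis <- "sto-3g"
  mf <- runMeanField(mol, basis, reference, verbose = verbose)
  qp <- switch(method,
               qsgw = runQsGW(mf, config, verbose = verbose),
               evgw = runEvGW(mf, config, verbose = verbose),
               g0w0 = runG0W0(mf, config, verbose = verbose))
  op <- buildBSEOperator(qp, config, mode = "BSE")
  ex <- davidsonSolve(op, nRoots = min(nRoots, nrow(op@pairs)),
                      tol = config$davidsonTol)
  part <- if (is.null(fragments)) defineFragments(mol)
          else defineFragments(mol, fragments)
  rep <- excitonReport(ex, qp, part)
  list(meanField = mf, qp = qp, excitons = ex, report = rep)
}
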