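# Accessor generics.  Slot access from user code goes through these.

#' @rdname accessors
#' @param object an object of the package's S4 classes
#' @export
setGeneric("moEnergies", function(object) standardGeneric("moEnergies"))
#' @rdname accessors
#' @export
setGeneric("moCoefficients", function(object) standardGeneric("moCoefficients"))
#' @rdname accessors
#' @export
setGeneric("qpEnergies", function(object) standardGeneric("qpEnergies"))
#' @rdname accessors
#' @export
setGeneric("excitationEnergies",
           function(object) standardGeneric("excitationEnergies"))
#' @rdname accessors
#' @export
setGeneric("homoLumoGap", function(object) standardGeneric("homoLumoGap"))
#' @rdname accessors
#' @export
setGeneric("occupationsOf", function(object) standardGeneric("occupationsOf"))

#' Accessors for mean-field, quasiparticle and exciton solutions
#'
#' \code{homoLumoGap} returns the gap in Hartree.
#' @name accessors
NULL

#' @rdname accessors
setMethod("moEnergies", "MeanFieldSolution", function(object) object@moEnergy)
#' @rdname accessors
setMethod("moCoefficients", "MeanFieldSolution",
          function(object) object@moCoeff)
#' @rdname accessors
setMethod("moCoefficients", "QPSolution", function(object) object@moCoeff)
#' @rdname accessors
setMethod("qpEnergies", "QPSolution", function(object) object@qpEnergy)
#' @rdname accessors
setMethod("excitationEnergies", "ExcitonSolution",
          function(object) object@omegas)
#' @rdname accessors
setMethod("occupationsOf", "MeanFieldSolution",
          function(object) object@occupations)
#' @rdname accessors
setMethod("occupationsOf", "QPSolution", function(object) object@occupations)

.gapOf <- function(e, occ) min(e[occ == 0]) - max(e[occ > 0])

#' @rdname accessors
setMethod("homoLumoGap", "MeanFieldSolution",
          function(object) .gapOf(object@moEnergy, object@occupations))
#' @rdname accessors
setMethod("homoLumoGap", "QPSolution",
          function(object) .gapOf(object@qpEnergy, object@occupations))
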