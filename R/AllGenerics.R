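#' Accessors for DetectionHistory objects
#'
#' \code{detections()} returns the species x site matrix of occasion counts
#' y_ik; \code{effort()} returns the per-site number of active occasions n_i.
#'
#' @param object a \linkS4class{DetectionHistory}.
#' @return \code{detections()}: an integer matrix (species x sites);
#'   \code{effort()}: a named integer vector of length \code{ncol(object)}.
#' @examples
#' dh <- exampleDetectionHistory()
#' detections(dh)[1:2, 1:3]
#' effort(dh)
#' @aliases detections effort
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))

#' @rdname detections
#' @export
setGeneric("effort", function(object) standardGeneric("effort"))

#' @rdname detections
setMethod("detections", "DetectionHistory", function(object)
  SummarizedExperiment::assay(object, "detections"))

#' @rdname detections
setMethod("effort", "DetectionHistory", function(object)
  setNames(object$effort, colnames(object)))

setMethod("show", "DetectionHistory", function(object) {
  y <- detections(object)
  cat(sprintf("DetectionHistory: %d species x %d sites\n", nrow(y), ncol(y)))
  cat(sprintf("  effort: %d-%d occasions of %g day(s) per site, total %d\n",
              min(object$effort), max(object$effort), object@occasionDays,
              sum(object$effort)))
  cat(sprintf("  detections: %d occasion-level events, naive richness %d\n",
              sum(y), nrow(y)))
})
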