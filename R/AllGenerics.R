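#' Accessors for knockoutDepletion classes
#'
#' \code{cellTracks} returns the per-frame track table of a
#' \linkS4class{LineageTree}; \code{progenitors} its root cell ids;
#' \code{nCells} the number of distinct cells; \code{fractionTimes} the
#' fraction collection times of a \linkS4class{TfnseqExperiment};
#' \code{truthTable} its simulation ground truth (or \code{NULL}).
#'
#' @param x a \linkS4class{LineageTree} or \linkS4class{TfnseqExperiment}.
#' @return see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellTracks", function(x) standardGeneric("cellTracks"))

#' @rdname accessors
#' @export
setGeneric("progenitors", function(x) standardGeneric("progenitors"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("fractionTimes", function(x) standardGeneric("fractionTimes"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setMethod("cellTracks", "LineageTree", function(x) x@tracks)

#' @rdname accessors
#' @export
setMethod("progenitors", "LineageTree", function(x) x@progenitorIds)

#' @rdname accessors
#' @export
setMethod("nCells", "LineageTree", function(x) {
  length(unique(x@tracks$cell_id))
})

#' @rdname accessors
#' @export
setMethod("fractionTimes", "TfnseqExperiment", function(x) x$time_h)

#' @rdname accessors
#' @export
setMethod("truthTable", "TfnseqExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"class" %in% names(rd)) {
    return(NULL)
  }
  df <- as.data.frame(rd)
  df$gene_id <- rownames(df)
  rownames(df) <- NULL
  df[, c("gene_id", setdiff(names(df), "gene_id"))]
})

setMethod("show", "LineageTree", function(object) {
  tr <- object@tracks
  cat("LineageTree with", length(unique(tr$cell_id)), "cells,",
      length(object@progenitorIds), "progenitor(s)\n")
  if (nrow(tr)) {
    cat(sprintf(
      "  time span: %.3g - %.3g h (%d frames), fluorescence: %s\n",
      min(tr$time_h), max(tr$time_h), length(unique(tr$time_h)),
      if ("fluor_au" %in% names(tr)) "yes" else "no"
    ))
  }
  invisible(NULL)
})

setMethod("show", "FitnessLandscape", function(object) {
  cat("FitnessLandscape:", length(object@relAbundance), "points; ")
  if (is.na(object@arrestRelAbundance)) {
    cat("no arrest detected\n")
  } else {
    cat(sprintf("arrest at C/C0 = %.4g\n", object@arrestRelAbundance))
  }
  invisible(NULL)
})

setMethod("show", "RltoParams", function(object) {
  cat(sprintf(
    "RltoParams: muM = %g, epsilon = %g, arrestFitness = %g, noise = %s\n",
    object@muM, object@epsilon, object@arrestFitness, object@noiseModel
  ))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname accessors
#' @export
setGeneric("growthRate", function(x) standardGeneric("growthRate"))

#' @rdname accessors
#' @export
setGeneric("arrestRelAbundance", function(x) standardGeneric("arrestRelAbundance"))

#' @rdname accessors
#' @export
setMethod("relAbundance", "FitnessLandscape", function(x) x@relAbundance)

#' @rdname accessors
#' @export
setMethod("growthRate", "FitnessLandscape", function(x) x@growthRate)

#' @rdname accessors
#' @export
setMethod("arrestRelAbundance", "FitnessLandscape", function(x) {
  x@arrestRelAbundance
})
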