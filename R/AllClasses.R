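#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData rowData<-
NULL

#' LineageTree: a tracked single-cell lineage
#'
#' Container for per-cell time series of segmented area (and, optionally,
#' integrated fluorescence) linked by parentage. One row of \code{tracks} is
#' one cell observed at one frame. Time zero is the knockout (transformation)
#' event; areas are in square microns and fluorescence in arbitrary units.
#'
#' @slot tracks \code{data.frame} with columns \code{cell_id},
#'   \code{parent_id} (\code{NA} for progenitors), \code{time_h},
#'   \code{area_um2} and optionally \code{fluor_au} (integrated
#'   fluorescence, i.e. protein amount, not concentration).
#' @slot progenitorIds integer vector of root cell ids present at the first
#'   frame.
#' @slot metadata list of free-form provenance (simulation parameters,
#'   source file, ...).
#'
#' @seealso [simulateLineage()], [readCellTracks()], [totalAreaSeries()]
#' @export
setClass("LineageTree",
  representation(
    tracks = "data.frame",
    progenitorIds = "integer",
    metadata = "list"
  ),
  prototype(
    tracks = data.frame(
      cell_id = integer(), parent_id = integer(),
      time_h = numeric(), area_um2 = numeric()
    ),
    progenitorIds = integer(),
    metadata = list()
  )
)

setValidity("LineageTree", function(object) {
  tr <- object@tracks
  need <- c("cell_id", "parent_id", "time_h", "area_um2")
  if (!all(need %in% names(tr))) {
    return(paste("tracks must contain columns:", paste(need, collapse = ", ")))
  }
  if (nrow(tr) == 0L) {
    return(TRUE)
  }
  if (any(tr$area_um2 <= 0)) {
    return("all areas must be positive")
  }
  sp <- split(tr$time_h, tr$cell_id)
  if (any(vapply(sp, function(t) any(diff(t) <= 0), logical(1)))) {
    return("per-cell times must be strictly increasing")
  }
  ## parent links: acyclic and child first frame >= parent last frame
  firstT <- vapply(split(tr$time_h, tr$cell_id), min, numeric(1))
  lastT <- vapply(split(tr$time_h, tr$cell_id), max, numeric(1))
  par <- tr$parent_id[!duplicated(tr$cell_id)]
  ids <- tr$cell_id[!duplicated(tr$cell_id)]
  names(par) <- as.character(ids)
  for (i in seq_along(ids)) {
    p <- par[[i]]
    if (is.na(p)) next
    key <- as.character(p)
    if (!key %in% names(firstT)) {
      return(sprintf("cell %s has unknown parent %s", ids[i], p))
    }
    if (firstT[[as.character(ids[i])]] < lastT[[key]] - 1e-9) {
      return("child cells cannot appear before their parent's last frame")
    }
  }
  ## acyclicity: follow parents, must terminate
  for (i in seq_along(ids)) {
    seen <- character(0)
    key <- as.character(ids[i])
    while (!is.na(par[[key]])) {
      if (key %in% seen) return("parent links contain a cycle")
      seen <- c(seen, key)
      key <- as.character(par[[key]])
      if (!key %in% names(par)) break
    }
  }
  TRUE
})

#' TfnseqExperiment: a transposon-library depletion time course
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' \code{"counts"} holds mapped-read counts for insertion mutants (rows)
#' across timed culture fractions (columns). \code{colData} carries the
#' fraction collection times in hours (\code{time_h}); \code{rowData} may
#' carry simulation ground truth (\code{class}, \code{slope},
#' \code{arrest_time_h}, \code{log10_o}) or annotation.
#'
#' @export
setClass("TfnseqExperiment", contains = "SummarizedExperiment")

setValidity("TfnseqExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  if (!"time_h" %in% names(SummarizedExperiment::colData(object))) {
    return("colData column 'time_h' is required")
  }
  tt <- object$time_h
  if (any(diff(tt) <= 0)) {
    return("fraction times must be strictly increasing")
  }
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0)) {
    return("counts must be non-negative")
  }
  TRUE
})

#' FitnessLandscape: growth rate versus relative protein abundance
#'
#' Pairs of relative protein abundance C/C0 (descending from 1 as the
#' lineage dilutes the protein) and aggregate areal growth rate, together
#' with the relative abundance at which growth arrest was detected.
#'
#' @slot relAbundance numeric, C/C0 in (0, 1], ordered decreasing.
#' @slot growthRate numeric, aggregate growth rate (1/h) at each abundance.
#' @slot arrestRelAbundance scalar C_A/C0 where arrest was detected
#'   (\code{NA} if no arrest).
#' @export
setClass("FitnessLandscape",
  representation(
    relAbundance = "numeric",
    growthRate = "numeric",
    arrestRelAbundance = "numeric"
  ),
  prototype(arrestRelAbundance = NA_real_)
)

setValidity("FitnessLandscape", function(object) {
  ra <- object@relAbundance
  if (length(ra) != length(object@growthRate)) {
    return("relAbundance and growthRate must have equal length")
  }
  if (length(ra) && (any(ra <= 0) || any(ra > 1 + 1e-9))) {
    return("relAbundance must lie in (0, 1]")
  }
  a <- object@arrestRelAbundance
  if (!is.na(a) && (a <= 0 || a > 1 + 1e-9)) {
    return("arrestRelAbundance must lie in (0, 1]")
  }
  TRUE
})

#' RltoParams: parameters of the Robustness-Load Trade-Off model
#'
#' @slot muM message number: transcripts produced per gene per cell cycle.
#'   Sets the expression-noise scale (gamma model: CV^2 = 1/muM).
#' @slot epsilon relative metabolic load per unit of sufficient expression
#'   (fitness cost of expressing one threshold-equivalent of protein).
#' @slot arrestFitness relative fitness of an arrested lineage (default 0:
#'   arrest is lethal on the experiment's timescale).
#' @slot noiseModel \code{"gamma"} (burst-limited expression, the default)
#'   or \code{"lognormal"} (CV matched).
#' @export
setClass("RltoParams",
  representation(
    muM = "numeric",
    epsilon = "numeric",
    arrestFitness = "numeric",
    noiseModel = "character"
  ),
  prototype(epsilon = 1e-3, arrestFitness = 0, noiseModel = "gamma")
)

setValidity("RltoParams", function(object) {
  if (length(object@muM) != 1 || object@muM <= 0) {
    return("muM must be a single positive number")
  }
  if (object@epsilon <= 0 || object@epsilon >= 1) {
    return("epsilon must lie in (0, 1)")
  }
  if (object@arrestFitness < 0 || object@arrestFitness >= 1) {
    return("arrestFitness must lie in [0, 1)")
  }
  if (!object@noiseModel %in% c("gamma", "lognormal")) {
    return("noiseModel must be 'gamma' or 'lognormal'")
  }
  TRUE
})

#' @describeIn RltoParams-class constructor.
#' @param muM,epsilon,arrestFitness,noiseModel see slots.
#' @export
RltoParams <- function(muM, epsilon = 1e-3, arrestFitness = 0,
                       noiseModel = c("gamma", "lognormal")) {
  new("RltoParams",
    muM = as.numeric(muM), epsilon = as.numeric(epsilon),
    arrestFitness = as.numeric(arrestFitness),
    noiseModel = match.arg(noiseModel)
  )
}

#' @describeIn TfnseqExperiment-class constructor.
#'
#' @param counts integer/numeric matrix, genes x fractions.
#' @param times numeric vector of fraction times (h), one per column.
#' @param rowData optional \code{DataFrame}/\code{data.frame} of per-gene
#'   annotation or simulation truth.
#' @param metadata optional list.
#' @export
TfnseqExperiment <- function(counts, times, rowData = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  if (length(times) != ncol(counts)) {
    stop("length(times) must equal ncol(counts)")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("t_", times)
  }
  cd <- S4Vectors::DataFrame(time_h = as.numeric(times))
  rownames(cd) <- colnames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    metadata = metadata
  )
  if (!is.null(rowData)) {
    SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
  }
  new("TfnseqExperiment", se)
}
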