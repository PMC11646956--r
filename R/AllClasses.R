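#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   colData rowData<- colData<-
NULL

#' PeakTable: an untargeted metabolomics feature table
#'
#' A \code{PeakTable} holds one deconvolved LC-MS or GC-MS peak table:
#' a features x samples intensity matrix (assay \code{"intensity"}), feature
#' metadata (\code{mz} in Da, \code{rt} in minutes, \code{platform}) as
#' \code{rowData}, and per-injection sample metadata (\code{sample_type} in
#' \{sample, QC, blank\}, \code{batch}, \code{injection_order}, class labels
#' and covariates) as \code{colData}. Missing intensities are \code{NA};
#' negative intensities are invalid. Every transformation applied by the
#' preprocessing functions appends an entry to the provenance log stored in
#' \code{metadata(x)$provenance}.
#'
#' @section Validity:
#' \itemize{
#'   \item rowData has numeric \code{mz > 0} and \code{rt >= 0}; feature ids
#'     (rownames) are unique and non-empty.
#'   \item colData has \code{sample_type} in \{sample, QC, blank\}, integer
#'     \code{batch}, and \code{injection_order} unique within each batch;
#'     sample ids (colnames) are unique.
#'   \item intensities are numeric, and never negative where observed.
#' }
#'
#' @slot .. inherits all slots from \linkS4class{SummarizedExperiment}.
#' @export
setClass("PeakTable", contains = "SummarizedExperiment")

validPeakTable <- function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  fid <- rownames(object)
  sid <- colnames(object)
  if (is.null(fid) || anyNA(fid) || any(fid == ""))
    msg <- c(msg, "feature ids (rownames) must be non-empty")
  else if (anyDuplicated(fid))
    msg <- c(msg, sprintf("duplicated feature id: '%s'",
                          fid[duplicated(fid)][1L]))
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    msg <- c(msg, "sample ids (colnames) must be non-empty")
  else if (anyDuplicated(sid))
    msg <- c(msg, sprintf("duplicated sample id: '%s'",
                          sid[duplicated(sid)][1L]))
  rd <- rowData(object)
  for (col in c("mz", "rt")) if (!col %in% colnames(rd))
    msg <- c(msg, sprintf("rowData column '%s' is required", col))
  if ("mz" %in% colnames(rd) && any(rd$mz <= 0, na.rm = TRUE))
    msg <- c(msg, "feature mz must be > 0")
  if ("rt" %in% colnames(rd) && any(rd$rt < 0, na.rm = TRUE))
    msg <- c(msg, "feature rt must be >= 0")
  cd <- colData(object)
  for (col in c("sample_type", "batch", "injection_order"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("sample_type" %in% colnames(cd) &&
      !all(cd$sample_type %in% c("sample", "QC", "blank")))
    msg <- c(msg, "sample_type must be one of 'sample', 'QC', 'blank'")
  if (all(c("batch", "injection_order") %in% colnames(cd))) {
    key <- paste(cd$batch, cd$injection_order)
    if (anyDuplicated(key))
      msg <- c(msg, sprintf(
        "injection_order duplicated within batch (batch %s, order %s)",
        cd$batch[duplicated(key)][1L],
        cd$injection_order[duplicated(key)][1L]))
  }
  if ("intensity" %in% SummarizedExperiment::assayNames(object)) {
    x <- assay(object, "intensity")
    if (!is.numeric(x))
      msg <- c(msg, "intensities must be numeric")
    else if (any(x < 0, na.rm = TRUE)) {
      bad <- which(x < 0, arr.ind = TRUE)[1L, ]
      msg <- c(msg, sprintf(
        "negative intensity at feature '%s', sample '%s'",
        rownames(object)[bad[1L]], colnames(object)[bad[2L]]))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("PeakTable", validPeakTable)

#' Construct a PeakTable
#'
#' @param intensity numeric matrix, features x samples (rownames = feature
#'   ids, colnames = sample ids); \code{NA} marks missing values.
#' @param features data.frame/DataFrame of feature metadata with at least
#'   \code{mz} and \code{rt}; one row per feature.
#' @param samples data.frame/DataFrame of sample metadata with at least
#'   \code{sample_type}, \code{batch}, \code{injection_order}; one row per
#'   sample (injection).
#' @param provenance optional list of provenance entries to seed the log.
#' @return a validated \linkS4class{PeakTable}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("F1", "F2"), c("S1", "S2")))
#' pt <- PeakTable(m,
#'                 features = data.frame(mz = c(100.1, 200.2), rt = c(1, 2)),
#'                 samples  = data.frame(sample_type = c("sample", "QC"),
#'                                       batch = 1L,
#'                                       injection_order = 1:2))
#' dim(pt)
#' @export
PeakTable <- function(intensity, features, samples, provenance = list()) {
  stopIf(!is.matrix(intensity), "'intensity' must be a matrix")
  stopIf(nrow(features) != nrow(intensity),
         "feature metadata rows (", nrow(features),
         ") do not match intensity rows (", nrow(intensity), ")")
  stopIf(nrow(samples) != ncol(intensity),
         "sample metadata rows (", nrow(samples),
         ") do not match intensity columns (", ncol(intensity), ")")
  rd <- DataFrame(features)
  cd <- DataFrame(samples)
  if (!is.null(rownames(features)) &&
      !identical(rownames(features), as.character(seq_len(nrow(features)))))
    rownames(rd) <- rownames(features)
  else rownames(rd) <- rownames(intensity)
  rownames(cd) <- if (!is.null(rownames(samples)) &&
      !identical(rownames(samples), as.character(seq_len(nrow(samples)))))
    rownames(samples) else colnames(intensity)
  se <- SummarizedExperiment(assays = list(intensity = intensity),
                             rowData = rd, colData = cd)
  obj <- new("PeakTable", se)
  metadata(obj)$provenance <- provenance
  validObject(obj)
  obj
}

#' @describeIn PeakTable intensity matrix accessor (features x samples).
#' @param x a PeakTable.
#' @export
intensities <- function(x) assay(x, "intensity")

#' @describeIn PeakTable replace the intensity matrix (same dimensions).
#' @param value replacement matrix.
#' @export
`intensities<-` <- function(x, value) {
  assay(x, "intensity") <- value
  validObject(x)
  x
}

#' @describeIn PeakTable feature metadata as a data.frame, with feature ids
#'   as rownames.
#' @export
featureData <- function(x) as.data.frame(rowData(x))

#' @describeIn PeakTable sample metadata as a data.frame, with sample ids as
#'   rownames.
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @describeIn PeakTable ordered list of transformations applied so far.
#' @export
provenance <- function(x) metadata(x)$provenance %||% list()

## Internal: append one provenance entry (monotone log).
logProvenance <- function(x, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  metadata(x)$provenance <- c(provenance(x), list(entry))
  x
}

setMethod("show", "PeakTable", function(object) {
  cd <- colData(object)
  cat(sprintf("PeakTable: %d features x %d injections\n",
              nrow(object), ncol(object)))
  cat(sprintf("  samples: %d, QCs: %d, blanks: %d, batches: %d\n",
              sum(cd$sample_type == "sample"), sum(cd$sample_type == "QC"),
              sum(cd$sample_type == "blank"), length(unique(cd$batch))))
  cat(sprintf("  missing: %.1f%%\n",
              100 * mean(is.na(assay(object, "intensity")))))
  stages <- vapply(provenance(object), function(e) e$stage, character(1))
  cat("  provenance:", if (length(stages)) paste(stages, collapse = " -> ")
      else "(raw)", "\n")
})

#' PLSModel: a fitted PLS2 discriminant model
#'
#' Holds the result of NIPALS partial least squares regression of a one-hot
#' class indicator matrix on a preprocessed intensity matrix, as used for
#' PLS-DA. Scores/weights/loadings follow the usual PLS2 conventions:
#' X-weights \code{W} (p x A, unit-norm columns), X-scores \code{T}
#' (n x A, mutually orthogonal), X-loadings \code{P} (p x A), Y-loadings
#' \code{Q} (k x A), and the regression coefficient matrix \code{B} (p x k)
#' on centred scales.
#'
#' @slot weights p x A X-weight matrix W.
#' @slot loadings p x A X-loading matrix P.
#' @slot scores n x A X-score matrix T (training scores).
#' @slot yloadings k x A Y-loading matrix Q.
#' @slot coefficients p x k coefficient matrix B for centred X and Y.
#' @slot xmeans,ymeans training column means used for centring.
#' @slot classes character vector of class labels (column order of Y).
#' @slot ncomp number of components A.
#' @slot featureIds feature ids matching rows of W/P/B.
#' @export
setClass("PLSModel", representation(
  weights = "matrix", loadings = "matrix", scores = "matrix",
  yloadings = "matrix", coefficients = "matrix",
  xmeans = "numeric", ymeans = "numeric",
  classes = "character", ncomp = "integer", featureIds = "character"))

setValidity("PLSModel", function(object) {
  msg <- character()
  A <- object@ncomp
  if (ncol(object@weights) != A) msg <- c(msg, "weights must have A columns")
  if (!all(abs(colSums(object@weights^2) - 1) < 1e-6))
    msg <- c(msg, "W columns must be unit norm")
  TT <- crossprod(object@scores)
  off <- abs(TT[upper.tri(TT)])
  lim <- 1e-8 * max(diag(TT))
  if (length(off) && any(off > lim))
    msg <- c(msg, "score columns must be mutually orthogonal")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d features, %d classes (%s), %d components\n",
              nrow(object@weights), length(object@classes),
              paste(object@classes, collapse = "/"), object@ncomp))
})

#' ValidationSummary: bootstrap + permutation validation of a classifier
#'
#' @slot observed_ccr per-bootstrap out-of-bag correct classification rates
#'   (percent).
#' @slot null_ccr per-permutation null CCRs (percent); length 0 when no
#'   permutation test was run.
#' @slot mean_ccr mean of \code{observed_ccr} (percent).
#' @slot classwise_ccr named per-class mean recall (percent).
#' @slot sensitivity,specificity,accuracy macro one-vs-rest means (percent).
#' @slot empirical_p (1 + #\{null >= mean observed\}) / (n_perm + 1); NA when
#'   no permutations were run.
#' @slot n_boot,n_perm,seed the resampling configuration used.
#' @export
setClass("ValidationSummary", representation(
  observed_ccr = "numeric", null_ccr = "numeric", mean_ccr = "numeric",
  classwise_ccr = "numeric", sensitivity = "numeric",
  specificity = "numeric", accuracy = "numeric", empirical_p = "numeric",
  n_boot = "integer", n_perm = "integer", seed = "integer"))

setValidity("ValidationSummary", function(object) {
  msg <- character()
  rates <- c(object@observed_ccr, object@null_ccr, object@mean_ccr,
             object@classwise_ccr, object@sensitivity, object@specificity,
             object@accuracy)
  if (any(rates < 0 | rates > 100, na.rm = TRUE))
    msg <- c(msg, "all rates must lie in [0, 100]")
  if (length(object@observed_ccr) != object@n_boot)
    msg <- c(msg, "observed_ccr length must equal n_boot")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ValidationSummary", function(object) {
  cat(sprintf(
    "ValidationSummary: %d bootstrap iterations, %d permutations\n",
    object@n_boot, object@n_perm))
  cat(sprintf("  mean CCR: %.2f%% (accuracy %.2f%%, sens %.2f%%, spec %.2f%%)\n",
              object@mean_ccr, object@accuracy, object@sensitivity,
              object@specificity))
  if (length(object@null_ccr))
    cat(sprintf("  null CCR mean: %.2f%%, empirical p = %.4g\n",
                mean(object@null_ccr), object@empirical_p))
})

#' PathwayModel: compound-set definitions over a reference universe
#'
#' @slot pathways named list; each element is a list with \code{name} and
#'   \code{compounds} (character vector of compound ids).
#' @slot universe character vector of all reference compound ids.
#' @export
setClass("PathwayModel",
         representation(pathways = "list", universe = "character"))

setValidity("PathwayModel", function(object) {
  msg <- character()
  for (pid in names(object@pathways)) {
    pw <- object@pathways[[pid]]
    if (!all(c("name", "compounds") %in% names(pw))) {
      msg <- c(msg, sprintf("pathway '%s' needs 'name' and 'compounds'", pid))
      next
    }
    missing <- setdiff(pw$compounds, object@universe)
    if (length(missing))
      msg <- c(msg, sprintf(
        "pathway '%s' member(s) not in reference universe: %s",
        pid, paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PathwayModel", function(object) {
  cat(sprintf("PathwayModel: %d pathways over %d reference compounds\n",
              length(object@pathways), length(object@universe)))
})

#' Accessors for PathwayModel
#' @param x a PathwayModel.
#' @return \code{pathwayIds}: character vector of pathway ids;
#'   \code{pathwayCompounds}: character vector of member compound ids.
#' @export
pathwayIds <- function(x) names(x@pathways)

#' @rdname pathwayIds
#' @param id a pathway id.
#' @export
pathwayCompounds <- function(x, id) x@pathways[[id]]$compounds
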