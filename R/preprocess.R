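## QC-driven feature filtering, LOESS signal-drift correction, cubic-spline
## imputation, log10 transformation and Pareto scaling.
##
## Filter semantics follow the usual pooled-QC conventions: a feature must be
## present (non-missing) in at least `qc_presence_min` of the QC injections
## (boundary inclusive), must have QC relative standard deviation strictly
## below `qc_rsd_max` percent, and must carry at least `blank_ratio_min` times
## more mean signal in study samples than in extraction blanks (boundary
## inclusive; a feature with no blank signal is kept).

#' Preprocessing filter configuration
#'
#' @param qc_presence_min minimum fraction of QC injections in which a
#'   feature must be detected (default 0.10, inclusive).
#' @param qc_rsd_max maximum QC relative standard deviation in percent
#'   (default 40, strict: RSD must be < this value).
#' @param blank_ratio_min minimum mean(sample)/mean(blank) intensity fold
#'   (default 3, inclusive).
#' @param loess_span LOESS span (fraction of QC points per batch) for drift
#'   correction, degree-1 local regression.
#' @return list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(qc_presence_min = 0.10, qc_rsd_max = 40,
                         blank_ratio_min = 3, loess_span = 0.75) {
  stopIf(qc_presence_min <= 0 || qc_presence_min > 1,
         "qc_presence_min must be in (0, 1]")
  stopIf(qc_rsd_max <= 0, "qc_rsd_max must be > 0")
  stopIf(blank_ratio_min < 1, "blank_ratio_min must be >= 1")
  structure(list(qc_presence_min = qc_presence_min, qc_rsd_max = qc_rsd_max,
                 blank_ratio_min = blank_ratio_min, loess_span = loess_span),
            class = "FilterConfig")
}

qcCols <- function(x) which(sampleData(x)$sample_type == "QC")
blankCols <- function(x) which(sampleData(x)$sample_type == "blank")
sampleCols <- function(x) which(sampleData(x)$sample_type == "sample")

#' Per-feature QC relative standard deviation
#'
#' @param x a \linkS4class{PeakTable} with QC injections.
#' @return named numeric vector, percent (100 * sd / mean over non-missing QC
#'   intensities; \code{NA} for features with fewer than two QC values or
#'   zero QC mean).
#' @export
qcRsd <- function(x) {
  qc <- intensities(x)[, qcCols(x), drop = FALSE]
  apply(qc, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    100 * sd(v) / m
  })
}

#' QC presence filter
#'
#' Keeps a feature iff it is non-missing in at least
#' \code{config$qc_presence_min} of the pooled-QC injections.
#'
#' @param x a \linkS4class{PeakTable}.
#' @param config a \code{\link{filterConfig}}.
#' @return list with \code{table} (filtered) and \code{removed} (feature
#'   ids dropped).
#' @export
qcPresenceFilter <- function(x, config = filterConfig()) {
  qc <- qcCols(x)
  stopIf(length(qc) == 0L,
         "no QC injections in table; QC presence filter requires pooled QCs")
  frac <- rowMeans(!is.na(intensities(x)[, qc, drop = FALSE]))
  keep <- frac >= config$qc_presence_min
  out <- x[keep, ]
  out <- logProvenance(out, "qc_presence_filter",
                       threshold = config$qc_presence_min,
                       removed = sum(!keep), kept = sum(keep))
  list(table = out, removed = rownames(x)[!keep])
}

#' QC RSD filter
#'
#' Keeps a feature iff its QC relative standard deviation is strictly below
#' \code{config$qc_rsd_max} percent. Features with fewer than two non-missing
#' QC values, or a zero QC mean, are dropped with reason
#' \code{"insufficient QC support"}.
#'
#' @inheritParams qcPresenceFilter
#' @return list with \code{table}, \code{removed} and \code{reasons} (named
#'   character: why each removed feature was dropped).
#' @export
qcRsdFilter <- function(x, config = filterConfig()) {
  rsd <- qcRsd(x)
  keep <- !is.na(rsd) & rsd < config$qc_rsd_max
  reasons <- ifelse(is.na(rsd), "insufficient QC support",
                    sprintf("QC RSD %.2f%% >= %g%%", rsd, config$qc_rsd_max))
  out <- x[keep, ]
  out <- logProvenance(out, "qc_rsd_filter", threshold = config$qc_rsd_max,
                       removed = sum(!keep), kept = sum(keep))
  list(table = out, removed = rownames(x)[!keep],
       reasons = setNames(reasons[!keep], rownames(x)[!keep]))
}

#' Blank signal ratio filter
#'
#' Keeps a feature iff mean(sample intensity) / mean(blank intensity) is at
#' least \code{config$blank_ratio_min}. Features with no observed blank
#' signal (all blank cells missing, or blank mean zero) are kept. With no
#' blank injections in the table the filter is skipped with a warning.
#'
#' @inheritParams qcPresenceFilter
#' @return list with \code{table} and \code{removed}.
#' @export
blankRatioFilter <- function(x, config = filterConfig()) {
  bl <- blankCols(x)
  if (length(bl) == 0L) {
    warning("no blank injections; blank ratio filter skipped")
    out <- logProvenance(x, "blank_ratio_filter", skipped = TRUE,
                         removed = 0L, kept = nrow(x))
    return(list(table = out, removed = character()))
  }
  m <- intensities(x)
  s_mean <- rowMeans(m[, sampleCols(x), drop = FALSE], na.rm = TRUE)
  b_mean <- rowMeans(m[, bl, drop = FALSE], na.rm = TRUE)
  no_blank <- is.nan(b_mean) | b_mean == 0
  keep <- no_blank | (s_mean / b_mean >= config$blank_ratio_min)
  keep[is.na(keep)] <- FALSE
  out <- x[keep, ]
  out <- logProvenance(out, "blank_ratio_filter",
                       threshold = config$blank_ratio_min,
                       removed = sum(!keep), kept = sum(keep))
  list(table = out, removed = rownames(x)[!keep])
}

## Global acquisition index: injections ordered by (batch, injection_order).
runOrder <- function(x) {
  sd_ <- sampleData(x)
  order(sd_$batch, sd_$injection_order)
}

#' QC-based LOESS signal-drift correction
#'
#' For each feature and batch a degree-1 LOESS curve is fitted to the pooled
#' QC intensities against injection order; every injection in the batch is
#' divided by the curve value at its injection order. Batches are then
#' rescaled so the per-batch QC medians agree, and the feature is returned to
#' its original scale via the grand QC median. Batches with fewer than 4 QC
#' injections fall back to a median-ratio correction (constant divisor) with
#' a warning. Features for which any required divisor is non-positive are
#' flagged and left uncorrected.
#'
#' @param x a \linkS4class{PeakTable}.
#' @param span LOESS span as a fraction of QC points per batch; widened
#'   automatically when a batch has too few QCs for the requested span.
#' @return list with \code{table} (corrected) and \code{model} (list:
#'   \code{span}, \code{fallback_batches}, \code{flagged} feature ids).
#' @export
driftCorrect <- function(x, span = 0.75) {
  m <- intensities(x)
  sd_ <- sampleData(x)
  batches <- sort(unique(sd_$batch))
  is_qc <- sd_$sample_type == "QC"
  fallback <- integer()
  for (b in batches)
    if (sum(is_qc & sd_$batch == b) < 4L) fallback <- c(fallback, b)
  if (length(fallback))
    warning("batch(es) ", paste(fallback, collapse = ", "),
            " have < 4 QC injections; using median-ratio correction there")

  corrected <- m
  flagged <- logical(nrow(m))
  grand_med <- apply(m[, is_qc, drop = FALSE], 1L, median, na.rm = TRUE)

  for (b in batches) {
    jb <- which(sd_$batch == b)
    o_all <- sd_$injection_order[jb]
    jq <- jb[is_qc[jb]]
    o_qc <- sd_$injection_order[jq]
    for (f in seq_len(nrow(m))) {
      if (flagged[f]) next
      yq <- m[f, jq]
      ok <- !is.na(yq)
      if (b %in% fallback || sum(ok) < 4L) {
        div <- median(yq[ok])
        if (!is.finite(div) || div <= 0) { flagged[f] <- TRUE; next }
        fit <- rep(div, length(jb))
      } else {
        sp <- max(span, min(1, 4 / sum(ok)))
        lo <- tryCatch(
          loess(yq[ok] ~ o_qc[ok], span = sp, degree = 1,
                family = "gaussian",
                control = loess.control(surface = "direct")),
          error = function(e) NULL)
        if (is.null(lo)) { flagged[f] <- TRUE; next }
        fit <- predict(lo, newdata = o_all)
      }
      if (any(!is.finite(fit) | fit <= 0)) { flagged[f] <- TRUE; next }
      corrected[f, jb] <- m[f, jb] / fit
    }
  }

  ## inter-batch rescaling: per-batch QC medians -> 1, then restore scale.
  for (f in which(!flagged)) {
    for (b in batches) {
      jb <- which(sd_$batch == b)
      mb <- median(corrected[f, jb[is_qc[jb]]], na.rm = TRUE)
      if (is.finite(mb) && mb > 0) corrected[f, jb] <- corrected[f, jb] / mb
    }
    if (is.finite(grand_med[f]) && grand_med[f] > 0)
      corrected[f, ] <- corrected[f, ] * grand_med[f]
  }
  corrected[flagged, ] <- m[flagged, ]

  intensities(x) <- corrected
  x <- logProvenance(x, "drift_correct", span = span,
                     flagged = sum(flagged),
                     fallback_batches = fallback)
  list(table = x,
       model = list(span = span, fallback_batches = fallback,
                    flagged = rownames(m)[flagged]))
}

#' Cubic-spline imputation of missing intensities
#'
#' Per feature, a natural cubic spline is fitted to the observed intensities
#' against the global acquisition index (batch, then injection order).
#' Interior missing cells take the spline value; cells before the first or
#' after the last observation take the nearest observed value; imputed
#' values are clipped at zero. Features with fewer than 4 observed values
#' fall back to the feature median.
#'
#' @param x a \linkS4class{PeakTable}.
#' @return the imputed \linkS4class{PeakTable}.
#' @export
imputeMissing <- function(x) {
  m <- intensities(x)
  ord <- runOrder(x)
  idx <- integer(ncol(m)); idx[ord] <- seq_along(ord)  # acquisition index
  n_fallback <- 0L
  for (f in seq_len(nrow(m))) {
    miss <- is.na(m[f, ])
    if (!any(miss)) next
    obs <- which(!miss)
    if (length(obs) < 4L) {
      m[f, miss] <- if (length(obs)) median(m[f, obs]) else 0
      n_fallback <- n_fallback + 1L
      next
    }
    xo <- idx[obs]; yo <- m[f, obs]
    xm <- idx[miss]
    lo <- min(xo); hi <- max(xo)
    inside <- xm >= lo & xm <= hi
    vals <- numeric(length(xm))
    if (any(inside))
      vals[inside] <- spline(xo, yo, xout = xm[inside],
                             method = "natural")$y
    if (any(!inside)) {
      nearest <- ifelse(xm[!inside] < lo, yo[which.min(xo)],
                        yo[which.max(xo)])
      vals[!inside] <- nearest
    }
    m[f, miss] <- pmax(vals, 0)
  }
  intensities(x) <- m
  logProvenance(x, "impute_missing", fallback_features = n_fallback)
}

#' log10 transformation
#'
#' Zeros are first replaced by half the feature's minimum positive intensity
#' (logged per feature); all intensities must be non-negative.
#'
#' @param x a \linkS4class{PeakTable}.
#' @return the transformed \linkS4class{PeakTable}.
#' @export
log10Transform <- function(x) {
  m <- intensities(x)
  zero_feats <- 0L
  for (f in seq_len(nrow(m))) {
    z <- !is.na(m[f, ]) & m[f, ] == 0
    if (any(z)) {
      pos <- m[f, !is.na(m[f, ]) & m[f, ] > 0]
      stopIf(length(pos) == 0L, "feature '", rownames(m)[f],
             "' is all-zero; cannot log-transform")
      m[f, z] <- min(pos) / 2
      zero_feats <- zero_feats + 1L
    }
  }
  m <- log10(m)
  ## bypass the validity check: log10 intensities may legitimately be < 0
  assay(x, "intensity", withDimnames = FALSE) <- m
  logProvenance(x, "log10_transform", zero_substituted_features = zero_feats)
}

#' Pareto scaling
#'
#' Per feature: subtract the mean and divide by the square root of the
#' (sample, n-1) standard deviation. Zero-variance features are set to zero
#' with a warning.
#'
#' @param x a \linkS4class{PeakTable} (usually log10-transformed).
#' @return the scaled \linkS4class{PeakTable}.
#' @export
paretoScale <- function(x) {
  m <- intensities(x)
  stopIf(ncol(m) < 2L, "Pareto scaling needs at least 2 samples")
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1L, sd, na.rm = TRUE)
  zero_var <- !is.na(s) & s == 0
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance feature(s) set to 0")
  m <- sweep(m, 1L, mu, `-`)
  nz <- !zero_var
  m[nz, ] <- sweep(m[nz, , drop = FALSE], 1L, sqrt(s[nz]), `/`)
  m[zero_var, ] <- 0
  assay(x, "intensity", withDimnames = FALSE) <- m
  logProvenance(x, "pareto_scale", zero_variance_features = sum(zero_var))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: QC presence filter, QC RSD filter, blank ratio filter,
#' LOESS drift correction, cubic-spline imputation, log10 transformation and
#' Pareto scaling, logging per-stage feature counts in the provenance.
#' QC and blank injections are used by the filters and the drift model and
#' are dropped before the transformation stages unless \code{keep_all}.
#'
#' @param x a \linkS4class{PeakTable} with QC (and ideally blank) injections.
#' @param config a \code{\link{filterConfig}}.
#' @param keep_all keep QC/blank columns through transformation (default
#'   drops them after imputation, since downstream statistics operate on
#'   study samples).
#' @return the preprocessed \linkS4class{PeakTable}.
#' @export
runPreprocess <- function(x, config = filterConfig(), keep_all = FALSE) {
  x <- qcPresenceFilter(x, config)$table
  x <- qcRsdFilter(x, config)$table
  x <- blankRatioFilter(x, config)$table
  stopIf(nrow(x) == 0L, "no features survived filtering")
  x <- driftCorrect(x, span = config$loess_span)$table
  x <- imputeMissing(x)
  if (!keep_all) {
    keep <- sampleCols(x)
    x <- x[, keep]
    x <- logProvenance(x, "subset_samples", n_samples = length(keep))
  }
  x <- log10Transform(x)
  paretoScale(x)
}
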