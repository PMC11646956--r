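## File I/O for peak tables, sample metadata, compound tables and pathway
## models. All formats are plain text: comma-separated for tables/metadata,
## tab-separated for compound tables, JSON for pathway models and provenance.
##
## Feature table CSV layout (the transpose of the internal features x samples
## matrix): one row per sample, first column `sample_id`, remaining columns
## named by feature id. Missing cells are written "" and parsed from "" or
## "NA". Feature m/z and RT travel in the metadata CSV written alongside.

#' Read a feature table and its sample metadata
#'
#' @param path CSV of intensities: rows = samples (first column
#'   \code{sample_id}), columns = features.
#' @param metadata_path CSV of per-sample metadata with columns
#'   \code{sample_id}, \code{sample_type}, \code{batch},
#'   \code{injection_order} plus any class labels/covariates.
#' @param feature_path optional CSV of per-feature metadata
#'   (\code{feature_id}, \code{mz}, \code{rt}, \code{platform}); when absent,
#'   m/z and RT are parsed from feature ids of the form
#'   \code{"M<mz>T<rt>"} if possible, else an error is raised.
#' @return a validated \linkS4class{PeakTable}. If a provenance sidecar
#'   (\code{<path>.provenance.json}) exists it is restored.
#' @export
readPeakTable <- function(path, metadata_path, feature_path = NULL) {
  stopIf(!file.exists(path), "intensity file not found: ", path)
  stopIf(!file.exists(metadata_path),
         "metadata file not found: ", metadata_path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIf(ncol(raw) < 1L || names(raw)[1L] != "sample_id",
         "first column of ", path, " must be 'sample_id'")
  sid <- as.character(raw$sample_id)
  dup <- sid[duplicated(sid)]
  stopIf(length(dup) > 0,
         "duplicated sample id in ", path, ": '", dup[1L], "'")
  fid <- names(raw)[-1L]
  dupf <- fid[duplicated(fid)]
  stopIf(length(dupf) > 0,
         "duplicated feature id in ", path, ": '", dupf[1L], "'")
  mat <- t(as.matrix(raw[, -1L, drop = FALSE]))
  if (is.character(mat)) {
    num <- suppressWarnings(as.numeric(mat))
    bad <- which(is.na(num) & !(trimws(mat) %in% c("", "NA", NA)))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(mat))
      stop("non-numeric intensity '", mat[bad[1L]], "' at feature '",
           fid[rc[1L]], "', sample '", sid[rc[2L]], "' in ", path,
           call. = FALSE)
    }
    mat <- matrix(num, nrow = nrow(mat))
  }
  storage.mode(mat) <- "double"
  dimnames(mat) <- list(fid, sid)
  if (any(mat < 0, na.rm = TRUE)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop("negative intensity at feature '", fid[bad[1L]], "', sample '",
         sid[bad[2L]], "' in ", path, call. = FALSE)
  }

  meta <- read.csv(metadata_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  stopIf(!"sample_id" %in% names(meta),
         "metadata must contain a 'sample_id' column")
  missing <- setdiff(sid, meta$sample_id)
  stopIf(length(missing) > 0,
         "sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(sid, meta$sample_id), , drop = FALSE]
  rownames(meta) <- meta$sample_id
  meta$sample_id <- NULL

  if (!is.null(feature_path)) {
    stopIf(!file.exists(feature_path),
           "feature metadata file not found: ", feature_path)
    fmeta <- read.csv(feature_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
    stopIf(!"feature_id" %in% names(fmeta),
           "feature metadata must contain a 'feature_id' column")
    missf <- setdiff(fid, fmeta$feature_id)
    stopIf(length(missf) > 0, "feature(s) missing from feature metadata: ",
           paste(head(missf, 3), collapse = ", "))
    fmeta <- fmeta[match(fid, fmeta$feature_id), , drop = FALSE]
    rownames(fmeta) <- fmeta$feature_id
    fmeta$feature_id <- NULL
  } else {
    mz <- suppressWarnings(as.numeric(sub("^M([0-9.]+)T[0-9.]+$", "\\1", fid)))
    rt <- suppressWarnings(as.numeric(sub("^M[0-9.]+T([0-9.]+)$", "\\1", fid)))
    stopIf(anyNA(mz) || anyNA(rt),
           "no feature metadata given and feature ids are not 'M<mz>T<rt>'")
    fmeta <- data.frame(mz = mz, rt = rt, row.names = fid)
  }

  prov <- list()
  provpath <- paste0(path, ".provenance.json")
  if (file.exists(provpath))
    prov <- jsonlite::read_json(provpath, simplifyVector = FALSE)
  PeakTable(mat, features = fmeta, samples = meta, provenance = prov)
}

#' Write a feature table, its metadata and provenance sidecar
#'
#' Writes three files: \code{path} (intensity CSV, rows = samples, columns in
#' the table's feature order), \code{metadata_path} (sample metadata CSV) and
#' \code{<path>.provenance.json}. Missing values are written as empty cells.
#'
#' @param x a \linkS4class{PeakTable}.
#' @param path,metadata_path output CSV paths.
#' @param feature_path optional path for the feature metadata CSV (default:
#'   \code{<path>} with suffix \code{.features.csv}).
#' @return invisibly, the paths written.
#' @export
writePeakTable <- function(x, path, metadata_path,
                           feature_path = sub("(\\.csv)?$", ".features.csv",
                                              path)) {
  mat <- intensities(x)
  df <- data.frame(sample_id = colnames(mat),
                   t(mat), check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  meta <- data.frame(sample_id = colnames(x), sampleData(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(meta, metadata_path, row.names = FALSE, na = "")
  fmeta <- data.frame(feature_id = rownames(x), featureData(x),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(fmeta, feature_path, row.names = FALSE, na = "")
  provpath <- paste0(path, ".provenance.json")
  jsonlite::write_json(provenance(x), provpath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(path, metadata_path, feature_path, provpath))
}

#' Read a compound table
#'
#' Tab-separated with columns \code{compound_id}, \code{name},
#' \code{monoisotopic_mass} (Da) and \code{pathway_ids}
#' (semicolon-separated, may be empty).
#'
#' @param path TSV path.
#' @return data.frame with one row per compound and a list column
#'   \code{pathway_ids}.
#' @export
readCompoundTable <- function(path) {
  stopIf(!file.exists(path), "compound table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "name", "monoisotopic_mass")
  miss <- setdiff(need, names(df))
  stopIf(length(miss) > 0,
         "compound table lacks column(s): ", paste(miss, collapse = ", "))
  stopIf(anyDuplicated(df$compound_id) > 0, "duplicated compound_id: '",
         df$compound_id[duplicated(df$compound_id)][1L], "'")
  bad <- df$compound_id[!is.finite(df$monoisotopic_mass) |
                          df$monoisotopic_mass <= 0]
  stopIf(length(bad) > 0,
         "compound with non-positive monoisotopic mass: '", bad[1L], "'")
  df$pathway_ids <- if ("pathway_ids" %in% names(df))
    lapply(strsplit(ifelse(is.na(df$pathway_ids), "", df$pathway_ids), ";"),
           function(v) v[nzchar(v)])
  else rep(list(character()), nrow(df))
  df
}

#' Read a pathway model
#'
#' JSON of the form \code{\{"universe": [...], "pathways": \{"<id>":
#' \{"name": ..., "compounds": [...]\}, ...\}\}}. Every pathway member must
#' be present in the universe.
#'
#' @param path JSON path.
#' @return a validated \linkS4class{PathwayModel}.
#' @export
readPathwayModel <- function(path) {
  stopIf(!file.exists(path), "pathway model not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopIf(!all(c("universe", "pathways") %in% names(js)),
         "pathway model needs 'universe' and 'pathways'")
  pathways <- lapply(js$pathways, function(pw)
    list(name = pw$name, compounds = unlist(pw$compounds) %||% character()))
  new("PathwayModel", pathways = pathways,
      universe = unlist(js$universe) %||% character())
}

#' Write a pathway model to JSON
#' @param x a \linkS4class{PathwayModel}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePathwayModel <- function(x, path) {
  jsonlite::write_json(
    list(universe = x@universe,
         pathways = lapply(x@pathways, function(pw)
           list(name = pw$name, compounds = pw$compounds))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
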