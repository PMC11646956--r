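## VIP-score feature ranking and accurate-mass putative annotation.

#' Default positive-mode adduct mass shifts (Da)
#'
#' Observed m/z = neutral monoisotopic mass + shift, for singly charged
#' positive-mode adducts.
#' @export
positiveAdducts <- c("[M+H]+" = 1.007276, "[M+Na]+" = 22.989218,
                     "[M+K]+" = 38.963158, "[M+NH4]+" = 18.033823)

#' VIP scores of a fitted PLS-DA model
#'
#' The variable importance in projection of feature j is
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj} / \|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{SSY_a = \|q_a\|^2 (t_a \cdot t_a)} is the Y-variance explained
#' by component a and p the number of model features. The mean of squared
#' VIPs over all features equals 1.
#'
#' @param model a fitted \linkS4class{PLSModel}.
#' @return data.frame with columns \code{feature_id}, \code{vip},
#'   \code{vip_gt1}, sorted by descending VIP with ties broken by feature id.
#' @export
vipScores <- function(model) {
  stopIf(!is(model, "PLSModel"), "'model' must be a fitted PLSModel")
  W <- model@weights
  p <- nrow(W)
  ssy <- colSums(model@yloadings^2) * colSums(model@scores^2)
  wn2 <- sweep(W^2, 2L, colSums(W^2), `/`)   # (w_aj/||w_a||)^2
  vip <- sqrt(p * as.vector(wn2 %*% ssy) / sum(ssy))
  out <- data.frame(feature_id = model@featureIds, vip = vip,
                    vip_gt1 = vip > 1, stringsAsFactors = FALSE)
  out[order(-out$vip, out$feature_id), , drop = FALSE]
}

#' Select top features from a VIP ranking
#'
#' @param ranking data.frame from \code{\link{vipScores}}.
#' @param mode \code{"vip_gt1"} keeps features with VIP strictly greater
#'   than 1; \code{"top_fraction"} keeps the \code{ceiling(fraction * p)}
#'   largest.
#' @param fraction fraction kept in \code{"top_fraction"} mode (default 0.10).
#' @return character vector of feature ids in descending-VIP order (ties
#'   broken by feature id).
#' @export
selectFeatures <- function(ranking, mode = c("vip_gt1", "top_fraction"),
                           fraction = 0.10) {
  mode <- match.arg(mode)
  stopIf(nrow(ranking) == 0L, "empty ranking")
  ord <- ranking[order(-ranking$vip, ranking$feature_id), , drop = FALSE]
  if (mode == "vip_gt1") ord$feature_id[ord$vip > 1]
  else ord$feature_id[seq_len(min(nrow(ord), ceiling(fraction * nrow(ord))))]
}

#' Accurate-mass adduct annotation
#'
#' Matches each feature m/z against every (compound, adduct) pair: a
#' candidate is retained when
#' \code{|mz - (M + shift)| / (M + shift) * 1e6 <= tol_ppm}.
#' All candidates are kept, ranked by absolute ppm error within feature.
#'
#' @param features data.frame with \code{feature_id} and \code{mz} columns
#'   (e.g. \code{featureData} of a \linkS4class{PeakTable} plus its ids).
#' @param compounds compound table from \code{\link{readCompoundTable}}.
#' @param adducts named numeric vector of adduct mass shifts
#'   (default \code{\link{positiveAdducts}}).
#' @param tol_ppm mass tolerance in parts per million (default 5).
#' @return data.frame with columns \code{feature_id}, \code{compound_id},
#'   \code{name}, \code{adduct}, \code{mass_error_ppm}, \code{msi_level},
#'   \code{plausibility}; zero rows when nothing matches.
#' @export
annotateMz <- function(features, compounds, adducts = positiveAdducts,
                       tol_ppm = 5) {
  stopIf(nrow(compounds) == 0L, "empty compound table")
  stopIf(is.null(names(adducts)), "adducts must be a named numeric vector")
  out <- list()
  for (a in names(adducts)) {
    expected <- compounds$monoisotopic_mass + adducts[[a]]
    for (i in seq_len(nrow(features))) {
      ppm <- (features$mz[i] - expected) / expected * 1e6
      hit <- which(abs(ppm) <= tol_ppm)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          feature_id = features$feature_id[i],
          compound_id = compounds$compound_id[hit],
          name = compounds$name[hit],
          adduct = a,
          mass_error_ppm = ppm[hit],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(feature_id = character(), compound_id = character(),
                      name = character(), adduct = character(),
                      mass_error_ppm = numeric(), msi_level = character(),
                      plausibility = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$feature_id, abs(res$mass_error_ppm)), , drop = FALSE]
  rownames(res) <- NULL
  ## accurate mass alone is putative annotation: MSI level 3 at best
  res$msi_level <- "3"
  res$plausibility <- "plausible"
  res
}

#' Plausibility gating of annotation candidates
#'
#' Applies declarative chromatographic/biological plausibility rules.
#' Candidates failing a rule are relabelled
#' \code{"unknown/unidentified"} (never dropped). The built-in rule type
#' \code{min_rt} flags compound classes eluting implausibly early on a
#' reversed-phase gradient (e.g. a lipid peak within the first two minutes).
#'
#' @param candidates data.frame from \code{\link{annotateMz}}.
#' @param rules list of rules; each rule is a list with \code{type =
#'   "min_rt"}, \code{compound_ids} (ids the rule applies to) and
#'   \code{min_rt} (minutes). An empty rule list is the identity.
#' @param features data.frame with \code{feature_id} and \code{rt}, required
#'   when any rule needs retention times.
#' @return the candidates with updated \code{plausibility}.
#' @export
plausibilityGate <- function(candidates, rules = list(), features = NULL) {
  if (!length(rules) || nrow(candidates) == 0L) return(candidates)
  for (rule in rules) {
    stopIf(!identical(rule$type, "min_rt"),
           "unknown rule type: ", rule$type %||% "<missing>")
    stopIf(is.null(features), "rules of type 'min_rt' need 'features'")
    rt <- features$rt[match(candidates$feature_id, features$feature_id)]
    fail <- candidates$compound_id %in% rule$compound_ids &
      !is.na(rt) & rt < rule$min_rt
    candidates$plausibility[fail] <- "unknown/unidentified"
  }
  candidates
}

#' Ranked, annotated feature report
#'
#' Combines VIP ranking, selection and accurate-mass annotation into the
#' table the workflow reports: one row per selected feature (plus one row per
#' retained annotation candidate).
#'
#' @param model fitted \linkS4class{PLSModel}.
#' @param features data.frame with \code{feature_id}, \code{mz}, \code{rt}.
#' @param compounds compound table.
#' @param mode,fraction see \code{\link{selectFeatures}}.
#' @param tol_ppm annotation tolerance (ppm).
#' @param rules plausibility rules (see \code{\link{plausibilityGate}}).
#' @return data.frame: \code{rank}, \code{feature_id}, \code{vip}, \code{mz},
#'   \code{rt}, and annotation columns (NA for unannotated features).
#' @export
rankAndAnnotate <- function(model, features, compounds,
                            mode = "top_fraction", fraction = 0.10,
                            tol_ppm = 5, rules = list()) {
  ranking <- vipScores(model)
  sel <- selectFeatures(ranking, mode, fraction)
  sub <- ranking[match(sel, ranking$feature_id), , drop = FALSE]
  sub$rank <- seq_len(nrow(sub))
  feats <- features[match(sel, features$feature_id), , drop = FALSE]
  ann <- annotateMz(feats, compounds, tol_ppm = tol_ppm)
  ann <- plausibilityGate(ann, rules, features = feats)
  out <- merge(cbind(sub, mz = feats$mz, rt = feats$rt), ann,
               by = "feature_id", all.x = TRUE, sort = FALSE)
  out[order(out$rank, abs(out$mass_error_ppm), na.last = TRUE), , drop = FALSE]
}
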