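## Mummichog-style pathway enrichment: nonparametric per-feature ranking,
## m/z -> compound mapping via adduct mass matching, per-pathway one-tailed
## Fisher's exact tests with a resampling adjustment, and BH-FDR control.

#' Nonparametric per-feature group tests
#'
#' Ranks every feature by a Mann-Whitney U test (2 groups; exact two-sided p
#' when both groups have <= 8 observations and no ties, normal approximation
#' with tie correction otherwise) or a Kruskal-Wallis test (3+ groups,
#' chi-square p with tie correction).
#'
#' @param X samples x features matrix.
#' @param labels group labels, one per row of X; each group needs >= 2
#'   members.
#' @param feature_ids optional ids (default: column names of X).
#' @return data.frame with \code{feature_id}, \code{statistic} (U or H) and
#'   \code{p_value}.
#' @export
rankFeatures <- function(X, labels, feature_ids = colnames(X)) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopIf(nrow(X) != length(labels), "labels must match rows of X")
  counts <- table(labels)
  small <- names(counts)[counts < 2L]
  stopIf(length(small) > 0, "group(s) with < 2 members: ",
         paste(small, collapse = ", "))
  k <- length(counts)
  feature_ids <- feature_ids %||% sprintf("V%d", seq_len(ncol(X)))
  stat <- p <- numeric(ncol(X))
  if (k == 2L) {
    g1 <- labels == names(counts)[1L]
    for (j in seq_len(ncol(X))) {
      x1 <- X[g1, j]; x2 <- X[!g1, j]
      exact <- length(x1) <= 8L && length(x2) <= 8L &&
        !anyDuplicated(c(x1, x2))
      wt <- suppressWarnings(
        wilcox.test(x1, x2, exact = exact, correct = !exact))
      stat[j] <- unname(wt$statistic)
      p[j] <- wt$p.value
    }
  } else {
    fl <- factor(labels)
    for (j in seq_len(ncol(X))) {
      kw <- kruskal.test(X[, j], fl)
      stat[j] <- unname(kw$statistic)
      p[j] <- kw$p.value
    }
  }
  p[is.na(p)] <- 1   # fully tied feature carries no information
  data.frame(feature_id = feature_ids, statistic = stat, p_value = p,
             stringsAsFactors = FALSE)
}

#' Significant feature set
#'
#' @param ranked data.frame from \code{\link{rankFeatures}}.
#' @param alpha p-value threshold (features with p <= alpha are kept).
#' @param vip_selected optional externally supplied feature ids (e.g. a
#'   VIP > 1 selection); when given it overrides the p-value rule.
#' @return character vector of feature ids.
#' @export
significantSet <- function(ranked, alpha = 0.05, vip_selected = NULL) {
  stopIf(nrow(ranked) == 0L, "empty ranking")
  if (!is.null(vip_selected))
    return(intersect(vip_selected, ranked$feature_id))
  ranked$feature_id[ranked$p_value <= alpha]
}

#' Map features to candidate compounds via adduct mass matching
#'
#' Thin wrapper over \code{\link{annotateMz}}: a feature may hit several
#' compounds (all retained, mummichog-style); each compound enters the
#' returned set once regardless of how many features/adducts hit it.
#'
#' @param feature_ids ids of the features to map.
#' @param features data.frame with \code{feature_id} and \code{mz}.
#' @param compounds compound table.
#' @param adducts,tol_ppm see \code{\link{annotateMz}}.
#' @return list with \code{candidates} (annotation data.frame) and
#'   \code{compound_set} (deduplicated compound ids).
#' @export
mzToCompounds <- function(feature_ids, features, compounds,
                          adducts = positiveAdducts, tol_ppm = 5) {
  sub <- features[features$feature_id %in% feature_ids, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(list(candidates = NULL, compound_set = character()))
  cand <- annotateMz(sub, compounds, adducts, tol_ppm)
  list(candidates = cand, compound_set = unique(cand$compound_id))
}

#' Per-pathway Fisher's exact enrichment tests
#'
#' For each pathway, the 2x2 table (in pathway vs not) x (significant vs not)
#' over the reference compound universe is tested one-tailed for enrichment
#' (hypergeometric upper tail). Expected hits are
#' \code{pathway_size * |sig| / |reference|}.
#'
#' @param sig_compounds significant compound ids (subset of the reference).
#' @param model a \linkS4class{PathwayModel}.
#' @param reference optional reference universe override (default: the
#'   model's universe).
#' @return data.frame: \code{pathway_id}, \code{name}, \code{size},
#'   \code{hits_observed}, \code{hits_expected}, \code{enrichment_ratio},
#'   \code{fet_p}; empty pathways are skipped with a warning.
#' @export
pathwayFET <- function(sig_compounds, model, reference = model@universe) {
  sig <- intersect(unique(sig_compounds), reference)
  N <- length(reference); k <- length(sig)
  rows <- list()
  for (pid in pathwayIds(model)) {
    members <- intersect(pathwayCompounds(model, pid), reference)
    m <- length(members)
    if (m == 0L) { warning("pathway '", pid, "' is empty; skipped"); next }
    hits <- length(intersect(sig, members))
    expected <- m * k / N
    ## one-tailed enrichment p: P(X >= hits), X ~ Hypergeom(m, N - m, k)
    p <- if (k == 0L) 1 else phyper(hits - 1L, m, N - m, k,
                                    lower.tail = FALSE)
    rows[[pid]] <- data.frame(
      pathway_id = pid, name = model@pathways[[pid]]$name, size = m,
      hits_observed = hits, hits_expected = expected,
      enrichment_ratio = if (expected > 0) hits / expected else NA_real_,
      fet_p = min(p, 1), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resampling adjustment of pathway hits
#'
#' Draws \code{n_resamples} random feature sets of the significant set's size
#' from all ranked features, maps each through the same m/z -> compound
#' machinery, and reports per pathway the empirical probability of observing
#' at least as many hits by chance:
#' \code{(1 + #\{null hits >= observed\}) / (n_resamples + 1)}.
#'
#' @param observed data.frame from \code{\link{pathwayFET}}.
#' @param all_features data.frame with \code{feature_id}, \code{mz} of every
#'   ranked feature.
#' @param sig_size size of the significant feature set.
#' @param model a \linkS4class{PathwayModel}.
#' @param compounds compound table.
#' @param adducts,tol_ppm mapping parameters (must match the observed run).
#' @param n_resamples resample count (>= 100).
#' @param seed integer seed.
#' @return \code{observed} with an added \code{resampling_p} column.
#' @export
resamplingAdjust <- function(observed, all_features, sig_size, model,
                             compounds, adducts = positiveAdducts,
                             tol_ppm = 5, n_resamples = 1000L, seed = 1L) {
  stopIf(n_resamples < 100L, "n_resamples must be >= 100")
  stopIf(sig_size > nrow(all_features),
         "sig_size (", sig_size, ") exceeds the number of ranked features (",
         nrow(all_features), ")")
  ## precompute the feature -> compound map once
  map <- annotateMz(all_features, compounds, adducts, tol_ppm)
  by_feat <- split(map$compound_id, map$feature_id)
  members <- lapply(pathwayIds(model), function(pid)
    pathwayCompounds(model, pid))
  names(members) <- pathwayIds(model)
  exceed <- setNames(integer(nrow(observed)), observed$pathway_id)
  withSeed(seed, {
    for (r in seq_len(n_resamples)) {
      draw <- all_features$feature_id[
        sample.int(nrow(all_features), sig_size)]
      cset <- unique(unlist(by_feat[intersect(draw, names(by_feat))],
                            use.names = FALSE))
      for (pid in observed$pathway_id) {
        h <- length(intersect(cset, members[[pid]]))
        if (h >= observed$hits_observed[observed$pathway_id == pid])
          exceed[pid] <- exceed[pid] + 1L
      }
    }
  })
  observed$resampling_p <- (1 + exceed[observed$pathway_id]) /
    (n_resamples + 1)
  observed
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone, capped at 1).
#'
#' @param p numeric p-values in (0, 1].
#' @return numeric q-values, same order as \code{p}.
#' @export
bhFdr <- function(p) {
  stopIf(any(p <= 0 | p > 1, na.rm = TRUE), "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' End-to-end pathway enrichment
#'
#' Ranks features (MW U / KW H), takes the significant set (p <= alpha or an
#' externally supplied VIP selection), maps it to compounds, tests each
#' pathway by one-tailed FET, optionally adds a resampling-adjusted p, and
#' BH-adjusts the FET p-values. Results are ordered by increasing FET p
#' (i.e. decreasing -log10 p, as in a bubble plot).
#'
#' @param X samples x features matrix.
#' @param labels group labels.
#' @param features data.frame with \code{feature_id}, \code{mz}.
#' @param compounds compound table.
#' @param model a \linkS4class{PathwayModel}.
#' @param alpha significance threshold on feature p-values.
#' @param vip_selected optional feature-id selection overriding alpha.
#' @param adducts,tol_ppm mapping parameters.
#' @param n_resamples resampling-adjustment draws (0 to skip).
#' @param seed integer seed for the resampling step.
#' @return data.frame: pathway table with \code{fet_p}, optional
#'   \code{resampling_p}, and \code{fdr_q}.
#' @export
runEnrichment <- function(X, labels, features, compounds, model,
                          alpha = 0.05, vip_selected = NULL,
                          adducts = positiveAdducts, tol_ppm = 5,
                          n_resamples = 0L, seed = 1L) {
  ranked <- rankFeatures(X, labels, feature_ids = features$feature_id)
  sig <- significantSet(ranked, alpha, vip_selected)
  cset <- mzToCompounds(sig, features, compounds, adducts,
                        tol_ppm)$compound_set
  res <- pathwayFET(cset, model)
  if (n_resamples > 0L)
    res <- resamplingAdjust(res, features, length(sig), model, compounds,
                            adducts, tol_ppm, n_resamples, seed)
  res$fdr_q <- bhFdr(res$fet_p)
  res[order(res$fet_p, res$pathway_id), , drop = FALSE]
}
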