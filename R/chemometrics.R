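## PLS-DA classification with bootstrap resampling and permutation null
## models.
##
## The discriminant model is PLS2 regression of a centred one-hot class
## indicator matrix on the centred intensity matrix, computed with NIPALS,
## classifying by the argmax of the predicted indicator columns. Validation
## draws bootstrap resamples as training sets and uses the out-of-bag samples
## as test sets; null models repeat the same cycle with permuted class
## labels.

#' Resampling configuration for PLS-DA validation
#'
#' @param n_boot bootstrap iterations (study default 1000).
#' @param n_perm permutation-null iterations (study default 1000).
#' @param seed master seed; each iteration derives its own substream.
#' @param max_components upper bound on the PLS component count explored by
#'   the inner cross-validation.
#' @param inner_cv_folds folds of the inner CV used to pick the component
#'   count on each training set.
#' @param smote \code{"off"} (default), \code{"fold"} (SMOTE applied to each
#'   bootstrap training set only — no leakage into the test set) or
#'   \code{"global"} (SMOTE applied once to the full data before resampling,
#'   as some studies do; leaks synthetic points into test sets).
#' @param k_neighbors SMOTE neighbourhood size.
#' @return list of class \code{"BootstrapConfig"}.
#' @export
bootstrapConfig <- function(n_boot = 1000L, n_perm = 1000L, seed = 1L,
                            max_components = 15L, inner_cv_folds = 7L,
                            smote = c("off", "fold", "global"),
                            k_neighbors = 5L) {
  smote <- match.arg(smote)
  stopIf(n_boot < 1 || n_perm < 0, "n_boot must be >= 1 and n_perm >= 0")
  structure(list(n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 max_components = as.integer(max_components),
                 inner_cv_folds = as.integer(inner_cv_folds),
                 smote = smote, k_neighbors = as.integer(k_neighbors)),
            class = "BootstrapConfig")
}

oneHot <- function(y, classes = sort(unique(y))) {
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

#' Fit a PLS2 discriminant model by NIPALS
#'
#' Regresses the centred one-hot indicator matrix of \code{y} on centred
#' \code{X}. Components are extracted by NIPALS with deflation of both
#' blocks; each weight vector is normalised and given a deterministic sign
#' (its largest-magnitude element is positive).
#'
#' @param X numeric matrix, samples x features (already preprocessed; the
#'   fit centres but does not rescale).
#' @param y class labels (>= 2 classes).
#' @param ncomp number of components A, at most \code{min(n - 1, p)}.
#' @return a \linkS4class{PLSModel}.
#' @export
fitPLS <- function(X, y, ncomp = 2L) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopIf(nrow(X) != length(y), "nrow(X) must equal length(y)")
  classes <- sort(unique(y))
  stopIf(length(classes) < 2L, "need at least 2 classes, got ",
         length(classes))
  n <- nrow(X); p <- ncol(X)
  stopIf(ncomp > min(n - 1L, p),
         "ncomp = ", ncomp, " exceeds min(n - 1, p) = ", min(n - 1L, p))
  Y <- oneHot(y, classes)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)

  A <- as.integer(ncomp)
  W <- P <- matrix(0, p, A)
  TT <- matrix(0, n, A)
  Q <- matrix(0, ncol(Y), A)
  a_done <- 0L
  for (a in seq_len(A)) {
    ## NIPALS power iteration for the dominant weight vector. The u/w
    ## alternation contracts to q <- (Y'X)(X'Y) q up to normalisation, so we
    ## iterate on that k x k problem (k = number of classes) and recover
    ## w = X'Y q afterwards: same fixed point, one O(npk) product per
    ## component instead of per iteration.
    Z <- crossprod(Xc, Yc)                   # p x k
    M <- crossprod(Z)                        # k x k
    if (max(abs(M)) < 1e-24) break
    q <- M[, which.max(diag(M))]
    q <- q / sqrt(sum(q^2))
    for (it in seq_len(1000L)) {
      q_new <- M %*% q
      nq <- sqrt(sum(q_new^2))
      if (nq < 1e-300) break
      q_new <- as.vector(q_new) / nq
      if (sum((q_new - q)^2) < 1e-24) { q <- q_new; break }
      q <- q_new
    }
    w <- as.vector(Z %*% q)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_new <- as.vector(Xc %*% w)
    if (sum(t_new^2) < 1e-12) break
    if (w[which.max(abs(w))] < 0) { w <- -w; t_new <- -t_new }
    q_load <- as.vector(crossprod(Yc, t_new)) / sum(t_new^2)
    pl <- as.vector(crossprod(Xc, t_new)) / sum(t_new^2)
    W[, a] <- w; TT[, a] <- t_new; P[, a] <- pl; Q[, a] <- q_load
    Xc <- Xc - tcrossprod(t_new, pl)
    Yc <- Yc - tcrossprod(t_new, q_load)
    a_done <- a
  }
  stopIf(a_done == 0L, "no PLS component could be extracted (X is constant?)")
  if (a_done < A) {
    warning("only ", a_done, " of ", A, " components extractable; truncating")
    W <- W[, seq_len(a_done), drop = FALSE]
    P <- P[, seq_len(a_done), drop = FALSE]
    TT <- TT[, seq_len(a_done), drop = FALSE]
    Q <- Q[, seq_len(a_done), drop = FALSE]
  }
  R <- W %*% solve(crossprod(P, W))          # projection: T_new = Xc R
  B <- R %*% t(Q)
  new("PLSModel", weights = W, loadings = P, scores = TT, yloadings = Q,
      coefficients = B, xmeans = xm, ymeans = ym, classes = classes,
      ncomp = a_done,
      featureIds = colnames(X) %||% sprintf("V%d", seq_len(p)))
}

#' Predicted class indicator matrix
#'
#' @param model a \linkS4class{PLSModel}.
#' @param X new samples x features matrix (same feature count/order as
#'   training).
#' @param ncomp number of components to use (default: all fitted).
#' @return n x k matrix of predicted indicator values.
#' @export
predictScores <- function(model, X, ncomp = model@ncomp) {
  X <- as.matrix(X)
  stopIf(ncol(X) != length(model@xmeans),
         "feature count mismatch: model has ", length(model@xmeans),
         ", new data has ", ncol(X))
  stopIf(ncomp < 1L || ncomp > model@ncomp, "invalid ncomp")
  Xc <- sweep(X, 2L, model@xmeans)
  W <- model@weights[, seq_len(ncomp), drop = FALSE]
  P <- model@loadings[, seq_len(ncomp), drop = FALSE]
  Q <- model@yloadings[, seq_len(ncomp), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  Yhat <- Xc %*% R %*% t(Q)
  sweep(Yhat, 2L, model@ymeans, `+`)
}

#' Predict class labels
#'
#' Assigns each sample the class whose predicted indicator column is largest;
#' exact ties resolve to the lexicographically first class label.
#'
#' @inheritParams predictScores
#' @return character vector of class labels.
#' @export
predictClasses <- function(model, X, ncomp = model@ncomp) {
  Yhat <- predictScores(model, X, ncomp)
  model@classes[apply(Yhat, 1L, which.max)]
}

#' Classification metrics
#'
#' \code{ccr}: percent of samples assigned their true class.
#' \code{classwiseRates}: per-class recall in percent.
#' \code{macroMetrics}: macro-averaged one-vs-rest sensitivity and
#' specificity, plus overall accuracy, in percent.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes label set defining the averaging (default: classes present
#'   in \code{truth}).
#' @return \code{ccr}: scalar percent; \code{classwiseRates}: named percent
#'   vector; \code{macroMetrics}: named vector (sensitivity, specificity,
#'   accuracy).
#' @export
ccr <- function(truth, predicted) {
  stopIf(length(truth) != length(predicted),
         "truth and predicted lengths differ")
  100 * mean(truth == predicted)
}

#' @rdname ccr
#' @export
classwiseRates <- function(truth, predicted, classes = sort(unique(truth))) {
  vapply(classes, function(cl) {
    idx <- truth == cl
    if (!any(idx)) return(NA_real_)
    100 * mean(predicted[idx] == cl)
  }, numeric(1))
}

#' @rdname ccr
#' @export
macroMetrics <- function(truth, predicted, classes = sort(unique(truth))) {
  sens <- spec <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- sum(truth != cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    sens[i] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec[i] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  c(sensitivity = mean(sens, na.rm = TRUE),
    specificity = mean(spec, na.rm = TRUE),
    accuracy = 100 * mean(truth == predicted))
}

#' SMOTE class balancing
#'
#' Upsamples every minority class to the majority class size. Each synthetic
#' point is \code{x_i + u * (x_nn - x_i)} with \code{u ~ Uniform(0, 1)} and
#' \code{x_nn} one of the \code{k_neighbors} nearest same-class neighbours
#' (Euclidean distance). Synthetic points therefore lie on segments between
#' minority points and never leave their convex hull.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param k_neighbors neighbourhood size; reduced with a warning when a
#'   minority class has fewer than \code{k_neighbors + 1} members.
#' @param seed integer seed.
#' @return list with balanced \code{X} and \code{y} (original rows first,
#'   synthetic rows appended).
#' @export
smoteOversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.character(y)
  sizes <- table(y)
  target <- max(sizes)
  if (all(sizes == target)) return(list(X = X, y = y))
  withSeed(seed, {
    add_X <- list(); add_y <- character()
    for (cl in names(sizes)) {
      need <- target - sizes[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      stopIf(length(idx) < 2L,
             "class '", cl, "' has a single member; SMOTE needs >= 2")
      k <- k_neighbors
      if (length(idx) <= k) {
        k <- length(idx) - 1L
        warning("class '", cl, "': k_neighbors reduced to ", k)
      }
      Xc <- X[idx, , drop = FALSE]
      d <- as.matrix(dist(Xc))
      diag(d) <- Inf
      nn <- apply(d, 1L, function(v) order(v)[seq_len(k)])
      nn <- matrix(nn, nrow = k)             # k x n_c
      base <- sample.int(length(idx), need, replace = TRUE)
      pick <- vapply(base, function(b) nn[sample.int(k, 1L), b], integer(1))
      u <- runif(need)
      synth <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      rownames(synth) <- sprintf("synth_%s_%d", cl, seq_len(need))
      add_X[[cl]] <- synth
      add_y <- c(add_y, rep(cl, need))
    }
    list(X = rbind(X, do.call(rbind, add_X)), y = c(y, add_y))
  })
}

## Predicted labels at every component count 1..A in one pass: the predicted
## indicator matrix grows by rank-1 updates T_new[, a] q_a' per component.
predictClassesAll <- function(model, X) {
  Xc <- sweep(as.matrix(X), 2L, model@xmeans)
  A <- model@ncomp
  R <- model@weights %*% solve(crossprod(model@loadings, model@weights))
  Tn <- Xc %*% R
  Yhat <- matrix(rep(model@ymeans, each = nrow(Xc)), nrow(Xc))
  out <- matrix(NA_character_, nrow(Xc), A)
  for (a in seq_len(A)) {
    Yhat <- Yhat + tcrossprod(Tn[, a], model@yloadings[, a])
    out[, a] <- model@classes[apply(Yhat, 1L, which.max)]
  }
  out
}

## Inner CV on a training set: pick the component count in 1..max_a that
## minimises CV misclassifications (ties -> fewest components). One fit per
## fold at max_a; predictions for every smaller a come from the same fit.
chooseNcomp <- function(X, y, max_a, folds) {
  n <- nrow(X)
  max_a <- min(max_a, ncol(X), n - ceiling(n / folds) - 1L)
  if (max_a < 2L) return(max(max_a, 1L))
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  errs <- rep(0L, max_a)
  for (fd in seq_len(folds)) {
    tr <- fold_id != fd
    if (length(unique(y[tr])) < 2L) next
    fit <- tryCatch(fitPLS(X[tr, , drop = FALSE], y[tr],
                           min(max_a, sum(tr) - 1L)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pred <- predictClassesAll(fit, X[!tr, , drop = FALSE])
    for (a in seq_len(max_a))
      errs[a] <- errs[a] + sum(pred[, min(a, fit@ncomp)] != y[!tr])
  }
  which.min(errs)
}

## One bootstrap fit/test cycle: resample training with replacement, fit on
## it (component count by inner CV), test on the out-of-bag samples.
## Degenerate draws (empty OOB or single-class training) are redrawn.
bootCycle <- function(X, y, config) {
  n <- nrow(X)
  for (attempt in seq_len(100L)) {
    tr <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(tr))
    if (length(oob) == 0L || length(unique(y[tr])) < 2L) next
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (config$smote == "fold") {
      bal <- smoteOversample(Xtr, ytr, config$k_neighbors,
                             seed = sample.int(.Machine$integer.max - 1L, 1L))
      Xtr <- bal$X; ytr <- bal$y
    }
    a <- chooseNcomp(Xtr, ytr, config$max_components, config$inner_cv_folds)
    fit <- fitPLS(Xtr, ytr, a)
    pred <- predictClasses(fit, X[oob, , drop = FALSE])
    return(list(truth = y[oob], pred = pred, redraws = attempt - 1L))
  }
  stop("could not draw a usable bootstrap resample in 100 attempts",
       call. = FALSE)
}

#' Bootstrap validation of a PLS-DA classifier
#'
#' Runs \code{config$n_boot} bootstrap iterations. Each iteration resamples
#' the data with replacement as a training set, optionally SMOTE-balances the
#' training set, picks the component count by inner cross-validation, fits
#' the model and scores the out-of-bag samples. Returns the full distribution
#' of test-set CCRs plus class-wise rates and macro metrics averaged over
#' iterations. Reproducible: the master seed spawns one substream per
#' iteration.
#'
#' @param X samples x features matrix (preprocessed).
#' @param y class labels.
#' @param config a \code{\link{bootstrapConfig}}.
#' @return a \linkS4class{ValidationSummary} with an empty null distribution
#'   (see \code{\link{permutationNull}} / \code{\link{validatePLSDA}}).
#' @export
bootstrapValidate <- function(X, y, config = bootstrapConfig()) {
  X <- as.matrix(X); y <- as.character(y)
  classes <- sort(unique(y))
  if (config$smote == "global") {
    bal <- smoteOversample(X, y, config$k_neighbors, seed = config$seed)
    X <- bal$X; y <- bal$y
  }
  seeds <- spawnSeeds(config$seed, config$n_boot)
  obs <- numeric(config$n_boot)
  cls <- matrix(NA_real_, config$n_boot, length(classes),
                dimnames = list(NULL, classes))
  mm <- matrix(NA_real_, config$n_boot, 3L)
  for (i in seq_len(config$n_boot)) {
    res <- withSeed(seeds[i], bootCycle(X, y, config))
    obs[i] <- ccr(res$truth, res$pred)
    cls[i, ] <- classwiseRates(res$truth, res$pred, classes)
    mm[i, ] <- macroMetrics(res$truth, res$pred, classes)
  }
  new("ValidationSummary",
      observed_ccr = obs, null_ccr = numeric(), mean_ccr = mean(obs),
      classwise_ccr = colMeans(cls, na.rm = TRUE),
      sensitivity = mean(mm[, 1L], na.rm = TRUE),
      specificity = mean(mm[, 2L], na.rm = TRUE),
      accuracy = mean(mm[, 3L], na.rm = TRUE),
      empirical_p = NA_real_, n_boot = config$n_boot, n_perm = 0L,
      seed = config$seed)
}

#' Permutation null distribution of test-set CCRs
#'
#' For each of \code{config$n_perm} iterations the class labels are randomly
#' permuted and one bootstrap fit/test cycle is run, recording the out-of-bag
#' CCR. The empirical p-value of an observed mean CCR is
#' \code{(1 + #\{null >= observed\}) / (n_perm + 1)}.
#'
#' @inheritParams bootstrapValidate
#' @param observed_mean optional observed mean CCR (percent) for which to
#'   report the empirical p-value.
#' @return list with \code{null_ccr} (percent, length \code{n_perm}) and
#'   \code{empirical_p} (NA when \code{observed_mean} is not given).
#' @export
permutationNull <- function(X, y, config = bootstrapConfig(),
                            observed_mean = NULL) {
  X <- as.matrix(X); y <- as.character(y)
  seeds <- spawnSeeds(config$seed + 1L, config$n_perm)
  null_ccr <- numeric(config$n_perm)
  for (i in seq_len(config$n_perm)) {
    null_ccr[i] <- withSeed(seeds[i], {
      yp <- sample(y)
      res <- bootCycle(X, yp, config)
      ccr(res$truth, res$pred)
    })
  }
  p <- if (is.null(observed_mean)) NA_real_
       else (1 + sum(null_ccr >= observed_mean)) / (config$n_perm + 1)
  list(null_ccr = null_ccr, empirical_p = p)
}

#' Full bootstrap + permutation validation
#'
#' Convenience wrapper: runs \code{\link{bootstrapValidate}} and
#' \code{\link{permutationNull}} and returns one
#' \linkS4class{ValidationSummary} with both distributions and the empirical
#' p-value of the observed mean CCR.
#'
#' @inheritParams bootstrapValidate
#' @return a \linkS4class{ValidationSummary}.
#' @export
validatePLSDA <- function(X, y, config = bootstrapConfig()) {
  vs <- bootstrapValidate(X, y, config)
  if (config$n_perm > 0L) {
    nul <- permutationNull(X, y, config, observed_mean = vs@mean_ccr)
    vs@null_ccr <- nul$null_ccr
    vs@empirical_p <- nul$empirical_p
    vs@n_perm <- config$n_perm
  }
  vs
}

#' PCA scores
#'
#' SVD-based principal component analysis (columns are mean-centred; no
#' rescaling, matching use on Pareto-scaled data).
#'
#' @param X samples x features matrix.
#' @param n_pc number of components to return.
#' @return list with \code{scores} (samples x n_pc) and
#'   \code{explained} (variance fractions, length n_pc).
#' @export
pcaScores <- function(X, n_pc = 2L) {
  X <- as.matrix(X)
  n_pc <- min(n_pc, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pc)])
}

#' Extract the classification matrix and labels from a PeakTable
#'
#' @param x a preprocessed \linkS4class{PeakTable}.
#' @param target colData column holding the class labels
#'   (\code{"ethnicity"}, \code{"age_band2"}, \code{"age_band4"}, ...).
#' @return list with \code{X} (samples x features) and \code{y} (labels);
#'   QC/blank injections and samples with missing labels are dropped.
#' @export
classMatrix <- function(x, target = "ethnicity") {
  sd_ <- sampleData(x)
  stopIf(!target %in% colnames(sd_), "no colData column '", target, "'")
  keep <- sd_$sample_type == "sample" & !is.na(sd_[[target]])
  list(X = t(intensities(x)[, keep, drop = FALSE]),
       y = as.character(sd_[[target]][keep]))
}
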