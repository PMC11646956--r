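## Synthetic cohorts and peak tables with recorded ground truth.
##
## The generator emulates the downstream form of a multi-batch untargeted
## serum metabolomics experiment: a three-group male cohort (White European /
## South Asian / African Caribbean, 287/143/142 by default, ages 40-86),
## log-normal feature intensities with smooth multiplicative within-batch
## signal drift, pooled-QC injections interleaved by injection order, blank
## injections, intensity-dependent missing values, and a planted subset of
## class-discriminative features whose identities are recorded for recovery
## tests.

#' Cohort specification
#'
#' Defaults reproduce the demographic structure of the study cohort the
#' package is designed around: three ethnic groups of 287/143/142 men with
#' group age means 63.66/56.97/54.01 (SD 10.68/11.12/10.63) years truncated
#' to [40, 86], and BMI 27.47/27.75/27.80 (SD 3.89/3.70/4.86) kg/m^2.
#'
#' @param group_sizes named integer vector: samples per group.
#' @param age_mean_sd named list of c(mean, sd) per group, years.
#' @param bmi_mean_sd named list of c(mean, sd) per group, kg/m^2.
#' @param age_range truncation bounds for ages, years.
#' @param covariate_rates named list per group with elements \code{alcohol},
#'   \code{smoking}, \code{morbid} (Bernoulli probabilities) and
#'   \code{alcohol_missing} (probability that alcohol status is unrecorded).
#' @param seed integer seed making generation reproducible.
#' @return a list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(
    group_sizes = c(WE = 287L, SA = 143L, AC = 142L),
    age_mean_sd = list(WE = c(63.66, 10.68), SA = c(56.97, 11.12),
                       AC = c(54.01, 10.63)),
    bmi_mean_sd = list(WE = c(27.47, 3.89), SA = c(27.75, 3.70),
                       AC = c(27.80, 4.86)),
    age_range = c(40, 86),
    covariate_rates = list(
      WE = list(alcohol = 74 / 215, alcohol_missing = 72 / 287,
                smoking = 21 / 287, morbid = 150 / 287),
      SA = list(alcohol = 141 / 143, alcohol_missing = 0,
                smoking = 22 / 142, morbid = 86 / 143),
      AC = list(alcohol = 128 / 142, alcohol_missing = 0,
                smoking = 21 / 142, morbid = 60 / 142)),
    seed = 1L) {
  stopIf(is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))),
         "group_sizes must be named")
  stopIf(any(group_sizes <= 0), "all group sizes must be > 0")
  for (g in names(group_sizes)) {
    stopIf(is.null(age_mean_sd[[g]]) || is.null(bmi_mean_sd[[g]]),
           "missing age/BMI parameters for group '", g, "'")
    stopIf(age_mean_sd[[g]][2L] <= 0 || bmi_mean_sd[[g]][2L] <= 0,
           "SDs must be > 0 (group '", g, "')")
  }
  structure(list(group_sizes = group_sizes, age_mean_sd = age_mean_sd,
                 bmi_mean_sd = bmi_mean_sd, age_range = age_range,
                 covariate_rates = covariate_rates, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Derive age-band labels
#'
#' @param age numeric ages in years.
#' @param bands \code{"two"} for <60 vs >=60, \code{"four"} for 10-year bands
#'   40-49.99 / 50-59.99 / 60-69.99 / >=70.
#' @return character labels.
#' @export
ageBand <- function(age, bands = c("two", "four")) {
  bands <- match.arg(bands)
  if (bands == "two") ifelse(age < 60, "<60", ">=60")
  else cut(age, breaks = c(-Inf, 50, 60, 70, Inf), right = FALSE,
           labels = c("40-49.99", "50-59.99", "60-69.99", ">=70")) |>
    as.character()
}

#' Generate a synthetic cohort
#'
#' Draws one sample record per subject: group label, truncated-normal age
#' (with derived two-band and four-band age labels), normal BMI, and binary
#' covariates (alcohol, smoking, morbidity) at the group rates of the spec.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return data.frame with columns \code{sample_id}, \code{ethnicity},
#'   \code{age}, \code{age_band2}, \code{age_band4}, \code{bmi},
#'   \code{alcohol}, \code{smoking}, \code{morbid}.
#' @examples
#' nrow(simulateCohort(cohortSpec()))   # 572
#' @export
simulateCohort <- function(spec) {
  stopIf(!inherits(spec, "CohortSpec"), "'spec' must be a CohortSpec")
  withSeed(spec$seed, {
    groups <- rep(names(spec$group_sizes), spec$group_sizes)
    n <- length(groups)
    age <- bmi <- numeric(n)
    alcohol <- smoking <- morbid <- logical(n)
    alc_missing <- logical(n)
    for (g in names(spec$group_sizes)) {
      idx <- which(groups == g)
      a <- spec$age_mean_sd[[g]]
      b <- spec$bmi_mean_sd[[g]]
      age[idx] <- rtruncnorm(length(idx), a[1L], a[2L],
                             spec$age_range[1L], spec$age_range[2L])
      bmi[idx] <- rnorm(length(idx), b[1L], b[2L])
      cr <- spec$covariate_rates[[g]] %||%
        list(alcohol = 0.5, alcohol_missing = 0, smoking = 0.1, morbid = 0.5)
      alcohol[idx] <- runif(length(idx)) < cr$alcohol
      alc_missing[idx] <- runif(length(idx)) < (cr$alcohol_missing %||% 0)
      smoking[idx] <- runif(length(idx)) < cr$smoking
      morbid[idx] <- runif(length(idx)) < cr$morbid
    }
    alcohol[alc_missing] <- NA
    data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      ethnicity = groups,
      age = age,
      age_band2 = ageBand(age, "two"),
      age_band4 = ageBand(age, "four"),
      bmi = bmi, alcohol = alcohol, smoking = smoking, morbid = morbid,
      stringsAsFactors = FALSE)
  })
}

#' Acquisition-run specification
#'
#' @param n_features number of features in the peak table.
#' @param n_batches number of acquisition batches.
#' @param qc_interval study-sample injections between pooled-QC injections
#'   (>= 2); each batch additionally opens and closes with a QC.
#' @param drift_amplitude maximum relative intensity deviation of the smooth
#'   within-batch drift (0 disables drift).
#' @param noise_cv technical coefficient of variation of QC/blank replicate
#'   intensities (fraction).
#' @param bio_sd biological between-subject SD of log10 intensities.
#' @param missing_rate overall fraction of cells set missing
#'   (intensity-dependent: low intensities are censored preferentially).
#' @param blank_level blank signal as a fraction of the median sample signal.
#' @param n_blanks_per_batch extraction-blank injections per batch.
#' @param mz_range,rt_range m/z (Da) and retention-time (minutes) ranges.
#' @param platform \code{"LC"} or \code{"GC"} label stamped on features.
#' @return a list of class \code{"RunSpec"}.
#' @export
runSpec <- function(n_features = 200L, n_batches = 4L, qc_interval = 10L,
                    drift_amplitude = 0.1, noise_cv = 0.05, bio_sd = 0.2,
                    missing_rate = 0.05, blank_level = 0.02,
                    n_blanks_per_batch = 2L,
                    mz_range = c(70, 1050), rt_range = c(0.5, 15),
                    platform = c("LC", "GC")) {
  platform <- match.arg(platform)
  stopIf(missing_rate < 0 || missing_rate >= 1,
         "missing_rate must be in [0, 1)")
  stopIf(qc_interval < 2, "qc_interval must be >= 2")
  stopIf(n_features < 1 || n_batches < 1, "counts must be positive")
  structure(list(n_features = as.integer(n_features),
                 n_batches = as.integer(n_batches),
                 qc_interval = as.integer(qc_interval),
                 drift_amplitude = drift_amplitude, noise_cv = noise_cv,
                 bio_sd = bio_sd, missing_rate = missing_rate,
                 blank_level = blank_level,
                 n_blanks_per_batch = as.integer(n_blanks_per_batch),
                 mz_range = mz_range, rt_range = rt_range,
                 platform = platform),
            class = "RunSpec")
}

#' Planted class-effect specification
#'
#' @param n_discriminative number of features given a class-specific mean
#'   shift (must not exceed the run's feature count).
#' @param effect_log10 mean shift on the log10-intensity scale added to the
#'   affected class of each planted feature.
#' @param affected_classes class labels eligible to receive shifts
#'   (default: all groups present in the cohort); planted features are
#'   assigned to these classes in rotation.
#' @param target class variable the effect discriminates
#'   (\code{"ethnicity"}, \code{"age_band2"} or \code{"age_band4"}).
#' @return a list of class \code{"EffectSpec"}.
#' @export
effectSpec <- function(n_discriminative = 10L, effect_log10 = 0.3,
                       affected_classes = NULL, target = "ethnicity") {
  stopIf(n_discriminative < 0, "n_discriminative must be >= 0")
  structure(list(n_discriminative = as.integer(n_discriminative),
                 effect_log10 = effect_log10,
                 affected_classes = affected_classes, target = target),
            class = "EffectSpec")
}

## Smooth multiplicative drift: cubic polynomial in scaled injection order
## with random coefficients, normalised so the maximum deviation over the
## batch equals drift_amplitude, floored away from zero so it remains a
## valid divisor.
driftCurve <- function(order_scaled, amplitude) {
  cf <- rnorm(3L)
  poly <- cf[1L] * order_scaled + cf[2L] * order_scaled^2 +
    cf[3L] * order_scaled^3
  mx <- max(abs(poly))
  if (mx < .Machine$double.eps || amplitude == 0)
    return(list(values = rep(1, length(order_scaled)), coef = cf * 0))
  list(values = pmax(1 + amplitude * poly / mx, 0.2),
       coef = cf * amplitude / mx)
}

#' Generate a synthetic peak table with known ground truth
#'
#' Builds the injection sequence (per batch: blanks, an opening QC, study
#' samples with a pooled QC every \code{qc_interval} injections, a closing
#' QC), draws log-normal baseline intensities with biological scatter for
#' samples, sets pooled-QC rows to the cohort mean profile with technical
#' noise, blank rows to \code{blank_level} of the median sample signal,
#' applies a smooth multiplicative per-batch drift to every injection, plants
#' class-discriminative mean shifts, and censors low intensities to reach the
#' requested missing rate.
#'
#' @param cohort data.frame from \code{\link{simulateCohort}}.
#' @param run a \code{\link{runSpec}}.
#' @param effects an \code{\link{effectSpec}}.
#' @param seed integer seed; the same seed reproduces the table bit for bit.
#' @param compound_masses optional numeric vector of neutral monoisotopic
#'   masses; when given, features are anchored in rotation to these masses
#'   (observed m/z = mass + 1.007276, protonated) so that annotation and
#'   enrichment can recover them.
#' @return list with elements \code{table} (a \linkS4class{PeakTable}) and
#'   \code{truth} (class \code{"SyntheticTruth"}: planted feature ids and
#'   their affected class, per-sample labels, drift coefficients per batch,
#'   and the seed).
#' @export
simulatePeakTable <- function(cohort, run, effects = effectSpec(0),
                              seed = 1L, compound_masses = NULL) {
  stopIf(nrow(cohort) == 0L, "cohort is empty")
  stopIf(effects$n_discriminative > run$n_features,
         "more discriminative features requested (",
         effects$n_discriminative, ") than features (", run$n_features, ")")
  withSeed(seed, {
    p <- run$n_features
    fid <- sprintf("F%04d", seq_len(p))
    mz <- runif(p, run$mz_range[1L], run$mz_range[2L])
    if (!is.null(compound_masses) && length(compound_masses)) {
      anchor <- seq_len(min(p, length(compound_masses)))
      mz[anchor] <- compound_masses[anchor] + 1.007276
    }
    rt <- runif(p, run$rt_range[1L], run$rt_range[2L])
    mu <- runif(p, 4, 7)                     # baseline log10 intensity

    ## injection sequence ---------------------------------------------------
    n <- nrow(cohort)
    batch_of <- sort(rep_len(seq_len(run$n_batches), n))
    shuffled <- sample.int(n)                # randomised acquisition order
    rows <- list()
    for (b in seq_len(run$n_batches)) {
      sidx <- shuffled[batch_of == b]
      seqb <- character()
      if (run$n_blanks_per_batch > 0)
        seqb <- paste0("blank", seq_len(run$n_blanks_per_batch))
      seqb <- c(seqb, "QC")
      for (i in seq_along(sidx)) {
        seqb <- c(seqb, paste0("sample", sidx[i]))
        if (i %% run$qc_interval == 0 && i < length(sidx))
          seqb <- c(seqb, "QC")
      }
      seqb <- c(seqb, "QC")
      rows[[b]] <- data.frame(what = seqb, batch = b,
                              injection_order = seq_along(seqb),
                              stringsAsFactors = FALSE)
    }
    inj <- do.call(rbind, rows)
    inj$sample_type <- ifelse(grepl("^sample", inj$what), "sample",
                              ifelse(inj$what == "QC", "QC", "blank"))
    inj$cohort_idx <- NA_integer_
    is_s0 <- inj$sample_type == "sample"
    inj$cohort_idx[is_s0] <- as.integer(sub("^sample", "", inj$what[is_s0]))
    qc_n <- cumsum(inj$sample_type == "QC")
    bl_n <- cumsum(inj$sample_type == "blank")
    inj$sample_id <- ifelse(inj$sample_type == "sample",
                            cohort$sample_id[inj$cohort_idx],
                            ifelse(inj$sample_type == "QC",
                                   sprintf("QC%03d", qc_n),
                                   sprintf("BL%03d", bl_n)))

    ## planted effects ------------------------------------------------------
    target <- effects$target
    labels <- cohort[[target]]
    stopIf(is.null(labels), "cohort lacks target column '", target, "'")
    classes <- effects$affected_classes %||% sort(unique(labels))
    planted <- if (effects$n_discriminative > 0)
      sort(sample.int(p, effects$n_discriminative)) else integer()
    planted_class <- if (length(planted))
      rep_len(classes, length(planted)) else character()

    ## sample intensities (log10 scale) -------------------------------------
    logm <- matrix(rep(mu, n), nrow = p)     # p x n, baseline
    if (length(planted)) for (i in seq_along(planted)) {
      hit <- labels == planted_class[i]
      logm[planted[i], hit] <- logm[planted[i], hit] + effects$effect_log10
    }
    logm <- logm + matrix(rnorm(p * n, 0, run$bio_sd), nrow = p)
    samp_int <- 10^logm                      # columns follow cohort order

    ## assemble full matrix in injection order ------------------------------
    m <- matrix(NA_real_, nrow = p, ncol = nrow(inj),
                dimnames = list(fid, inj$sample_id))
    is_s <- inj$sample_type == "sample"
    m[, is_s] <- samp_int[, inj$cohort_idx[is_s]]
    pool_mean <- rowMeans(samp_int)          # pooled QC = mean profile
    med_samp <- apply(samp_int, 1L, median)
    for (j in which(!is_s)) {
      base <- if (inj$sample_type[j] == "QC") pool_mean
              else run$blank_level * med_samp
      noise <- if (run$noise_cv > 0) exp(rnorm(p, 0, run$noise_cv)) else 1
      m[, j] <- base * noise
    }

    ## multiplicative smooth drift per batch --------------------------------
    drift_coef <- list()
    drift_values <- numeric(nrow(inj))
    for (b in seq_len(run$n_batches)) {
      jb <- which(inj$batch == b)
      o <- inj$injection_order[jb]
      u <- if (length(o) > 1) 2 * (o - min(o)) / (max(o) - min(o)) - 1 else 0
      dc <- driftCurve(u, run$drift_amplitude)
      drift_coef[[b]] <- dc$coef
      drift_values[jb] <- dc$values
      m[, jb] <- sweep(m[, jb, drop = FALSE], 2L, dc$values, `*`)
    }

    ## intensity-dependent missingness ---------------------------------------
    if (run$missing_rate > 0) {
      z <- (log10(m) - mean(log10(m))) / sd(log10(m))
      f <- function(a) mean(plogis(a - z)) - run$missing_rate
      a <- uniroot(f, c(-50, 50))$root
      drop <- matrix(runif(length(m)) < plogis(a - z), nrow = p)
      m[drop] <- NA
    }

    samples <- data.frame(
      sample_type = inj$sample_type, batch = inj$batch,
      injection_order = inj$injection_order, stringsAsFactors = FALSE)
    for (col in c("ethnicity", "age", "age_band2", "age_band4", "bmi",
                  "alcohol", "smoking", "morbid")) {
      v <- cohort[[col]][inj$cohort_idx]
      samples[[col]] <- v
    }
    rownames(samples) <- inj$sample_id
    features <- data.frame(mz = mz, rt = rt, platform = run$platform,
                           row.names = fid)
    tab <- PeakTable(m, features = features, samples = samples)
    tab <- logProvenance(tab, "simulate", seed = seed,
                         n_features = p, n_samples = n)
    truth <- structure(list(
      planted_ids = fid[planted],
      planted_class = setNames(planted_class, fid[planted]),
      target = target,
      labels = setNames(labels, cohort$sample_id),
      drift_coef = drift_coef,
      baseline_log10 = setNames(mu, fid),
      seed = seed), class = "SyntheticTruth")
    list(table = tab, truth = truth)
  })
}

#' Study presets for the synthetic generator
#'
#' \code{"paper"} mirrors the study scale (1758 LC or 1253 GC features,
#' 572 subjects); \code{"small"} keeps the cohort but uses 200 features so
#' the full pipeline runs in seconds. Both use 4 batches with a pooled QC
#' every 10 study injections — typical values, since batch structure is a
#' property of the acquisition run, not of the cohort.
#'
#' @param name \code{"small"} or \code{"paper"}.
#' @param platform \code{"LC"} or \code{"GC"}.
#' @param seed seed stored in the cohort spec.
#' @return list with elements \code{cohort} (CohortSpec), \code{run}
#'   (RunSpec) and \code{effects} (EffectSpec).
#' @export
synthPreset <- function(name = c("small", "paper"),
                        platform = c("LC", "GC"), seed = 1L) {
  name <- match.arg(name)
  platform <- match.arg(platform)
  nf <- if (name == "paper") {
    if (platform == "LC") 1758L else 1253L
  } else 200L
  run <- runSpec(n_features = nf, platform = platform,
                 mz_range = if (platform == "LC") c(70, 1050) else c(50, 550),
                 rt_range = if (platform == "LC") c(0.5, 15) else c(1, 14.42))
  list(cohort = cohortSpec(seed = seed),
       run = run,
       effects = effectSpec(n_discriminative = as.integer(round(0.05 * nf)),
                            effect_log10 = 0.3))
}

#' Generate a random compound library and pathway model
#'
#' Utility for tests and calibration studies: draws compound monoisotopic
#' masses uniformly on [80, 800] Da and partitions compounds into pathways of
#' equal size (every compound belongs to exactly one pathway).
#'
#' @param n_compounds,n_pathways library dimensions.
#' @param seed integer seed.
#' @return list with \code{compounds} (data.frame as from
#'   \code{\link{readCompoundTable}}) and \code{model}
#'   (a \linkS4class{PathwayModel}).
#' @export
simulateCompoundLibrary <- function(n_compounds = 60L, n_pathways = 6L,
                                    seed = 1L) {
  withSeed(seed, {
    id <- sprintf("C%03d", seq_len(n_compounds))
    pw <- rep_len(sprintf("P%02d", seq_len(n_pathways)), n_compounds)
    compounds <- data.frame(
      compound_id = id,
      name = paste0("compound_", seq_len(n_compounds)),
      monoisotopic_mass = runif(n_compounds, 80, 800),
      stringsAsFactors = FALSE)
    compounds$pathway_ids <- as.list(pw)
    pathways <- lapply(split(id, pw), function(v)
      list(name = paste0("pathway ", substr(v[1L], 2L, 4L)), compounds = v))
    names(pathways) <- sort(unique(pw))
    list(compounds = compounds,
         model = new("PathwayModel", pathways = pathways, universe = id))
  })
}
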