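## Fixtures built in code, shared across test files.

## Minimal PeakTable from a features x samples matrix.
makeTable <- function(m, sample_type, batch = rep(1L, length(sample_type)),
                      injection_order = NULL, mz = NULL, rt = NULL,
                      extra_sample_cols = NULL) {
  p <- nrow(m); n <- ncol(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("F%02d", seq_len(p))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(n))
  if (is.null(injection_order)) {
    injection_order <- integer(n)
    for (b in unique(batch))
      injection_order[batch == b] <- seq_len(sum(batch == b))
  }
  samples <- data.frame(sample_type = sample_type, batch = batch,
                        injection_order = injection_order,
                        stringsAsFactors = FALSE)
  if (!is.null(extra_sample_cols))
    samples <- cbind(samples, extra_sample_cols)
  PeakTable(m,
            features = data.frame(mz = mz %||% (100 + seq_len(p)),
                                  rt = rt %||% seq_len(p)),
            samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Engineered 10-feature filter fixture: 2 features fail the QC presence
## filter (1/20 QCs), 2 fail the QC RSD filter (RSD ~41%), 2 fail the blank
## ratio filter (ratio 2.5 at threshold 3), 4 survive everything.
filterFixture <- function() {
  n_samp <- 10L; n_qc <- 20L; n_blank <- 2L
  n <- n_samp + n_qc + n_blank
  type <- c(rep("sample", n_samp), rep("QC", n_qc), rep("blank", n_blank))
  m <- matrix(NA_real_, 10L, n,
              dimnames = list(sprintf("f%02d", 1:10), sprintf("I%02d", 1:n)))
  s <- seq_len(n_samp)
  q <- n_samp + seq_len(n_qc)
  b <- n_samp + n_qc + seq_len(n_blank)
  samp_vals <- 1000 + 10 * seq_len(n_samp)      # nonconstant across samples
  for (f in 1:10) m[f, s] <- samp_vals
  ## f01, f02: detected in only 1 of 20 QCs (5% < 10%)
  m[1:2, q] <- NA; m[1:2, q[1L]] <- 1000
  ## f03, f04: present in all QCs, RSD ~41% (alternating 60/140... x10)
  m[3, q] <- rep(c(600, 1400), 10L)
  m[4, q] <- rep(c(600, 1400), 10L)
  ## f05..f10: clean QCs (RSD 0)
  m[5:10, q] <- 1000
  ## blanks: f05, f06 fail ratio (mean sample ~1055 / blank 422 = 2.5)
  blank_fail <- mean(samp_vals) / 2.5
  m[5:6, b] <- blank_fail
  ## f07, f08: no blank signal at all (kept); f09, f10: ratio 10 (kept)
  m[7:8, b] <- NA
  m[9:10, b] <- mean(samp_vals) / 10
  ## f01..f04 blanks: absent
  m[1:4, b] <- NA
  makeTable(m, type)
}

## Noiseless linear within-batch drift: intensity = base * (100 + order).
linearDriftFixture <- function(n_feat = 3L, n_qc = 6L, n_samp = 12L) {
  n <- n_qc + n_samp
  type <- rep("sample", n)
  qc_at <- round(seq(1, n, length.out = n_qc))
  type[qc_at] <- "QC"
  base <- c(50, 200, 1000)[seq_len(n_feat)]
  m <- outer(base, (100 + seq_len(n)) / 100)
  rownames(m) <- sprintf("f%02d", seq_len(n_feat))
  colnames(m) <- sprintf("I%02d", seq_len(n))
  makeTable(m, type)
}

## One shared "small preset" simulation + preprocessing, computed lazily and
## cached for the whole test run (it is the expensive fixture).
.fixtures <- new.env(parent = emptyenv())
smallSimFixture <- function() {
  if (is.null(.fixtures$sim)) {
    ps <- synthPreset("small")
    cohort <- simulateCohort(ps$cohort)
    .fixtures$cohort <- cohort
    .fixtures$sim <- simulatePeakTable(cohort, ps$run, ps$effects, seed = 7L)
    .fixtures$pre <- suppressWarnings(runPreprocess(.fixtures$sim$table))
  }
  list(cohort = .fixtures$cohort, sim = .fixtures$sim, pre = .fixtures$pre)
}

bundledCompounds <- function()
  readCompoundTable(system.file("extdata", "compounds.tsv",
                                package = "serumPLS", mustWork = TRUE))
bundledPathways <- function()
  readPathwayModel(system.file("extdata", "pathways.json",
                               package = "serumPLS", mustWork = TRUE))
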