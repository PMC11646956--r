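## Independent oracles used to cross-check the package implementations.
## These deliberately take different numerical routes from the package code.

## SVD-based PLS2: the weight vector of each component is the leading left
## singular vector of the X'Y cross-product (computed by svd(), not by power
## iteration), with the same deflation and centring conventions.
svdPlsPredict <- function(Xtr, ytr, Xte, A) {
  classes <- sort(unique(ytr))
  Y <- 1 * outer(ytr, classes, "==")
  xm <- colMeans(Xtr); ym <- colMeans(Y)
  X <- sweep(Xtr, 2, xm); Yc <- sweep(Y, 2, ym)
  W <- P <- NULL; Q <- NULL
  for (a in seq_len(A)) {
    sv <- svd(crossprod(X, Yc), nu = 1, nv = 0)
    w <- sv$u[, 1]
    if (w[which.max(abs(w))] < 0) w <- -w
    tt <- drop(X %*% w)
    p <- drop(crossprod(X, tt)) / sum(tt^2)
    q <- drop(crossprod(Yc, tt)) / sum(tt^2)
    X <- X - tcrossprod(tt, p)
    Yc <- Yc - tcrossprod(tt, q)
    W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q)
  }
  B <- W %*% solve(t(P) %*% W) %*% t(Q)
  colnames(B) <- classes
  sweep(sweep(Xte, 2, xm) %*% B, 2, ym, `+`)
}

## Brute-force one-tailed hypergeometric enrichment p via binomial
## coefficients: P(X >= h) for X ~ Hypergeom(m in pathway, N total, k drawn).
hyperTailOracle <- function(N, m, k, h) {
  j <- seq(max(h, 0, k - (N - m)), min(m, k))
  if (length(j) == 0 || h > min(m, k)) return(if (h <= 0) 1 else 0)
  sum(choose(m, j) * choose(N - m, k - j)) / choose(N, k)
}

## Exact two-sided Mann-Whitney p by full enumeration of all C(n, n1) rank
## assignments (ties not supported), using the same two-sided convention as
## the exact test: 2 * min(P(U <= u), P(U >= u)), capped at 1.
mwEnumOracle <- function(x1, x2) {
  n1 <- length(x1); n <- n1 + length(x2)
  r <- rank(c(x1, x2))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2,
              function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## Kruskal-Wallis H computed from first principles (no ties).
kwHOracle <- function(values, labels) {
  n <- length(values)
  r <- rank(values)
  h <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    h <- h + sum(r[idx])^2 / sum(idx)
  }
  12 / (n * (n + 1)) * h - 3 * (n + 1)
}

## Permutation distribution of H over all label rearrangements.
kwPermOracle <- function(values, labels) {
  h_obs <- kwHOracle(values, labels)
  perms <- permuteAll(labels)
  hs <- vapply(perms, function(lb) kwHOracle(values, lb), numeric(1))
  mean(hs >= h_obs - 1e-12)
}

permuteAll <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permuteAll(v[-i]), function(rest) c(v[i], rest)))
  out
}

## VIP formula coded independently, element by element.
vipOracle <- function(model) {
  W <- model@weights; Tm <- model@scores; Q <- model@yloadings
  p <- nrow(W); A <- ncol(W)
  ssy <- numeric(A)
  for (a in seq_len(A))
    ssy[a] <- sum(Q[, a]^2) * sum(Tm[, a]^2)
  vip <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(A))
      acc <- acc + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    vip[j] <- sqrt(p * acc / sum(ssy))
  }
  vip
}

## Hand step-up BH adjustment.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
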