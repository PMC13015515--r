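# Small numerical helpers shared across the package.

#' Population standard deviation
#'
#' Standard deviation with the n (not n-1) denominator, used for every
#' z-scoring step in the package so that small fixed examples are exact and
#' repeated runs are bit-identical.
#'
#' @param x numeric vector; `NA` values are removed.
#' @return a single non-negative number.
#' @export
popSD <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Population z-score
#'
#' @param x numeric vector.
#' @return `(x - mean) / popSD`, or all zeros when the spread is zero.
#' @export
popZ <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- popSD(x)
  if (is.na(s) || s == 0) return(ifelse(is.na(x), NA_real_, 0))
  (x - m) / s
}

# Centered rolling mean with truncated edges; a missing center stays missing,
# missing neighbours are dropped from the local mean.
rollMeanTrunc <- function(x, width = 3L) {
  stopifnot(width >= 1L, width %% 2L == 1L)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    v <- x[max(1L, i - h):min(n, i + h)]
    out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Rank-based AUC with midrank ties
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic with
#' average ranks for ties. Equivalent to the probability that a randomly
#' chosen positive sample scores above a randomly chosen negative one.
#'
#' @param score numeric scores.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\]; `NA` if either class is empty.
#' @export
midrankAUC <- function(score, positive) {
  keep <- !is.na(score) & !is.na(positive)
  score <- score[keep]; positive <- as.logical(positive[keep])
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment, seeded and deterministic.
stratifiedFolds <- function(y, k, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  rng <- localRNG(seed)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[rng$permute(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Ridge-penalized logistic regression by IRLS (Newton) with an unpenalized
# intercept. Used for the module-score readout sigma(b0 + sum b_k m_k): a
# handful of predictors, exact deterministic coefficients, finite under
# complete separation.
ridgeLogistic <- function(x, y, lambda = 0.01, maxIter = 50L, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  X <- cbind(Intercept = 1, x)
  beta <- rep(0, p + 1L)
  pen <- diag(c(0, rep(lambda, p)), p + 1L)
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta0 = beta[1L], betas = stats::setNames(beta[-1L], colnames(x)),
       fitted = 1 / (1 + exp(-drop(X %*% beta))))
}

# Predict from a ridgeLogistic fit.
predictLogistic <- function(fit, x) {
  eta <- fit$beta0 + drop(as.matrix(x) %*% fit$betas)
  1 / (1 + exp(-eta))
}

# A self-contained RNG stream: evaluates `expr`-style draws without touching
# (or depending on) the caller's .Random.seed.
localRNG <- function(seed) {
  env <- new.env()
  local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    norm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    unif = function(n) run(function() stats::runif(n)),
    permute = function(n) run(function() sample.int(n)),
    sampleInt = function(n, size, replace = FALSE) run(function() sample.int(n, size, replace = replace)),
    int = function(n, max) run(function() sample.int(max, n, replace = TRUE))
  )
}

#' Canonical unordered edge key
#'
#' `"geneA|geneB"` with the smaller id first; the identity used for
#' edge-set comparisons (bootstrap Jaccard stability).
#'
#' @param i,j character vectors of gene ids.
#' @return a character vector of keys.
#' @export
edgeKey <- function(i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  paste(a, b, sep = "|")
}
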