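## Node-wise nonparametric permutation testing between two sets of tract
## profiles with max-statistic family-wise-error correction over the nodes
## (the FWE scheme of permutation tools such as FSL randomise).

#' Permutation test between two groups of tract profiles
#'
#' The node-wise statistic is the mean difference divided by its standard
#' error. The null distribution is built from random sign flips of
#' subject-wise differences (paired) or group-label shuffles (unpaired),
#' always including the identity permutation. The corrected p-value at a
#' node is the fraction of permutations whose maximum |statistic| over all
#' nodes reaches the observed |statistic| there, controlling the
#' family-wise error over nodes.
#'
#' @param profilesA,profilesB numeric matrices, subjects x nodes. For a
#'   paired design rows must correspond across the two matrices.
#' @param nPermutations number of permutations (default 5000).
#' @param alpha significance level (default 0.05).
#' @param paired paired design via sign flips (default TRUE).
#' @param seed integer seed recorded in the output.
#' @return list(statistic, pCorrected, significant, alpha, seed,
#'   nPermutations); p-values lie in (0, 1] with minimum
#'   1/nPermutations.
#' @export
permutationTest <- function(profilesA, profilesB, nPermutations = 5000L,
                            alpha = 0.05, paired = TRUE, seed = 1L) {
  stopifnot(nPermutations >= 1L, alpha > 0, alpha < 1)
  profilesA <- as.matrix(profilesA)
  profilesB <- as.matrix(profilesB)
  stopifnot(ncol(profilesA) == ncol(profilesB))
  if (paired && nrow(profilesA) != nrow(profilesB))
    stop("paired design requires equal subject counts in matched order")
  nn <- ncol(profilesA)
  eps <- .Machine$double.eps
  set.seed(seed)
  colVar <- function(m) {                # unbiased column variances
    n <- nrow(m)
    mu <- colMeans(m)
    (colSums(m^2) - n * mu^2) / (n - 1)
  }
  tStat <- function(d) {                 # one-sample t on differences
    n <- nrow(d)
    mu <- colMeans(d)
    se <- sqrt(pmax(colVar(d), 0) / n)
    flagged <- se <= eps
    se[flagged] <- eps
    s <- mu / se
    s[flagged & abs(mu) <= eps] <- 0
    s
  }
  twoStat <- function(a, b) {            # two-sample (Welch-style SE)
    na <- nrow(a); nb <- nrow(b)
    mu <- colMeans(a) - colMeans(b)
    se <- sqrt(pmax(colVar(a), 0) / na + pmax(colVar(b), 0) / nb)
    flagged <- se <= eps
    se[flagged] <- eps
    s <- mu / se
    s[flagged & abs(mu) <= eps] <- 0
    s
  }
  if (paired) {
    d <- profilesA - profilesB
    n <- nrow(d)
    obs <- tStat(d)
    maxT <- numeric(nPermutations)
    maxT[1] <- max(abs(obs))             # identity permutation
    for (p in seq_len(nPermutations - 1L)) {
      fl <- sample(c(-1, 1), n, replace = TRUE)
      maxT[p + 1L] <- max(abs(tStat(d * fl)))
    }
  } else {
    pool <- rbind(profilesA, profilesB)
    na <- nrow(profilesA)
    obs <- twoStat(profilesA, profilesB)
    maxT <- numeric(nPermutations)
    maxT[1] <- max(abs(obs))
    for (p in seq_len(nPermutations - 1L)) {
      idx <- sample(nrow(pool))
      maxT[p + 1L] <- max(abs(twoStat(pool[idx[seq_len(na)], , drop = FALSE],
                                      pool[idx[-seq_len(na)], , drop = FALSE])))
    }
  }
  pCorr <- vapply(abs(obs), function(t0) mean(maxT >= t0), numeric(1))
  pCorr <- pmax(pCorr, 1 / nPermutations)
  list(statistic = obs, pCorrected = pCorr,
       significant = pCorr < alpha, alpha = alpha, seed = seed,
       nPermutations = as.integer(nPermutations))
}
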