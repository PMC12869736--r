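# shared small fixtures, built in code

toyNet <- function() {
  EcoNetwork(data.frame(from = c("A", "A"), to = c("B", "C"),
                        weight = c(0.6, -0.4)),
             nodes = c("A", "B", "C"))
}

toyTable <- function(rel = c(A = 0.5, B = 0.3, C = 0.2), depth = 1000) {
  m <- matrix(rel * depth, ncol = 1,
              dimnames = list(names(rel), "s1"))
  AsvExperiment(m, NULL, "bacteria")
}

completeGraph <- function(k, weight = 1) {
  prs <- t(combn(letters[seq_len(k)], 2))
  EcoNetwork(data.frame(from = prs[, 1], to = prs[, 2], weight = weight))
}

# exhaustive two-group PERMANOVA oracle: pseudo-F over all label
# assignments, from the classic sum-of-squared-distances partition
permanovaExact <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssF <- function(g) {
    ssw <- 0
    for (lv in unique(g)) {
      i <- which(g == lv)
      ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  fObs <- ssF(groups)
  lev <- unique(groups)
  idx <- which(groups == lev[1])
  combs <- combn(n, length(idx))
  fs <- apply(combs, 2, function(ix) {
    g <- rep(lev[2], n); g[ix] <- lev[1]
    ssF(g)
  })
  list(F = fObs, p = mean(fs >= fObs - 1e-12))
}
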