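# Independent oracles, written from first principles and kept free of any
# package internals, plus small fixture builders.

# Textbook two-sample t: explicit sums, no shared code with the package.
oracleTTest <- function(a, b, equalVar = TRUE) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  if (equalVar) {
    df <- na + nb - 2
    se <- sqrt((((na - 1) * va + (nb - 1) * vb) / df) * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- (ma - mb) / se
  list(estimate = ma - mb, t = tt, p = 2 * stats::pt(-abs(tt), df), df = df)
}

# Exact hypergeometric upper tail by direct enumeration of the pmf.
oracleHyperTail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  sum(vapply(js, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# Step-up BH from the definition: q_i = min_{j: rank_j >= rank_i} m p_(j)/j.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q <- numeric(m)
  for (i in seq_len(m))
    q[o[i]] <- min(1, min(ranked[i:m]))
  q
}

# Naive unweighted (p = 0) GSEA running sum over the full list: O(N).
oracleGseaES <- function(rankedIds, members, preferPositive = TRUE) {
  N <- length(rankedIds)
  hit <- rankedIds %in% members
  NH <- sum(hit)
  steps <- ifelse(hit, 1 / NH, -1 / (N - NH))
  running <- cumsum(steps)
  top <- max(running, 0)
  bottom <- min(running, 0)
  if (top + bottom >= -1e-12) top else bottom
}

# Tiny ProximityExperiment built by hand.
toyPE <- function(values, role, batch = "nonstress_expt", ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  ProximityExperiment(values, role = role, batch = batch, ...)
}

# A bare experiment carrying only an identifier set, for overlap arithmetic.
idOnlyPE <- function(ids, batch = "nonstress_expt") {
  roles <- if (batch == "stress_expt") c("iv", "v") else c("i", "iii")
  m <- matrix(25, length(ids), 4,
              dimnames = list(ids, paste0(batch, "_s", 1:4)))
  ProximityExperiment(m, role = rep(roles, each = 2), batch = batch)
}

# Fully preprocessed simulated experiment pair for pipeline-level tests.
preppedPair <- function(cfg, seedOffset = 50L) {
  prep <- function(pe, off)
    imputeDownshift(filterValidValues(medianNormalize(pe)),
                    seed = cfg@seed + off)
  list(nonstress = prep(simulateProximityExperiment(cfg), seedOffset),
       stress = prep(simulateStressExperiment(cfg), seedOffset + 1L))
}
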