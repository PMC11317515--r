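# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs against the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed))
    return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise two-sample t statistics over two matrices with NA cells.
# Undefined rows (fewer than two finite values in a group, or zero pooled
# standard error) get NA statistics and a reason, mirroring the scalar
# twoSampleTTest() error contract.
rowTTest <- function(a, b, equalVar = TRUE) {
  stopifnot(nrow(a) == nrow(b))
  groupStats <- function(m) {
    n <- rowSums(is.finite(m))
    mu <- rowMeans(m, na.rm = TRUE)
    mu[n == 0] <- NA_real_
    ss <- rowSums((m - mu)^2, na.rm = TRUE)
    v <- ifelse(n > 1, ss / pmax(n - 1, 1), NA_real_)
    list(n = n, mean = mu, var = v)
  }
  sa <- groupStats(a)
  sb <- groupStats(b)
  est <- sa$mean - sb$mean
  ok <- sa$n >= 2 & sb$n >= 2
  if (equalVar) {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$var + (sb$n - 1) * sb$var) / pmax(df, 1)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    va <- sa$var / sa$n
    vb <- sb$var / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / pmax(sa$n - 1, 1) + vb^2 / pmax(sb$n - 1, 1))
  }
  zero <- ok & !is.na(se) & se == 0
  usable <- ok & !zero
  tstat <- ifelse(usable, est / se, NA_real_)
  p <- ifelse(is.finite(tstat),
              2 * stats::pt(abs(tstat), df, lower.tail = FALSE), NA_real_)
  reason <- rep(NA_character_, nrow(a))
  reason[!ok] <- "insufficient_valid_values"
  reason[zero] <- "zero_variance"
  list(estimate = ifelse(usable, est, NA_real_), t = tstat, p = p,
       df = ifelse(usable, df, NA_real_), nA = sa$n, nB = sb$n,
       reason = reason)
}

# Columns of `pe` belonging to a role (optionally within a batch).
roleColumns <- function(pe, role, batch = NULL) {
  sel <- sampleRoles(pe) == role
  if (!is.null(batch))
    sel <- sel & sampleBatches(pe) == batch
  which(sel)
}

requireRoles <- function(pe, roles, batch = NULL, minPerRole = 2) {
  for (r in roles) {
    n <- length(roleColumns(pe, r, batch))
    if (n == 0)
      stop(sprintf("missing required role '%s'", r))
    if (n < minPerRole)
      stop(sprintf("role '%s' needs >= %d samples, found %d",
                   r, minPerRole, n))
  }
  invisible(TRUE)
}

writeTsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
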