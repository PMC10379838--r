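# Independent textbook/brute-force oracles. These deliberately avoid the
# code paths (and the stats wrappers) used by the package: everything here
# is written from first principles so agreement is a real cross-check.

oracle_chisq_uniform <- function(counts) {
  k <- length(counts)
  e <- sum(counts) / k
  stat <- sum((counts - e)^2 / e)
  list(stat = stat, df = k - 1, p = pchisq(stat, k - 1, lower.tail = FALSE))
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mean(a) - mean(b)) / se
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_anova <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  n <- vapply(groups, length, 0L)
  ss_b <- sum(n * (vapply(groups, mean, 0) - gm)^2)
  ss_w <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  f <- (ss_b / df1) / (ss_w / df2)
  list(f = f, df = c(df1, df2), p = pf(f, df1, df2, lower.tail = FALSE),
       r2 = ss_b / (ss_b + ss_w))
}

# Tukey HSD pairwise p from the studentized range, Tukey-Kramer for
# unequal n
oracle_tukey_p <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) /
    (sum(n) - k)
  out <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(m[i] - m[j]) / se
    out <- c(out, unname(ptukey(q, k, sum(n) - k, lower.tail = FALSE)))
  }
  out
}

# exhaustive mismatch-minimising shift (IUPAC-aware), written directly
oracle_best_shift <- function(seq, refseq, max_shift = 30) {
  iup <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sc <- strsplit(seq, "")[[1]]; rc <- strsplit(refseq, "")[[1]]
  best <- list(shift = NA, frac = Inf, mm = NA)
  for (s in -max_shift:max_shift) {
    lo <- max(1, 1 + s); hi <- min(length(sc), length(rc) + s)
    if (hi - lo + 1 < 15) next
    mm <- 0
    for (i in lo:hi) {
      ok <- !is.null(iup[[sc[i]]]) && rc[i - s] %in% iup[[sc[i]]]
      if (!ok) mm <- mm + 1
    }
    frac <- mm / (hi - lo + 1)
    better <- frac < best$frac - 1e-12
    tie <- abs(frac - best$frac) <= 1e-12 &&
      (abs(s) < abs(best$shift) || (abs(s) == abs(best$shift) &&
                                    s < best$shift))
    if (better || tie) best <- list(shift = s, frac = frac, mm = mm)
  }
  best
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
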