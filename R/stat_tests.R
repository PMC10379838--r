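# Statistical comparisons used in the regional analysis: chi-square
# against a uniform haplotype distribution, unpaired two-tailed t-tests
# (pooled-variance by default, Welch optional), one-way ANOVA with
# Tukey's HSD and a compact letter display. The p-values come from the
# base stats machinery (chisq.test, t.test, lm/anova, ptukey); this file
# only shapes them into a common result object.

hm_htest <- function(method, statistic, df, p_value, groups = NULL,
                     extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, df = df,
           p_value = p_value, groups = groups), extra),
    class = "hm_htest")
}

#' @export
print.hm_htest <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4f\n",
              x$method, x$statistic, dfs, x$p_value))
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' @export
tidy.hm_htest <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic,
         df = x$df[1],
         df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p_value)
}

#' @export
glance.hm_htest <- function(x, ...) tidy(x)

group_summary <- function(groups, names = NULL) {
  if (is.null(names)) names <- paste0("group", seq_along(groups))
  tibble(group = names,
         n = vapply(groups, length, 0L),
         mean = round(vapply(groups, mean, 0), 2),
         sd = round(vapply(groups, sd, 0), 2))
}

#' Chi-square test against a uniform haplotype distribution
#'
#' Pearson goodness-of-fit of observed haplotype counts against equal
#' expected counts, df = k - 1, upper-tail p.
#'
#' @param counts Vector of k >= 2 non-negative counts.
#' @return An `hm_htest`.
#' @export
chi_square_uniform <- function(counts) {
  if (length(counts) < 2L) abort("need at least two categories")
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("counts must be non-negative with positive total")
  }
  ct <- suppressWarnings(chisq.test(counts))
  hm_htest("Chi-square (uniform expected)",
           unname(ct$statistic), unname(ct$parameter), ct$p.value,
           extra = list(expected = unname(ct$expected)))
}

#' Unpaired two-tailed t-test
#'
#' `pooled` is the classic equal-variance test with df = n_a + n_b - 2;
#' `welch` uses the Satterthwaite approximation.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return An `hm_htest` with group summaries (means/sds to 2 decimals).
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least 2 observations")
  }
  tt <- t.test(a, b, var.equal = (variant == "pooled"))
  hm_htest(sprintf("Two-sample t (%s, two-tailed)", variant),
           unname(tt$statistic), unname(tt$parameter), tt$p.value,
           groups = group_summary(list(a, b), c("a", "b")))
}

#' One-way ANOVA
#'
#' F statistic with (k - 1, N - k) df and the effect size
#' r^2 = SS_between / SS_total.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return An `hm_htest` with an `r_squared` element.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) abort("need at least two groups")
  if (any(vapply(groups, length, 0L) < 2L)) {
    abort("each group needs at least 2 observations")
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (all(vapply(groups, function(v) var(v) == 0, TRUE))) {
    abort("zero within-group variance: F is undefined")
  }
  fit <- lm(y ~ g)
  av <- anova(fit)
  ss_b <- av$`Sum Sq`[1]; ss_w <- av$`Sum Sq`[2]
  hm_htest("One-way ANOVA", av$`F value`[1],
           c(av$Df[1], av$Df[2]), av$`Pr(>F)`[1],
           groups = group_summary(groups, names(groups)),
           extra = list(r_squared = ss_b / (ss_b + ss_w)))
}

#' Tukey's HSD with a compact letter display
#'
#' All pairwise comparisons by the studentized range following a one-way
#' ANOVA, plus a compact letter display: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class `hm_tukey`: `pairs` (tibble: group1, group2,
#'   diff, lwr, upr, p_adj), `letters` (named character vector),
#'   `anova` (the underlying `hm_htest`).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  aout <- one_way_anova(groups)
  y <- unlist(groups)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  tk <- TukeyHSD(aov(y ~ g), conf.level = 1 - alpha)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble(
    group1 = vapply(nm, `[`, "", 1L),
    group2 = vapply(nm, `[`, "", 2L),
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]))
  letters <- compact_letter_display(names(groups),
                                    vapply(groups, mean, 0),
                                    pairs, alpha)
  structure(list(pairs = pairs, letters = letters, anova = aout,
                 alpha = alpha),
            class = "hm_tukey")
}

#' @export
print.hm_tukey <- function(x, ...) {
  print(x$anova)
  print(x$pairs)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.hm_tukey <- function(x, ...) x$pairs

# insert-and-absorb compact letter display over a pairwise p-value table
compact_letter_display <- function(group_names, group_means, pairs, alpha) {
  k <- length(group_names)
  ord <- order(-group_means)
  gn <- group_names[ord]
  sig <- matrix(FALSE, k, k, dimnames = list(gn, gn))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$p_adj[i] < alpha) {
      sig[pairs$group1[i], pairs$group2[i]] <- TRUE
      sig[pairs$group2[i], pairs$group1[i]] <- TRUE
    }
  }
  # columns are letter classes (logical membership vectors over groups)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!sig[gn[i], gn[j]]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] | !cols[[cj]]) && !identical(cols[[ci]],
                                                      cols[[cj]])) {
        # cj contained in ci
        keep[cj] <- FALSE
      }
    }
    # drop exact duplicates too
    sig_str <- vapply(cols, function(c) paste(c, collapse = ""), "")
    keep <- keep & !duplicated(sig_str)
    cols <- cols[keep]
  }
  lab <- rep("", k)
  for (ci in seq_along(cols)) {
    lab[cols[[ci]]] <- paste0(lab[cols[[ci]]], letters[ci])
  }
  out <- setNames(lab, gn)
  out[group_names]
}
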