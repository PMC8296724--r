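## Group statistics over per-individual percentages: normality screening
## (D'Agostino-Pearson omnibus K2), Kruskal-Wallis with Dunn's post hoc and a
## compact letter display for >= 3 groups, Mann-Whitney for two independent
## groups and the paired Wilcoxon signed-rank test for within-individual
## 5' vs 3' comparisons. Rank tests delegate to the standard base-R
## implementations (tie-corrected H, exact small-sample distributions);
## the omnibus normality test and Dunn's z-statistics are implemented here.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness and kurtosis z-statistics (D'Agostino 1970;
#' Anscombe & Glynn 1983) into K2 = Zg1^2 + Zg2^2, referred to a chi-squared
#' distribution with 2 df.
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `k2`, `p_value`, `z_skew`, `z_kurt`, `n`. For n < 8 or a
#'   constant vector the statistic is `NA` and `reason` explains why.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) {
    return(list(k2 = NA_real_, p_value = NA_real_, n = n,
                reason = "insufficient n (< 8)"))
  }
  if (sd(x) == 0) {
    return(list(k2 = NA_real_, p_value = NA_real_, n = n,
                reason = "degenerate (constant) sample"))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  ## Skewness: D'Agostino (1970) transformation to normality.
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  ## Kurtosis: Anscombe & Glynn (1983).
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(k2 = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H referred to chi-squared with k - 1 df.
#'
#' @param groups List of numeric vectors (>= 3 groups).
#' @return List `statistic` (H), `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 3L)
  if (any(lengths(groups) < 1L)) stop("every group needs >= 1 value", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L,
                n = length(values)))
  }
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

#' Dunn's multiple comparison test with a compact letter display
#'
#' Pairwise z-statistics on the pooled ranks with tie correction, adjusted
#' family-wise over all pairs (Bonferroni by default, as in the common
#' commercial implementation; method configurable via [stats::p.adjust()]).
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return List with `pairwise` (data frame `group1`, `group2`, `z`, `p`,
#'   `p_adj`, `significant`) and `letters` (named character vector; groups
#'   share a letter iff their adjusted p is >= `alpha`).
#' @export
dunn_posthoc <- function(groups, alpha = 0.05, method = "bonferroni") {
  k <- length(groups)
  stopifnot(k >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  gl <- rep(names(groups), lengths(groups))
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, factor(gl, levels = names(groups)), mean)
  sizes <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = res["z", ], p = res["p", ],
                   p_adj = pmin(1, p.adjust(res["p", ], method = method)),
                   stringsAsFactors = FALSE)
  pw$significant <- pw$p_adj < alpha
  list(pairwise = pw, letters = compact_letters(names(groups), pw, alpha))
}

#' Compact letter display from pairwise comparisons
#'
#' Greedy insert-and-absorb: two groups share at least one letter if and
#' only if their adjusted pairwise p-value is >= `alpha`.
#'
#' @param group_names Character vector of group labels.
#' @param pairwise Data frame with `group1`, `group2`, `p_adj`.
#' @param alpha Significance level.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(group_names, pairwise, alpha = 0.05) {
  k <- length(group_names)
  nonsig <- matrix(TRUE, k, k, dimnames = list(group_names, group_names))
  for (i in seq_len(nrow(pairwise))) {
    s <- pairwise$p_adj[i] < alpha
    nonsig[pairwise$group1[i], pairwise$group2[i]] <- !s
    nonsig[pairwise$group2[i], pairwise$group1[i]] <- !s
  }
  sets <- list(group_names[1])
  for (g in group_names[-1]) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (all(nonsig[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    ## open a fresh set for g and any uncovered non-significant partner
    if (!placed) sets[[length(sets) + 1L]] <- g
    for (h in group_names[seq_len(match(g, group_names) - 1L)]) {
      if (nonsig[g, h] && !any(vapply(sets, function(s) all(c(g, h) %in% s), logical(1)))) {
        sets[[length(sets) + 1L]] <- c(h, g)
      }
    }
  }
  ## absorb subsets
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) for (b in seq_along(sets)) {
    if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]])) keep[a] <- FALSE
  }
  sets <- sets[keep]
  out <- setNames(rep("", k), group_names)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  out
}

#' Mann-Whitney rank test for two independent groups
#'
#' Exact two-sided p by the rank-sum distribution when the sample product
#' n * m <= 10000 and there are no ties; normal approximation with tie and
#' continuity correction otherwise (identical groups give exactly p = 1:
#' at z = 0 the correction vanishes).
#'
#' @param a,b Numeric vectors.
#' @return List `statistic` (U for `a` vs `b`), `p_value`, `exact`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) * length(b) <= 10000
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value),
       exact = exact)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (classic convention). Exact two-sided p for
#' up to 25 non-zero untied differences, normal approximation otherwise.
#' With no non-zero differences the test is degenerate and returns p = 1
#' with a warning.
#'
#' @param x,y Paired numeric vectors (same individuals, same order).
#' @return List `statistic` (V, sum of positive signed ranks), `p_value`,
#'   `exact`, `n_used` (non-zero pairs).
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; test degenerate")
    return(list(statistic = NA_real_, p_value = 1, exact = FALSE, n_used = 0L))
  }
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value),
       exact = exact, n_used = length(d))
}
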