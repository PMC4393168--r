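#' Kruskal-Wallis test across groups
#'
#' Tie-corrected Kruskal-Wallis rank-sum test (chi-square approximation
#' with k-1 degrees of freedom), the omnibus test used for all structural
#' indices because they frequently violate normality and equal-variance
#' assumptions.
#'
#' @param values Numeric vector of index values.
#' @param groups Factor (or coercible) of group labels, same length.
#' @return A list with `H` (tie-corrected statistic), `p_value`, `df`,
#'   and `n` per group.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) != length(groups)) stop("length mismatch")
  if (stats::var(values) == 0) {
    return(list(H = 0, p_value = 1, df = nlevels(groups) - 1L,
                n = table(groups)))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = table(groups))
}

#' Dunn's post hoc multiple comparisons
#'
#' Pairwise z tests on mean ranks following a Kruskal-Wallis test, with the
#' usual tie correction, adjusted familywise over all k(k-1)/2 pairs
#' (Bonferroni by default, Holm available).
#'
#' @param values Numeric vector of index values.
#' @param groups Factor of group labels.
#' @param method Familywise adjustment: `"bonferroni"` (default) or
#'   `"holm"`.
#' @return A data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding groups with fewer than 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
    sizes <- table(groups)
  }
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups of size >= 2")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z[i] <- (rbar[[g1]] - rbar[[g2]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_unadjusted = p,
             p_adjusted = pmin(stats::p.adjust(p, method = method), 1))
}

#' Paired t test
#'
#' Two-sided paired t test (used for within-group body-weight changes).
#'
#' @param before,after Equal-length paired numeric vectors (n >= 2).
#' @return List with `t`, `p_value`, `df`, `mean_difference`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) stop("paired vectors differ in length")
  if (length(before) < 2) stop("need n >= 2 pairs")
  d <- after - before
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p_value = 1, df = length(d) - 1L, mean_difference = 0))
    stop("zero variance of paired differences")
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate))
}

#' Percent contrast between a reference and a comparator value
#'
#' The reporting arithmetic behind statements like "X% smaller in group A
#' than in group B": `smaller = 100 (ref - comp) / ref` and
#' `larger = 100 (comp - ref) / ref`, with the integer-rounded direction
#' actually applying.
#'
#' @param reference Reference (e.g. control-group) value, nonzero.
#' @param comparator Comparator value.
#' @return List with `percent_smaller`, `percent_larger`, `direction`
#'   (`"smaller"`, `"larger"` or `"equal"`), and `percent` (the rounded
#'   integer magnitude in the applying direction).
#' @export
percent_contrast <- function(reference, comparator) {
  if (reference == 0) stop("reference value must be nonzero")
  smaller <- 100 * (reference - comparator) / reference
  larger <- 100 * (comparator - reference) / reference
  direction <- if (comparator < reference) "smaller"
  else if (comparator > reference) "larger" else "equal"
  list(percent_smaller = smaller, percent_larger = larger,
       direction = direction,
       percent = round(if (direction == "smaller") smaller else larger))
}

#' Consistency check of size-specific partitions against totals
#'
#' Verifies that the five vessel-size-specific values sum to the printed
#' total within a rounding tolerance (per-bin tables and totals are
#' typically rounded independently).
#'
#' @param per_bin Numeric vector of the five per-class values.
#' @param total The corresponding total.
#' @param tolerance Allowed absolute discrepancy; defaults to 0.02 for
#'   percent-scale totals (< 100) and 1.0 for density-scale totals.
#' @return List with `sum`, `total`, `discrepancy`, `tolerance`, `pass`.
#' @export
partition_check <- function(per_bin, total,
                            tolerance = if (abs(total) < 100) 0.02 else 1.0) {
  if (length(per_bin) != 5L) stop("expected five diameter-class values")
  s <- sum(per_bin)
  list(sum = s, total = total, discrepancy = abs(s - total),
       tolerance = tolerance, pass = abs(s - total) <= tolerance)
}

#' Group summary as mean and standard error
#'
#' @param df Data.frame with a `group` column and numeric index columns.
#' @param indices Columns to summarize; default all numeric columns except
#'   `group`.
#' @return Long data.frame: `group`, `index`, `mean`, `sem`, `n`.
#' @export
group_summary <- function(df, indices = NULL) {
  if (is.null(indices))
    indices <- names(df)[vapply(df, is.numeric, TRUE) & names(df) != "group"]
  out <- list()
  for (ix in indices) {
    for (g in unique(as.character(df$group))) {
      v <- df[[ix]][df$group == g]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        group = g, index = ix, mean = mean(v),
        sem = stats::sd(v) / sqrt(length(v)), n = length(v))
    }
  }
  do.call(rbind, out)
}
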