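#' Tie-aware Spearman rank correlation
#'
#' Spearman's rs computed as the Pearson correlation of midranks (average
#' ranks for ties), with the two-sided p-value from the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on n - 2 degrees of freedom.
#' Pairs with missing values are deleted pairwise before ranking.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return An object of class `"correlation_result"`: `rs`, `p`, `n`, and a
#'   `ties` note.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant vector: Spearman correlation undefined")
  rs <- stats::cor(rank(x), rank(y))
  p <- if (abs(rs) >= 1) 0 else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(rs = rs, p = p, n = n,
                 ties = anyDuplicated(x) > 0 || anyDuplicated(y) > 0),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rs = %.3f, p = %.4g, n = %d%s\n",
              x$rs, x$p, x$n, if (x$ties) " (midranks for ties)" else ""))
  invisible(x)
}

#' Numeric coding of censored %GP4 values
#'
#' Entries censored as "<5" are mapped to a common value strictly inside
#' (0, 5) - default the midpoint 2.5 - so that they tie with each other and
#' rank above an exact 0 and below an exact 5. Any value in (0, 5) yields the
#' same ranks, so the choice is rank-safe.
#'
#' @param values Character or numeric vector; censored entries are `"<5"`.
#' @param midpoint Value assigned to censored entries.
#' @return List with numeric `value` and logical `censored`.
#' @export
gp4_numeric <- function(values, midpoint = 2.5) {
  if (midpoint <= 0 || midpoint >= 5) stop("midpoint must lie strictly in (0, 5)")
  ch <- trimws(as.character(values))
  censored <- ch == "<5"
  num <- suppressWarnings(as.numeric(ch))
  num[censored] <- midpoint
  if (any(is.na(num) & !is.na(values)))
    stop("unparseable %GP4 entries: ",
         paste(unique(ch[is.na(num) & !is.na(values)]), collapse = ", "))
  list(value = num, censored = censored)
}

#' Pairwise Spearman correlation matrix of cohort variables
#'
#' Symmetric matrix of tie-aware Spearman correlations over selected cohort
#' columns with per-pair n. No multiplicity correction is applied by default
#' (set `adjust = "BH"` for Benjamini-Hochberg adjusted p-values). Lesions
#' flagged `excluded_from_correlation` are dropped according to `exclude`:
#' `"gp4_pairs"` (default) drops them only for pairs involving `pctGP4`,
#' `"all_pairs"` drops them everywhere, `"none"` keeps all lesions.
#'
#' @param cohort Data frame with one row per lesion (see [read_cohort_csv()]).
#' @param vars Character vector of numeric column names to correlate.
#' @param exclude Exclusion policy, see above.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with matrices `rs`, `p`, `n` and a long-format data frame
#'   `pairs` (var1, var2, rs, p, n).
#' @export
correlation_matrix <- function(cohort, vars,
                               exclude = c("gp4_pairs", "all_pairs", "none"),
                               adjust = c("none", "BH")) {
  exclude <- match.arg(exclude)
  adjust <- match.arg(adjust)
  missing_vars <- setdiff(vars, names(cohort))
  if (length(missing_vars)) stop("unknown variables: ",
                                 paste(missing_vars, collapse = ", "))
  k <- length(vars)
  excl <- if ("excluded_from_correlation" %in% names(cohort))
    cohort$excluded_from_correlation else rep(FALSE, nrow(cohort))
  rs_m <- p_m <- n_m <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rs_m) <- 1
  diag(p_m) <- 0
  diag(n_m) <- colSums(!is.na(cohort[vars]))
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    drop_rows <- switch(exclude,
      none = rep(FALSE, nrow(cohort)),
      all_pairs = excl,
      gp4_pairs = if ("pctGP4" %in% c(vars[i], vars[j])) excl
                  else rep(FALSE, nrow(cohort)))
    sub <- cohort[!drop_rows, ]
    res <- spearman_cor(sub[[vars[i]]], sub[[vars[j]]])
    rs_m[i, j] <- rs_m[j, i] <- res$rs
    p_m[i, j] <- p_m[j, i] <- res$p
    n_m[i, j] <- n_m[j, i] <- res$n
    pairs[[length(pairs) + 1]] <- data.frame(
      var1 = vars[i], var2 = vars[j], rs = res$rs, p = res$p, n = res$n)
  }
  pairs <- do.call(rbind, pairs)
  if (adjust == "BH") {
    pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  }
  list(rs = rs_m, p = p_m, n = n_m, pairs = pairs)
}

#' Two-sided Mann-Whitney U comparison
#'
#' Exact-enumeration p-value for combined n <= `exact_limit` without ties,
#' tie-corrected normal approximation (without continuity correction)
#' otherwise; `mode` can force either. Built on [stats::wilcox.test()]; the
#' U statistic reported is for the first sample, so that `U + U' = n1 * n2`.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @param exact_limit Combined-size threshold for the exact mode under
#'   `"auto"`.
#' @return An object of class `"group_comparison"`: `U`, `p`, group sizes,
#'   `direction` (sign of median(a) - median(b)), `mode_used`, and a
#'   `degenerate` flag (all pooled values identical gives p = 1).
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal"),
                         exact_limit = 12L) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1) {
    return(structure(list(U = length(a) * length(b) / 2, p = 1,
                          n1 = length(a), n2 = length(b), direction = 0,
                          mode_used = "degenerate", degenerate = TRUE),
                     class = "group_comparison"))
  }
  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = !ties && (length(a) + length(b)) <= exact_limit)
  if (use_exact && ties)
    stop("exact mode is defined for tie-free samples only")
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, exact = use_exact, correct = FALSE, alternative = "two.sided"))
  structure(list(U = unname(wt$statistic), p = wt$p.value,
                 n1 = length(a), n2 = length(b),
                 direction = sign(stats::median(a) - stats::median(b)),
                 mode_used = if (use_exact) "exact" else "normal",
                 degenerate = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p, x$mode_used))
  invisible(x)
}

#' Partition intermediate-risk lesions by percent Gleason pattern 4
#'
#' Splits ISUP grade group 2-3 lesions into a low (%GP4 <= cutoff, censored
#' "<5" entries counted low) and a high (%GP4 > cutoff) group. ISUP 1
#' (Gleason 3+3) lesions, which carry %GP4 = 0 by definition, are excluded,
#' as are lesions flagged `excluded_from_histology`. The boundary value is
#' assigned to the low group.
#'
#' @param cohort Cohort data frame (see [read_cohort_csv()]).
#' @param cutoff Percent cutoff, default 10.
#' @param honour_exclusions Drop `excluded_from_histology` lesions (default).
#' @return Factor of levels `low`/`high` indexed like `cohort` rows, with NA
#'   for excluded lesions; attribute `"n"` holds the group sizes.
#' @export
group_by_gp4 <- function(cohort, cutoff = 10, honour_exclusions = TRUE) {
  if (!all(c("ISUP", "pctGP4") %in% names(cohort)))
    stop("cohort must contain ISUP and pctGP4 columns")
  gp4 <- cohort$pctGP4
  if (any(is.na(gp4) & cohort$ISUP >= 2))
    stop("unknown %GP4 (and censoring status) for an intermediate-risk lesion")
  grp <- ifelse(gp4 <= cutoff, "low", "high")
  grp[!cohort$ISUP %in% c(2L, 3L)] <- NA
  if (honour_exclusions && "excluded_from_histology" %in% names(cohort))
    grp[cohort$excluded_from_histology] <- NA
  f <- factor(grp, levels = c("low", "high"))
  attr(f, "n") <- table(f)
  f
}

#' Transform RSEM expression values to log2 scale
#'
#' Default is `log2(value + 1)`; the `"log2m1"` variant `log2(value - 1)` is
#' retained as a documented alternative (it is undefined below 1 and is
#' returned as NA there). The variant used is recorded in the
#' `"transform"` attribute.
#'
#' @param values Non-negative RSEM values.
#' @param variant `"log2p1"` (default) or `"log2m1"`.
#' @return Transformed values with attribute `"transform"`.
#' @export
transform_rsem <- function(values, variant = c("log2p1", "log2m1")) {
  variant <- match.arg(variant)
  if (any(values < 0, na.rm = TRUE)) stop("RSEM values must be >= 0")
  out <- if (variant == "log2p1") log2(values + 1) else {
    o <- rep(NA_real_, length(values))
    ok <- !is.na(values) & values > 1
    o[ok] <- log2(values[ok] - 1)
    o
  }
  attr(out, "transform") <- variant
  out
}
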