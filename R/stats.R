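#' Mann-Whitney U test
#'
#' U is computed from midranks (tie-tolerant). The two-sided p-value is
#' exact — from the null permutation distribution of U — when the smaller
#' sample has at most `exact_max` values and there are no ties; otherwise
#' the normal approximation with tie-corrected variance is used (no
#' continuity correction). The branch taken is reported in `method`.
#'
#' @param a,b numeric samples (each >= 1 value).
#' @param exact_max largest min(n) for which the exact path is used.
#' @return list with `U` (for sample `a`), `p`, `method`
#'   (`"exact"`/`"normal"`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (min(n1, n2) <= exact_max && !ties) {
    # exact null distribution of U (pwilcox is that distribution)
    lo <- stats::pwilcox(U, n1, n2)
    hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (U - n1 * n2 / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = p, method = method, n1 = n1, n2 = n2)
}

#' Paired t-test on matched cells
#'
#' Two-sided t-test on within-pair differences (df = n - 1). Pairs are
#' matched by `ids`; all-zero differences give t = 0, p = 1; constant
#' nonzero differences are flagged degenerate with p = 0.
#'
#' @param before,after per-cell values.
#' @param ids_before,ids_after per-cell identifiers; when given, the two
#'   id sets must match and are used to align the pairs (default:
#'   positional pairing).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_t <- function(before, after, ids_before = NULL, ids_after = NULL) {
  if (is.null(ids_before)) {
    if (length(before) != length(after)) stop("pairing error: unequal lengths")
    d <- after - before
  } else {
    if (anyDuplicated(ids_before) || anyDuplicated(ids_after) ||
        !setequal(ids_before, ids_after) ||
        length(before) != length(ids_before) ||
        length(after) != length(ids_after)) {
      stop("pairing error: ids must match one-to-one across conditions")
    }
    d <- after[match(ids_before, ids_after)] - before
  }
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1, degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       degenerate = FALSE)
}

#' Welch two-sample t-test
#'
#' Two-sided, unequal-variance (Welch-Satterthwaite df). Two constant
#' samples give p = 1 when the means agree and p = 0 otherwise.
#'
#' @param a,b numeric samples (>= 2 values each).
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Significance mark for a p-value
#'
#' `"n.s."` for p >= 0.05, `"*"` for p < 0.05, `"**"` for p < 0.01,
#' `"***"` for p < 0.001 (strict inequalities; the most extreme applicable
#' mark is returned). Vectorized.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of marks.
#' @export
significance_marks <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "n.s.")))
}

#' Summary table for per-condition value samples
#'
#' Per condition: n, arithmetic mean, sample SD, median, and the two
#' centre quartiles (linear-interpolation / type-7 rule). SD is `NA` for a
#' single value.
#'
#' @param samples named list of numeric vectors (names are condition
#'   labels).
#' @return data frame with one row per condition.
#' @export
summarize_counts <- function(samples) {
  stopifnot(length(samples) >= 1L)
  if (is.null(names(samples))) {
    names(samples) <- paste0("condition_", seq_along(samples))
  }
  rows <- lapply(names(samples), function(lbl) {
    v <- samples[[lbl]]
    if (any(!is.finite(v))) stop("values must be finite in condition ", lbl)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(condition = lbl, n = length(v), mean = mean(v),
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
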