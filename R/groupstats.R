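#' One-tailed Mann-Whitney U test with the ties-count-half convention
#'
#' The statistic is `U = #\{(x, y): x > y\} + 0.5 * #\{ties\}`, so
#' `U < n1 * n2 / 2` indicates group 1 tends to be smaller. The p-value is
#' the exact permutation probability of the observed tail when
#' `n1 * n2 <= 400` (computed by the shift-algorithm recursion over
#' mid-ranks, identical to full enumeration and valid under ties), and the
#' normal approximation with tie correction and continuity correction
#' otherwise. Medians use the usual midpoint convention for even sizes.
#'
#' @param xs,ys Numeric vectors of scores (non-empty, finite).
#' @param alternative `"less"` (is group 1 stochastically smaller?) or
#'   `"greater"`.
#' @return A `mig_comparison` object: n1, n2, median1, median2, U, p,
#'   alternative and method (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_one_tailed(c(1, 2), c(3, 4), "less")  # U = 0, p = 1/6
#' @export
mann_whitney_one_tailed <- function(xs, ys, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  xs <- as.numeric(xs)
  ys <- as.numeric(ys)
  if (!length(xs) || !length(ys)) stop("both score lists must be non-empty")
  if (any(!is.finite(c(xs, ys)))) stop("scores must be finite")
  n1 <- length(xs)
  n2 <- length(ys)
  pooled <- c(xs, ys)
  r <- rank(pooled)  # mid-ranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 * n2 <= 400) {
    # Condition the DP on the smaller group (via U(x,y) = n1*n2 - U(y,x))
    # to keep the rank-sum table small.
    if (n1 <= n2) {
      p <- .mw_exact_p(r, n1, U, alternative)
    } else {
      r2 <- c(r[(n1 + 1):(n1 + n2)], r[seq_len(n1)])
      alt2 <- if (alternative == "less") "greater" else "less"
      p <- .mw_exact_p(r2, n2, n1 * n2 - U, alt2)
    }
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all values identical: observed tail has probability one
    } else if (alternative == "less") {
      p <- stats::pnorm((U + 0.5 - mu) / sqrt(sigma2))
    } else {
      p <- 1 - stats::pnorm((U - 0.5 - mu) / sqrt(sigma2))
    }
    method <- "normal"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(n1 = n1, n2 = n2,
                 median1 = stats::median(xs), median2 = stats::median(ys),
                 U = U, p = p, alternative = alternative, method = method),
            class = "mig_comparison")
}

# Exact permutation distribution of U via the distribution of the group-1
# mid-rank sum over all choose(n1+n2, n1) subsets. Doubled mid-ranks are
# integers, so a shift-algorithm DP over (items taken, doubled rank sum)
# counts subsets exactly; counts stay below 2^53 for any n with
# n1 * n2 <= 400.
.mw_exact_p <- function(r, n1, U, alternative) {
  w <- as.integer(round(2 * r))
  n <- length(w)
  maxsum <- sum(sort(w, decreasing = TRUE)[seq_len(n1)])
  # f[k + 1, s + 1] = number of k-subsets with doubled rank sum s
  f <- matrix(0, n1 + 1L, maxsum + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(n)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      shifted <- c(rep(0, w[i]), f[k, seq_len(maxsum + 1L - w[i])])
      f[k + 1L, ] <- f[k + 1L, ] + shifted
    }
  }
  counts <- f[n1 + 1L, ]
  total <- sum(counts)
  us <- (seq_along(counts) - 1L) / 2 - n1 * (n1 + 1) / 2  # U for each sum
  if (alternative == "less") {
    sum(counts[us <= U + 1e-9]) / total
  } else {
    sum(counts[us >= U - 1e-9]) / total
  }
}

#' Compare the instability scores of two sets of MIGs
#'
#' Reads two 2-column score lists — (MIG identifier, instability score),
#' comma- or tab-delimited — and tests whether the first group's scores are
#' stochastically smaller with a one-tailed Mann-Whitney U test.
#'
#' @param file_a,file_b Paths to the two score lists.
#' @param alternative Passed to [mann_whitney_one_tailed()]; default
#'   `"less"` (is group A smaller?).
#' @return A `mig_comparison` object.
#' @export
compare_mig_sets <- function(file_a, file_b, alternative = "less") {
  a <- .read_score_list(file_a)
  b <- .read_score_list(file_b)
  mann_whitney_one_tailed(a, b, alternative)
}

.read_score_list <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keep <- nzchar(trimws(lines))
  scores <- numeric(0)
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    parts <- strsplit(trimws(lines[i]), "[,\t]")[[1]]
    parts <- trimws(parts)
    val <- suppressWarnings(as.numeric(parts[length(parts)]))
    if (length(parts) < 2L || is.na(val)) {
      # tolerate a single header line naming the columns
      if (i == 1L && any(grepl("cluster|score|id", parts, ignore.case = TRUE))) next
      stop("malformed score row at line ", i, " of ", file)
    }
    scores <- c(scores, val)
  }
  if (!length(scores)) stop("no scores found in ", file)
  scores
}

#' @export
print.mig_comparison <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U (one-tailed, %s; %s p): n = %d vs %d, medians = %g vs %g, U = %g, p = %.4g\n",
    x$alternative, x$method, x$n1, x$n2, x$median1, x$median2, x$U, x$p))
  invisible(x)
}
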