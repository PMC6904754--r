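# Cross-modality agreement statistics: Bland-Altman limits of agreement
# on per-FPU percent differences, and the Wilcoxon rank-sum test with an
# exact small-sample path.

#' Pair MRI and CT FBV estimates by (subject, FPU)
#'
#' Inner join on `(subject_id, fpu)`; the count of unpaired rows is
#' attached as attribute `n_unpaired` and reported via a message.
#'
#' @param mri,ct `data.frame`s of estimates (as from [run_study()]),
#'   single modality each.
#' @return `data.frame` with `subject_id`, `fpu`, `fbv_mri`, `fbv_ct`.
#' @export
pair_estimates <- function(mri, ct) {
  m <- mri[, c("subject_id", "fpu", "fbv")]
  names(m)[3] <- "fbv_mri"
  c2 <- ct[, c("subject_id", "fpu", "fbv")]
  names(c2)[3] <- "fbv_ct"
  paired <- merge(m, c2, by = c("subject_id", "fpu"))
  n_unpaired <- (nrow(m) - nrow(paired)) + (nrow(c2) - nrow(paired))
  if (n_unpaired > 0) message(n_unpaired, " unpaired FPU estimate(s) excluded")
  attr(paired, "n_unpaired") <- n_unpaired
  paired[order(paired$subject_id, paired$fpu), ]
}

#' Bland-Altman agreement on percent differences
#'
#' Per-pair percent difference `100 * (a - b) / ((a + b)/2)`, mean bias,
#' and 95% limits of agreement at bias +/- 1.96 sample SD, plus the
#' fraction of pairs falling inside the limits. The percent scale matches
#' how method-agreement results for FBV are usually plotted; the absolute
#' differences are returned alongside for completeness.
#'
#' @param a,b Numeric vectors of paired measurements (e.g. MRI and CT
#'   FBV), equal length >= 2, or a `data.frame` from [pair_estimates()]
#'   passed as `a` (with `b` missing).
#' @return Object of class `bland_altman_result`: `percent_diff`,
#'   `abs_diff`, `mean_bias`, `sd_diff`, `lower_limit`, `upper_limit`
#'   (all on the percent scale), `fraction_within`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (missing(b) && is.data.frame(a)) {
    b <- a$fbv_ct; a <- a$fbv_mri
  }
  stopifnot(length(a) == length(b), length(a) >= 2L)
  pair_mean <- (a + b) / 2
  if (any(pair_mean == 0)) {
    stop("a pair sums to zero; percent difference undefined", call. = FALSE)
  }
  pct <- 100 * (a - b) / pair_mean
  bias <- mean(pct)
  sd_diff <- stats::sd(pct)
  lower <- bias - 1.96 * sd_diff
  upper <- bias + 1.96 * sd_diff
  structure(
    list(percent_diff = pct, abs_diff = a - b, mean_bias = bias,
         sd_diff = sd_diff, lower_limit = lower, upper_limit = upper,
         fraction_within = mean(pct >= lower & pct <= upper),
         n = length(a)),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman_result> n = %d, bias = %.2f%%, ",
                     "limits [%.2f%%, %.2f%%], %.0f%% within\n"),
              x$n, x$mean_bias, x$lower_limit, x$upper_limit,
              100 * x$fraction_within))
  invisible(x)
}

# exact two-sided rank-sum p by full enumeration of the C(n, nx) ways to
# assign nx of the pooled ranks 1..n to x; tie-free inputs only
rank_sum_exact_p <- function(n, nx, w_obs) {
  w_all <- colSums(utils::combn(n, nx))
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test on the rank sum of `x` within the pooled sample. With
#' `n_x + n_y <= exact_max_n` and no ties, the p-value is exact by full
#' enumeration of all rank assignments; otherwise the normal
#' approximation with midranks, tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param exact_max_n Largest pooled size for the exact path (default 20).
#' @return Object of class `rank_sum_result`: `statistic` (rank sum of
#'   `x`), `method` (`"EXACT"` or `"NORMAL_APPROX"`), `p_two_sided`,
#'   `stars`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs >= 2 observations", call. = FALSE)
  }
  pooled <- c(x, y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  ranks <- rank(pooled)          # midranks under ties
  w <- sum(ranks[seq_len(nx)])
  ties <- any(duplicated(pooled))

  if (!ties && n <= exact_max_n) {
    p <- rank_sum_exact_p(n, nx, w)
    method <- "EXACT"
  } else {
    mu <- nx * (n + 1) / 2
    tie_counts <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "NORMAL_APPROX"
  }
  structure(list(statistic = w, method = method, p_two_sided = p,
                 stars = significance_stars(p)),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("<rank_sum_result> W = %g, p = %.4g (%s) %s\n",
              x$statistic, x$p_two_sided, x$method,
              strrep("*", x$stars)))
  invisible(x)
}

#' Significance tiers as asterisk counts
#'
#' 3 stars for p < 0.0005, 2 for p < 0.005, 1 for p < 0.05, else 0
#' (strict inequalities).
#'
#' @param p P-value(s) in (0, 1].
#' @return Integer star count(s).
#' @export
significance_stars <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  ifelse(p < 0.0005, 3L, ifelse(p < 0.005, 2L, ifelse(p < 0.05, 1L, 0L)))
}
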