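# Bias and quantification statistics: two-sample KS, rank-sum, Fisher's exact
# depletion, fold-depletion, stage-ratio distributions, FRAP relative recovery.
# The distributional tests are computed with the base R engines (ks.test,
# wilcox.test, fisher.test); small-sample exact p values are available by
# enumeration of label assignments.

.ks_D <- function(x, y) {
  # sup |ECDF_x - ECDF_y| evaluated at the pooled points
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. The p value is
#' asymptotic (Kolmogorov distribution) by default; with
#' `method = "permutation"` it is computed exactly by enumerating all label
#' assignments (practical for n + m up to about 12).
#'
#' @param x,y Numeric samples.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "permutation")) {
  method <- match.arg(method)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  D <- .ks_D(x, y)
  if (method == "asymptotic") {
    p <- suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value)
  } else {
    pooled <- c(x, y)
    n <- length(x)
    combs <- utils::combn(length(pooled), n)
    Ds <- apply(combs, 2, function(ix) .ks_D(pooled[ix], pooled[-ix]))
    p <- mean(Ds >= D - 1e-12)
  }
  list(D = D, p = p)
}

.U_stat <- function(x, y) {
  r <- rank(c(x, y))  # midranks for ties
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with midrank tie handling. The p value is the tie-corrected
#' normal approximation, or (default when n + m <= 12, or on request) the
#' exact two-sided enumeration over all label assignments:
#' `p = Pr(|U - nm/2| >= |U_obs - nm/2|)`.
#'
#' @param x,y Numeric samples.
#' @param method `"auto"` (exact when n + m <= 12), `"exact"`, or `"normal"`.
#' @return List with `U` and `p`.
#' @export
rank_sum_test <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n <- length(x); m <- length(y)
  U <- .U_stat(x, y)
  if (method == "auto") method <- if (n + m <= 12L) "exact" else "normal"
  if (method == "exact") {
    pooled <- c(x, y)
    combs <- utils::combn(n + m, n)
    Us <- apply(combs, 2, function(ix) .U_stat(pooled[ix], pooled[-ix]))
    mu <- n * m / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  list(U = U, p = p)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric two-sided p value (the sum of table
#' probabilities no larger than the observed one, the standard two-sided
#' convention) together with the sample odds ratio `(a d) / (b c)`; a zero
#' denominator with a nonzero numerator yields `Inf`, 0/0 yields `NaN`.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab))) {
    stop("tab must be a 2x2 matrix of non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("table total must be positive", call. = FALSE)
  p <- stats::fisher.test(tab)$p.value
  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  or <- if (den == 0 && num == 0) NaN else num / den
  list(odds_ratio = or, p = p)
}

#' Fold depletion of high-interface-index proteins from the abundant group
#'
#' With the ribosomal proteins split into an abundant and a non-abundant
#' group, the fold depletion of high-index (core-penetrating) proteins from
#' the abundant group is the ratio of high-index fractions:
#' `fold = frac(index > index_cut | non-abundant) / frac(index > index_cut | abundant)`
#' (baseline `"non_abundant"`, the default) or relative to all proteins
#' (baseline `"all"`).
#'
#' @param index_by_rp Named numeric vector, RP name to interface-index.
#' @param abundant Character vector of RP names in the abundant group.
#' @param index_cut Strict high-index threshold (default 0.6).
#' @param baseline `"non_abundant"` or `"all"`.
#' @return List with `fold`, `frac_abundant`, `frac_baseline`, and `infinite`
#'   flag (TRUE when the abundant group contains no high-index protein).
#' @export
depletion_fold <- function(index_by_rp, abundant, index_cut = 0.6,
                           baseline = c("non_abundant", "all")) {
  baseline <- match.arg(baseline)
  rp <- names(index_by_rp)
  in_ab <- rp %in% abundant
  if (!any(in_ab) || !any(!in_ab)) {
    stop("both the abundant and the non-abundant group must be non-empty",
         call. = FALSE)
  }
  high <- index_by_rp > index_cut
  if (!any(high)) {
    stop("no protein exceeds the index cutoff; fold depletion undefined",
         call. = FALSE)
  }
  fa <- mean(high[in_ab])
  fb <- if (baseline == "non_abundant") mean(high[!in_ab]) else mean(high)
  if (fa == 0) {
    warning("no high-index protein in the abundant group; fold is infinite",
            call. = FALSE)
    return(list(fold = Inf, frac_abundant = 0, frac_baseline = fb,
                infinite = TRUE))
  }
  list(fold = fb / fa, frac_abundant = fa, frac_baseline = fb,
       infinite = FALSE)
}

#' Interface-index vs abundance bias statistics
#'
#' The full bias summary relating ribosomal-protein structural position to
#' mRNA abundance: mean interface-index of the abundant (FPKM above
#' `fpkm_cut`, strict) and non-abundant groups, a two-sample KS test between
#' the two index distributions, Fisher's exact test on the 2x2 table of
#' (high index vs low index) x (abundant vs non-abundant), and the fold
#' depletion of high-index proteins from the abundant group.
#'
#' @param index_by_rp Named numeric vector, RP name to interface-index.
#' @param fpkm Named numeric vector, RP name to abundance (FPKM); names must
#'   cover `names(index_by_rp)`.
#' @param fpkm_cut Strict abundance threshold (default 100).
#' @param index_cut Strict high-index threshold (default 0.6).
#' @return A list of class `bias_result`: `group_hi_mean`, `group_lo_mean`,
#'   `ks_D`, `ks_p`, `fisher_table`, `fisher_p`, `odds_ratio`,
#'   `fold_depletion`, `n_abundant`, `n_non_abundant`, and the thresholds.
#' @export
abundance_bias <- function(index_by_rp, fpkm, fpkm_cut = 100, index_cut = 0.6) {
  rp <- names(index_by_rp)
  if (!all(rp %in% names(fpkm))) {
    stop("every RP with an index needs an abundance value", call. = FALSE)
  }
  ab <- fpkm[rp] > fpkm_cut
  if (!any(ab) || !any(!ab)) {
    stop("abundance split produced an empty group", call. = FALSE)
  }
  ks <- ks_two_sample(index_by_rp[ab], index_by_rp[!ab])
  high <- index_by_rp > index_cut
  tab <- matrix(c(sum(high & ab), sum(high & !ab),
                  sum(!high & ab), sum(!high & !ab)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("high_index", "low_index"),
                                c("abundant", "non_abundant")))
  fe <- fisher_exact_2x2(tab)
  fd <- tryCatch(depletion_fold(index_by_rp, rp[ab], index_cut = index_cut),
                 error = function(e) list(fold = NA_real_, infinite = FALSE))
  structure(
    list(group_hi_mean = mean(index_by_rp[ab]),
         group_lo_mean = mean(index_by_rp[!ab]),
         ks_D = ks$D, ks_p = ks$p,
         fisher_table = tab, fisher_p = fe$p, odds_ratio = fe$odds_ratio,
         fold_depletion = fd$fold,
         n_abundant = sum(ab), n_non_abundant = sum(!ab),
         fpkm_cut = fpkm_cut, index_cut = index_cut),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("<bias_result> abundant (FPKM > %g, n = %d) mean index %.3f vs non-abundant (n = %d) %.3f\n",
              x$fpkm_cut, x$n_abundant, x$group_hi_mean, x$n_non_abundant,
              x$group_lo_mean))
  cat(sprintf("  KS D = %.3f, p = %.3g; Fisher p = %.3g; %.2f-fold depletion of index > %g\n",
              x$ks_D, x$ks_p, x$fisher_p, x$fold_depletion, x$index_cut))
  invisible(x)
}

#' Stage-to-stage abundance ratio distributions
#'
#' Per-transcript abundance ratio between two consecutive developmental
#' stages, `(fpkm_b + pc) / (fpkm_a + pc)` on shared transcripts (returned as
#' log2 ratios), with a two-sample KS comparison of the
#' ribosomal-protein and non-RP ratio distributions.
#'
#' @param fpkm_a,fpkm_b Named numeric vectors, transcript id to FPKM at the
#'   earlier (a) and later (b) stage.
#' @param is_rp Named logical vector flagging RP transcripts.
#' @param pseudocount Added to both stages before forming the ratio
#'   (default 1.0); with `pseudocount = 0` any zero FPKM at stage a is an
#'   error.
#' @return List with `log2_ratio` (named), `ks_D`, `ks_p`, `n_rp`, `n_nonrp`.
#' @export
stage_ratio_distribution <- function(fpkm_a, fpkm_b, is_rp, pseudocount = 1.0) {
  shared <- intersect(names(fpkm_a), names(fpkm_b))
  shared <- shared[shared %in% names(is_rp)]
  rp_ids <- shared[is_rp[shared]]
  non_ids <- shared[!is_rp[shared]]
  if (length(rp_ids) < 2L || length(non_ids) < 2L) {
    stop("need at least 2 shared transcripts in each class", call. = FALSE)
  }
  if (pseudocount == 0 && any(fpkm_a[shared] == 0)) {
    stop("zero FPKM at stage a with pseudocount 0", call. = FALSE)
  }
  ratio <- (fpkm_b[shared] + pseudocount) / (fpkm_a[shared] + pseudocount)
  lr <- log2(ratio)
  ks <- ks_two_sample(lr[rp_ids], lr[non_ids])
  list(log2_ratio = lr, ks_D = ks$D, ks_p = ks$p,
       n_rp = length(rp_ids), n_nonrp = length(non_ids))
}

#' FRAP relative recovery
#'
#' Relative fluorescence recovery after photobleaching at each timepoint:
#' `Rx = (Ix - Ipost) / (Ipre - Ipost)`, applied after background
#' subtraction. Recovery is 0 at the immediate post-bleach intensity and 1 at
#' the pre-bleach intensity.
#'
#' @param Ix Numeric vector of per-timepoint intensities (per unit area).
#' @param Ipre,Ipost Pre-bleach and immediate post-bleach intensities.
#' @param bg_x Background intensity per timepoint (scalar or vector matching
#'   `Ix`; default 0).
#' @param bg_pre,bg_post Backgrounds for the pre/post readings (default 0).
#' @return Numeric vector of recovery fractions.
#' @export
frap_relative_recovery <- function(Ix, Ipre, Ipost, bg_x = 0, bg_pre = 0,
                                   bg_post = 0) {
  ix <- Ix - bg_x
  ipre <- Ipre - bg_pre
  ipost <- Ipost - bg_post
  if (!(ipre > ipost)) {
    stop("recovery undefined: background-corrected Ipre must exceed Ipost",
         call. = FALSE)
  }
  (ix - ipost) / (ipre - ipost)
}
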