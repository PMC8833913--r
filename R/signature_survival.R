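#' Geometric-mean signature score
#'
#' Per-sample score of a gene signature: the arithmetic mean of the log2
#' expression values over the signature genes present in the matrix, which is
#' the log2 of the geometric mean on the linear scale. Inputs are expected on
#' a nonnegative log2(normalized + 1)-style scale; signature genes absent
#' from the matrix are reported via the `"missing_genes"` attribute, never
#' imputed.
#'
#' @param values Numeric matrix, features x samples, nonnegative log2 scale.
#' @param genes Character vector of signature gene IDs; at least one must be
#'   present in `rownames(values)`.
#' @return Named numeric vector of per-sample scores (log2 space), attribute
#'   `missing_genes`.
#' @examples
#' m <- rbind(g1 = c(s1 = 2, s2 = 4), g2 = c(s1 = 4, s2 = 4))
#' signature_score(m, c("g1", "g2"))  # s1: log2 geometric mean of 4 and 16 = 3
#' @export
signature_score <- function(values, genes) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (any(values < 0, na.rm = TRUE)) {
    stop("signature_score: negative log2 values; scores expect a log2(x + 1)-style nonnegative scale")
  }
  present <- intersect(unique(genes), rownames(values))
  if (length(present) == 0L) {
    stop("signature_score: none of the ", length(unique(genes)),
         " signature genes are present in the matrix")
  }
  score <- colMeans(values[present, , drop = FALSE], na.rm = TRUE)
  attr(score, "missing_genes") <- setdiff(unique(genes), present)
  score
}

#' Dichotomize scores at the density valley between the two main peaks
#'
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth,
#' 512-point grid spanning the data plus three bandwidths on each side). If
#' the estimate has two or more modes, the threshold is the location of the
#' density minimum between the two highest peaks; a unimodal estimate falls
#' back to the median split. Two prominence guards keep finite-sample ripple
#' in an essentially unimodal distribution from producing a degenerate
#' split: local maxima below `min_peak_frac` of the global maximum are not
#' modes, and the valley must drop below `max_valley_frac` of the lower of
#' the two peaks (KDE ripple on unimodal samples leaves dips above ~0.9,
#' while genuinely bimodal mixtures dip below ~0.3). Deterministic for fixed
#' input and exactly translation-equivariant.
#'
#' @param scores Numeric vector, at least 10 values, not all identical.
#' @param min_peak_frac Mode height floor as a fraction of the highest peak
#'   (default 0.05).
#' @param max_valley_frac Maximum valley-to-lower-peak density ratio for the
#'   split to count as bimodal (default 0.8).
#' @return List with `threshold`, `stratum` (`"high"`/`"low"` per score,
#'   named like `scores`), `method` (`"density_valley"` or `"median"`),
#'   `bandwidth`, `n_peaks`.
#' @export
density_dichotomize <- function(scores, min_peak_frac = 0.05,
                                max_valley_frac = 0.8) {
  x <- as.numeric(scores)
  if (length(x) < 10L) stop("density_dichotomize: need at least 10 scores")
  if (anyNA(x)) stop("density_dichotomize: NA scores")
  if (max(x) == min(x)) stop("density_dichotomize: all scores identical; no stratification possible")
  d <- stats::density(x, bw = "nrd0", n = 512, cut = 3)
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_peak & y >= min_peak_frac * max(y))
  method <- "median"
  threshold <- stats::median(x)
  if (length(peaks) >= 2L) {
    top2 <- sort(peaks[order(-y[peaks])][1:2])
    valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
    if (y[valley] < max_valley_frac * min(y[top2])) {
      threshold <- d$x[valley]
      method <- "density_valley"
    }
  }
  stratum <- ifelse(x > threshold, "high", "low")
  names(stratum) <- names(scores)
  list(threshold = threshold, stratum = stratum, method = method,
       bandwidth = d$bw, n_peaks = length(peaks))
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous, non-increasing survival step function with `S(0) = 1`;
#' censored observations leave later risk sets without contributing a step.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return `data.frame` with columns `time`, `n_risk`, `n_event`, `surv`,
#'   one row per distinct observed time.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L, all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with one degree of freedom for exactly two
#' strata; two-sided p value.
#'
#' @param time,event As in [km_estimate()].
#' @param stratum Two-level stratum labels per sample.
#' @return List with `statistic`, `p_value`, `n_events`.
#' @export
logrank_test <- function(time, event, stratum) {
  stratum <- as.character(stratum)
  lv <- unique(stratum)
  if (length(lv) != 2L) {
    stop("logrank_test: need exactly 2 strata, got ", length(lv))
  }
  if (sum(event) < 1L) stop("logrank_test: no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_events = sum(event))
}

#' Single-covariate Cox proportional hazards fit
#'
#' Newton maximization of the Cox partial likelihood with Breslow handling of
#' tied event times, written out directly for the one-covariate case. The
#' hazard ratio is `exp(coefficient)` per unit of the covariate.
#' Non-convergence and monotone-likelihood (perfect separation) fits are
#' flagged, never returned as silent numbers.
#'
#' @param time,event As in [km_estimate()]; at least one event.
#' @param covariate Per-sample numeric covariate (e.g. a signature score or a
#'   0/1 stratum indicator); must not be constant.
#' @param max_iter,tol Newton iteration controls.
#' @return List with `coef`, `hr`, `se`, `z`, `p_value`, `converged`,
#'   `flag` (`NA` or a description of the pathology), `n_events`, `iter`.
#' @export
cox_hr <- function(time, event, covariate, max_iter = 30L, tol = 1e-9) {
  stopifnot(length(time) == length(event), length(time) == length(covariate))
  keep <- is.finite(time) & is.finite(covariate) & !is.na(event)
  time <- time[keep]; event <- as.integer(event[keep]); x <- as.numeric(covariate[keep])
  if (sum(event) < 1L) stop("cox_hr: no events")
  if (stats::sd(x) == 0) stop("cox_hr: constant covariate")
  x <- x - mean(x)  # centering for numerical stability; coef is unchanged
  ord <- order(-time)
  t_s <- time[ord]; d_s <- event[ord]; x_s <- x[ord]
  # risk set of an event at time t = everyone with time >= t; with descending
  # sort, that is the prefix up to the last index sharing t
  r <- rle(t_s)
  rs_end <- rep(cumsum(r$lengths), r$lengths)
  ev <- which(d_s == 1L)
  beta <- 0
  converged <- FALSE
  flag <- NA_character_
  info <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- exp(beta * x_s)
    s0 <- cumsum(w)[rs_end[ev]]
    s1 <- cumsum(w * x_s)[rs_end[ev]]
    s2 <- cumsum(w * x_s^2)[rs_end[ev]]
    score <- sum(x_s[ev] - s1 / s0)
    info <- sum(s2 / s0 - (s1 / s0)^2)
    if (!is.finite(score) || !is.finite(info) || info <= 0) {
      flag <- "degenerate information matrix"
      break
    }
    step <- score / info
    beta <- beta + step
    if (abs(beta) > 15) {
      flag <- "monotone likelihood (perfect separation)"
      break
    }
    if (abs(step) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && is.na(flag)) flag <- "Newton iteration limit reached"
  se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  z <- if (!is.na(se)) beta / se else NA_real_
  list(
    coef = beta, hr = exp(beta), se = se, z = z,
    p_value = if (!is.na(z)) 2 * stats::pnorm(-abs(z)) else NA_real_,
    converged = converged, flag = flag, n_events = sum(event), iter = it
  )
}

#' Pairwise Welch comparisons of score groups
#'
#' Welch two-sample t test for every pair of groups, through the same code
#' path as the per-feature differential test, so the two surfaces agree
#' bit-for-bit on identical inputs. Differences are `mean(second) -
#' mean(first)` in pair order.
#'
#' @param groups Named list of numeric score vectors, at least 2 per group.
#' @return `data.frame` with columns `group_a`, `group_b`, `difference`,
#'   `statistic`, `p_value`.
#' @export
compare_scores <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  bad <- names(groups)[vapply(groups, function(g) sum(is.finite(g)) < 2L, logical(1))]
  if (length(bad)) {
    stop("compare_scores: groups with fewer than 2 usable values: ",
         paste(bad, collapse = ", "))
  }
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  rows <- apply(pairs, 2, function(pr) {
    w <- .welch_two_sample(groups[[pr[1]]], groups[[pr[2]]])
    data.frame(group_a = pr[1], group_b = pr[2], difference = w$diff,
               statistic = w$statistic, p_value = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trim a signature by univariate survival association
#'
#' Fits a univariate Cox model ([cox_hr()]) per signature gene on its
#' expression row, ranks genes by ascending p value (ties broken
#' lexicographically) and keeps the top `k`.
#'
#' @param values Numeric matrix, features x samples (log2 expression).
#' @param time,event Survival outcome per sample (columns of `values`).
#' @param genes Signature gene IDs.
#' @param k Number of genes to keep (default 20); must not exceed the number
#'   of signature genes present in the matrix.
#' @return Character vector of the `k` retained genes, with attribute
#'   `ranking` (data.frame `gene`, `coef`, `p_value` over all present genes).
#' @export
trim_by_survival <- function(values, time, event, genes, k = 20L) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  present <- intersect(unique(genes), rownames(values))
  if (length(present) == 0L) stop("trim_by_survival: no signature genes present")
  k <- as.integer(k)
  if (k < 1L || k > length(present)) {
    stop("trim_by_survival: k must be in 1..", length(present))
  }
  fits <- lapply(present, function(g) cox_hr(time, event, values[g, ]))
  ranking <- data.frame(
    gene = present,
    coef = vapply(fits, `[[`, numeric(1), "coef"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  ranking <- ranking[order(ranking$p_value, ranking$gene, method = "radix"), ]
  rownames(ranking) <- NULL
  out <- ranking$gene[seq_len(k)]
  attr(out, "ranking") <- ranking
  out
}
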