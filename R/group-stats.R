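#' Likelihood-ratio test for two binomial proportions
#'
#' G-test comparing k1/n1 against k2/n2: twice the log-likelihood-ratio of
#' the saturated (two-proportion) binomial model over the pooled-proportion
#' model, referred to a chi-square distribution with 1 df. Boundary counts
#' (k = 0 or k = n) are handled with the 0*log(0) = 0 convention.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return list with \code{chi2} (the G statistic), \code{p}, \code{p1},
#'   \code{p2} (the two sample proportions).
#' @examples
#' proportionLRT(50, 100, 10, 100)
#' @export
proportionLRT <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("group totals must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("counts must satisfy 0 <= k <= n")
  xlogx <- function(x) ifelse(x == 0, 0, x * log(x))
  ll <- function(k, n, p) {
    if (p <= 0 || p >= 1) {
      # boundary MLE: likelihood is 1 when the data are all-or-none
      if ((p <= 0 && k == 0) || (p >= 1 && k == n)) return(0)
      return(-Inf)
    }
    k * log(p) + (n - k) * log(1 - p)
  }
  p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
  g <- 2 * (ll(k1, n1, p1) + ll(k2, n2, p2) -
              ll(k1, n1, pp) - ll(k2, n2, pp))
  g <- max(0, g)  # guard tiny negative round-off when p1 == p2
  list(chi2 = g, p = stats::pchisq(g, df = 1, lower.tail = FALSE),
       p1 = p1, p2 = p2)
}

#' Format a "k of n (p%)" sensitivity line
#'
#' @param k number of frequency-sensitive neurons.
#' @param n total neurons.
#' @return character, e.g. \code{"693 of 3604 (19.23\%)"}.
#' @export
formatCountLine <- function(k, n) {
  sprintf("%d of %d (%.2f%%)", k, n, 100 * k / n)
}

#' Per-class response and reliability statistics
#'
#' Mean +/- SEM of the trial-averaged response at BF and of the Fano factor
#' for each FRA class, with Welch t-tests between every pair of classes.
#'
#' @param classifications row-bound output of [classifyNeurons()] across
#'   fields.
#' @param classes classes to compare.
#' @return list with \code{summary} (per-class n, mean, sem for
#'   response_at_bf and fano_factor) and \code{tests} (pairwise Welch t and
#'   p per measure).
#' @export
classGroupStats <- function(classifications,
                            classes = c("single", "double", "complex")) {
  d <- classifications[classifications$is_sensitive &
                         classifications$label %in% classes, , drop = FALSE]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(classes, function(cls) {
    s <- d[d$label == cls, ]
    data.frame(label = cls, n = nrow(s),
               response_mean = mean(s$response_at_bf, na.rm = TRUE),
               response_sem = sem(stats::na.omit(s$response_at_bf)),
               fano_mean = mean(s$fano_factor, na.rm = TRUE),
               fano_sem = sem(stats::na.omit(s$fano_factor)))
  }))
  pairs <- utils::combn(classes, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- d[d$label == pairs[1, k], ]
    b <- d[d$label == pairs[2, k], ]
    row <- data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
                      response_t = NA_real_, response_p = NA_real_,
                      fano_t = NA_real_, fano_p = NA_real_)
    if (nrow(a) >= 2L && nrow(b) >= 2L) {
      tr <- stats::t.test(a$response_at_bf, b$response_at_bf)
      row$response_t <- unname(tr$statistic); row$response_p <- tr$p.value
      fa <- stats::na.omit(a$fano_factor); fb <- stats::na.omit(b$fano_factor)
      if (length(fa) >= 2L && length(fb) >= 2L) {
        tf <- stats::t.test(fa, fb)
        row$fano_t <- unname(tf$statistic); row$fano_p <- tf$p.value
      }
    }
    row
  }))
  list(summary = summ, tests = tests)
}

#' One-way ANOVA with Tukey HSD on same-class pair correlations
#'
#' Tests whether the mean pairwise correlation differs across FRA classes,
#' using only pairs whose two neurons share a class, then runs Tukey's HSD
#' post-hoc comparisons.
#'
#' @param pairs row-bound output of [pairCorrelations()].
#' @param which \code{"signal"} or \code{"noise"}.
#' @param classes classes to compare.
#' @return list with \code{F}, \code{p}, \code{tukey} (data.frame of
#'   pairwise differences and adjusted p), and per-class \code{means}.
#' @export
correlationClassANOVA <- function(pairs, which = c("signal", "noise"),
                                  classes = c("single", "double", "complex")) {
  which <- match.arg(which)
  d <- pairs[pairs$label_a == pairs$label_b &
               pairs$label_a %in% classes, , drop = FALSE]
  v <- d[[paste0(which, "_r")]]
  cls <- factor(d$label_a, levels = classes)
  keep <- is.finite(v)
  v <- v[keep]; cls <- droplevels(cls[keep])
  if (nlevels(cls) < 2L)
    return(list(F = NA_real_, p = NA_real_, tukey = NULL,
                means = tapply(v, cls, mean)))
  fit <- stats::aov(v ~ cls)
  tab <- summary(fit)[[1]]
  tk <- as.data.frame(stats::TukeyHSD(fit)$cls)
  tk$comparison <- rownames(tk)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1], tukey = tk,
       means = tapply(v, cls, mean), sems = tapply(v, cls, sem))
}
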