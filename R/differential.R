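#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes of
#' `K_ij / g_i`, where `g_i` is the geometric mean of gene i across samples.
#' Genes whose geometric mean is zero (any zero count) are excluded from the
#' median.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  loggm <- rowMeans(log(counts))
  use <- is.finite(loggm)
  if (!any(use)) stop("no gene with all-positive counts; cannot estimate size factors")
  sf <- apply(counts[use, , drop = FALSE], 2, function(k) {
    exp(stats::median(log(k) - loggm[use]))
  })
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Fit a mean-dispersion trend, blind and fit-only
#'
#' All samples are pooled as one group (blind). Per gene, the baseline mean
#' of normalized counts `q_i` and a method-of-moments raw dispersion
#' `(w_i - q_i * mean(1/s_j)) / q_i^2` are computed, where `w_i` is the
#' sample variance of normalized counts (the subtracted term removes the
#' Poisson shot-noise contribution). The trend `alpha(q) = a0 + a1/q` is
#' fitted to all finite raw values by robust iteratively trimmed weighted
#' least squares; negative raw values (replicates less variable than
#' Poisson) stay in the fit so the trend is unbiased at alpha = 0 and
#' p-values remain uniform under a Poisson null. Fitted coefficients are
#' floored at zero, and every gene's working dispersion is the fitted value
#' at its own mean (fit-only: per-gene estimates are never kept), floored
#' at 1e-8.
#'
#' @param counts Integer matrix, genes x samples (>= 2 samples).
#' @param s Size factors from [size_factors()].
#' @return A list of class `DispersionModel`: `coefficients` (a0, a1),
#'   `base_mean` (per-gene q), `dispersion` (per-gene fitted alpha),
#'   `raw` (per-gene raw dispersion, NA where the mean is 0), and
#'   `fit_type` ("parametric" or "constant").
#' @export
fit_dispersion <- function(counts, s) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples to estimate dispersion")
  norm <- sweep(counts, 2, s, "/")
  q <- rowMeans(norm)
  w <- apply(norm, 1, stats::var)
  xi <- mean(1 / s)
  raw <- ifelse(q > 0, (w - q * xi) / q^2, NA_real_)
  usable <- which(is.finite(raw) & q > 0)
  positive <- which(is.finite(raw) & raw > 0)
  fit_type <- "parametric"
  if (length(positive) < 2) {
    warning("fewer than 2 positive raw dispersions; using constant dispersion fit")
    a0 <- if (length(positive)) mean(raw[positive]) else 1e-8
    coefs <- c(a0 = max(a0, 1e-8), a1 = 0)
    fit_type <- "constant"
  } else {
    coefs <- .parametric_dispersion_fit(q[usable], raw[usable], xi)
    if (is.null(coefs)) {
      warning("parametric dispersion fit failed to converge; using constant fit")
      coefs <- c(a0 = max(mean(raw[usable]), 1e-8), a1 = 0)
      fit_type <- "constant"
    }
  }
  disp <- pmax(coefs[["a0"]] + coefs[["a1"]] / q, 1e-8)
  disp[!is.finite(disp)] <- 1e-8  # genes with q = 0
  structure(list(coefficients = coefs, base_mean = q, dispersion = disp,
                 raw = raw, fit_type = fit_type),
            class = "DispersionModel")
}

# Iterated trimmed weighted least squares for alpha(q) = a0 + a1/q. Raw
# moment estimates scatter with standard deviation roughly proportional to
# alpha(q) + xi/q, so residuals are standardized by that scale and each
# round drops genes more than 3 MADs from the median standardized residual
# (the dispersion-outlier rule of the NB differential-expression
# frameworks): under blind pooling, genes with genuine between-condition
# signal show grossly inflated raw dispersions, and the trend is meant to
# describe the typical gene. Negative raw values are retained so the fit
# is centered, not upward-biased, when the data are Poisson; coefficients
# are floored at zero only after convergence. Returns NULL on failure.
.parametric_dispersion_fit <- function(means, disps, xi = 1) {
  df <- data.frame(disps = disps, invq = 1 / means)
  fit0 <- stats::lm(disps ~ invq, data = df)
  coefs <- stats::coef(fit0)
  for (iter in 1:20) {
    old <- coefs
    pred <- coefs[[1]] + coefs[[2]] / means
    scl <- pmax(pmax(pred, 0) + xi / means, 1e-12)
    r <- (disps - pred) / scl
    dev <- abs(r - stats::median(r))
    cut <- max(3 * stats::mad(r), 1e-3)
    good <- which(dev <= cut)
    if (length(good) < 2) return(NULL)
    fit <- tryCatch(stats::lm(disps ~ invq, data = df[good, ],
                              weights = 1 / scl[good]^2),
                    error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(stats::coef(fit)))) return(NULL)
    coefs <- stats::coef(fit)
    if (sum((coefs - old)^2) < 1e-10) break
  }
  coefs <- pmax(coefs, 0)
  names(coefs) <- c("a0", "a1")
  coefs
}

#' Negative-binomial conditional exact test for two condition totals
#'
#' Given the summed counts of two conditions and their summed size factors,
#' each condition total is modeled as negative binomial with mean
#' `mu_c = s_c * q` and variance `mu_c + alpha * s_c^2 * q^2`, where
#' `q = (K_A + K_B)/(s_A + s_B)` is the pooled mean. Conditioning on the
#' grand total S, the p-value is the probability mass of all splits
#' `(a, S-a)` whose joint probability does not exceed that of the observed
#' split, normalized by the total mass — the two-sided exact test of the
#' negative-binomial differential-expression framework. At `alpha_disp = 0`
#' the conditional law is exactly binomial.
#'
#' For totals above `big_total` only a window around the conditional mode is
#' enumerated; the mass outside the window is vanishingly small and always
#' qualifies for the numerator, so the approximation error is negligible.
#'
#' @param K_A,K_B Summed counts per condition.
#' @param s_A,s_B Summed size factors per condition.
#' @param alpha_disp Dispersion at the pooled mean (>= 0).
#' @param big_total Enumeration cutoff (default 1e5).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(K_A, K_B, s_A, s_B, alpha_disp, big_total = 1e5) {
  stopifnot(K_A >= 0, K_B >= 0, s_A > 0, s_B > 0, alpha_disp >= 0)
  S <- K_A + K_B
  if (S == 0) return(1)
  q <- S / (s_A + s_B)
  muA <- s_A * q
  muB <- s_B * q
  if (S <= big_total) {
    a <- 0:S
  } else {
    center <- round(S * muA / (muA + muB))
    half <- ceiling(max(2000, 30 * sqrt(S * (1 + alpha_disp * q))))
    a <- max(0, center - half):min(S, center + half)
    if (!(K_A %in% a)) a <- sort(unique(c(a, K_A)))
  }
  lp <- .nb_logpmf(a, muA, alpha_disp, s_A) +
        .nb_logpmf(S - a, muB, alpha_disp, s_B)
  lobs <- lp[match(K_A, a)]
  qualify <- lp <= lobs + 1e-7
  num <- .logsumexp(lp[qualify])
  den <- .logsumexp(lp)
  min(1, exp(num - den))
}

# log pmf of the condition-total law: NB with mean mu and variance
# mu + alpha * s^2 * q^2 = mu + alpha * mu^2 (since mu = s q), i.e.
# size = 1/alpha independent of the condition; Poisson in the alpha -> 0 limit.
.nb_logpmf <- function(k, mu, alpha, s) {
  if (alpha <= 0) stats::dpois(k, mu, log = TRUE)
  else stats::dnbinom(k, size = 1 / alpha, mu = mu, log = TRUE)
}

.logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`, preserving
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential transcription between two conditions
#'
#' Runs the full negative-binomial exact-test pipeline on an isoform x
#' sample count matrix: size factors (median of ratios), a blind fit-only
#' dispersion trend over all samples, the conditional exact test per
#' isoform on the two conditions' summed counts, and BH adjustment.
#' Isoforms of the same gene are then collapsed by keeping the isoform with
#' the largest absolute (log) fold change, and a gene is called
#' differentially transcribed when its adjusted p-value is at or below
#' `threshold`.
#'
#' Fold changes are ratios of mean normalized counts, condition B over
#' condition A, reported without pseudocounts (0 and Inf are legitimate
#' values at the extremes).
#'
#' @param counts Isoform x sample integer matrix (rownames = isoform ids).
#' @param conditions Character vector of condition labels, one per column.
#' @param comparison Length-2 character: `c(A, B)`; fold change is B/A.
#' @param genes Gene id per isoform (defaults to rownames: one isoform per
#'   gene).
#' @param threshold Adjusted-p cutoff for calling (default 0.1).
#' @return data.frame of class `DEResult`, one row per gene: gene, isoform,
#'   base_mean_A, base_mean_B, fold_change, log2_fold, pval, padj, called.
#' @export
call_differential <- function(counts, conditions, comparison,
                              genes = rownames(counts), threshold = 0.1) {
  counts <- as.matrix(counts)
  stopifnot(length(conditions) == ncol(counts), length(comparison) == 2,
            threshold > 0, threshold < 1)
  if (!all(comparison %in% conditions))
    stop("comparison conditions absent from the matrix: ",
         paste(setdiff(comparison, conditions), collapse = ", "))
  if (is.null(genes)) stop("isoform/gene identifiers required")
  s <- size_factors(counts)
  dm <- fit_dispersion(counts, s)
  colA <- which(conditions == comparison[1])
  colB <- which(conditions == comparison[2])
  kA <- rowSums(counts[, colA, drop = FALSE])
  kB <- rowSums(counts[, colB, drop = FALSE])
  sA <- sum(s[colA])
  sB <- sum(s[colB])
  pooled_q <- (kA + kB) / (sA + sB)
  alpha <- pmax(dm$coefficients[["a0"]] +
                dm$coefficients[["a1"]] / pmax(pooled_q, 1e-8), 1e-8)
  pval <- vapply(seq_along(kA), function(i) {
    nb_exact_test(kA[i], kB[i], sA, sB, alpha[i])
  }, numeric(1))
  padj <- bh_adjust(pval)
  mA <- kA / sA
  mB <- kB / sB
  fold <- mB / mA
  iso <- data.frame(
    gene = genes,
    isoform = if (is.null(rownames(counts))) as.character(seq_along(kA))
              else rownames(counts),
    base_mean_A = mA, base_mean_B = mB,
    fold_change = fold, log2_fold = log2(fold),
    pval = pval, padj = padj,
    stringsAsFactors = FALSE
  )
  # collapse isoforms: largest |log fold|; Inf/0 folds sort above any finite
  dev <- abs(log(iso$fold_change))
  dev[is.nan(dev)] <- -Inf  # 0/0: least informative isoform
  ord <- order(iso$gene, -dev)
  iso <- iso[ord, ]
  res <- iso[!duplicated(iso$gene), ]
  res$called <- res$padj <= threshold
  rownames(res) <- NULL
  class(res) <- c("DEResult", "data.frame")
  res
}
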