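#' Exact small-count probability for digital expression data
#'
#' Pointwise probability of observing \code{x} counts in one library given
#' \code{y} counts in another, under the classical exact model for tag
#' counts:
#' \deqn{P(x|y) = (N_2/N_1)^x \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' With equal library sizes (\code{N1 == N2}) the ratio term is 1 and the
#' distribution over \code{x} given \code{y} is negative binomial with
#' success probability 1/2. Evaluation is in log space.
#'
#' @param x,y Nonnegative integer counts (TPM values should be rounded
#'   before use). Vectorized over \code{x} and \code{y}.
#' @param N1,N2 Library normalization totals; defaults follow the
#'   convention of setting both to one million.
#' @return Pointwise probability (numeric vector).
#' @export
ac_probability <- function(x, y, N1 = 1e6, N2 = 1e6) {
  if (any(x < 0) || any(y < 0)) stop("counts must be nonnegative")
  if (any(x != round(x)) || any(y != round(y)))
    stop("counts must be integers; round TPM values first")
  r <- N2 / N1
  exp(x * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

#' Two-sided exact p-value for a pair of counts
#'
#' Doubled-tail construction over the pointwise exact probability: the
#' lower tail sums \code{P(t|y)} for \code{t <= x}, the upper tail for
#' \code{t >= x}; the p-value is twice the smaller tail, capped at 1.
#'
#' @inheritParams ac_probability
#' @return p-value in (0, 1].
#' @export
ac_pvalue <- function(x, y, N1 = 1e6, N2 = 1e6) {
  stopifnot(length(x) == 1, length(y) == 1)
  if (x < 0 || y < 0) stop("counts must be nonnegative")
  x <- round(x); y <- round(y)
  lower <- sum(ac_probability(0:x, y, N1, N2))
  upper <- 1 - lower + ac_probability(x, y, N1, N2)
  min(1, 2 * min(lower, upper))
}

#' Exact differential-expression test between two expression vectors
#'
#' Applies the exact test to each locus of two replicate-mean TPM vectors
#' (rounded to integers), reporting the pointwise probability, two-sided
#' p-value and log2 fold change. Loci are flagged differential at
#' \code{p < alpha} and \code{|log2FC| >= min_lfc}.
#'
#' @param tpm_a,tpm_b Numeric vectors of replicate-mean TPM (same length,
#'   same locus order).
#' @param alpha p-value cutoff (default 0.01).
#' @param min_lfc minimum absolute log2 fold change (default 1); a
#'   pseudocount of 1 is used inside the log ratio.
#' @param locus_id Optional identifiers.
#' @return data.frame with columns locus, x, y, prob, p_value, log2fc,
#'   significant.
#' @export
de_exact_test <- function(tpm_a, tpm_b, alpha = 0.01, min_lfc = 1,
                          locus_id = NULL) {
  stopifnot(length(tpm_a) == length(tpm_b))
  x <- round(tpm_a); y <- round(tpm_b)
  p <- vapply(seq_along(x), function(i) ac_pvalue(x[i], y[i]), numeric(1))
  prob <- ac_probability(x, y)
  lfc <- log2((x + 1) / (y + 1))
  if (is.null(locus_id)) locus_id <- seq_along(x)
  data.frame(locus = locus_id, x = x, y = y, prob = prob, p_value = p,
             log2fc = lfc,
             significant = p < alpha & abs(lfc) >= min_lfc,
             stringsAsFactors = FALSE)
}

#' Shannon entropy of an expression vector (bits)
#'
#' Relative expression \eqn{E_i = x_i / \sum x} with the convention
#' \eqn{0 \log 0 = 0}; the result lies in \eqn{[0, \log_2 n]}.
#'
#' @param x Nonnegative expression vector.
#' @return Entropy in bits, or NA for an all-zero vector.
#' @export
shannon_entropy <- function(x) {
  if (any(x < 0)) stop("expression values must be nonnegative")
  s <- sum(x)
  if (s == 0) return(NA_real_)
  e <- x / s
  e <- e[e > 0]
  -sum(e * log2(e))
}

#' One-step Tukey biweight center
#'
#' Robust location estimate: with \code{M} the median and \code{S} the
#' (unscaled) median absolute deviation, weights are
#' \eqn{w_i = (1-u_i^2)^2} for \eqn{|u_i| < 1}, else 0, where
#' \eqn{u_i = (x_i - M)/(cS + \epsilon)}. Constants follow the common
#' expression-array convention: \code{c = 5}, \code{eps = 1e-4}.
#'
#' @param x Numeric vector, length >= 2.
#' @param c_const,eps Tuning constant and guard against zero spread.
#' @return Weighted center (numeric scalar).
#' @export
tukey_biweight <- function(x, c_const = 5, eps = 1e-4) {
  stopifnot(length(x) >= 2)
  m <- median(x)
  s <- median(abs(x - m))
  u <- (x - m) / (c_const * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Robust specificity entropy (modH, bits)
#'
#' ROKU-style processed entropy: the expression vector is re-expressed as
#' absolute deviations from its one-step Tukey biweight center and the
#' Shannon entropy of the deviations is returned. A vector with zero
#' deviation everywhere is undefined (NA) and can never be called
#' tissue-specific.
#'
#' @inheritParams shannon_entropy
#' @return modH in bits, or NA.
#' @export
mod_entropy <- function(x) {
  if (any(x < 0)) stop("expression values must be nonnegative")
  centered <- abs(x - tukey_biweight(x))
  if (all(centered == 0)) return(NA_real_)
  shannon_entropy(centered)
}

#' Z scores of an expression vector
#'
#' \eqn{Z_i = (x_i - \mu)/\sigma} with the sample (n-1) standard
#' deviation by default.
#'
#' @param x Numeric vector, length >= 2.
#' @param sample_sd Use the n-1 denominator (default); set FALSE for the
#'   population denominator.
#' @return List with components \code{z} (vector, sums to zero) and
#'   \code{zmax}; both NA when the standard deviation is zero.
#' @export
zscores <- function(x, sample_sd = TRUE) {
  stopifnot(length(x) >= 2)
  mu <- mean(x)
  sigma <- if (sample_sd) stats::sd(x) else
    sqrt(mean((x - mu)^2))
  if (is.na(sigma) || sigma == 0)
    return(list(z = rep(NA_real_, length(x)), zmax = NA_real_))
  z <- (x - mu) / sigma
  list(z = z, zmax = max(z))
}

#' Call tissue-specific loci from an expression matrix
#'
#' A locus is tissue-specific when its robust entropy modH is below
#' \code{modh_max} (default 1.8 bits) and its maximum Z score exceeds
#' \code{zmax_min} (default 3). The target tissue is the column with the
#' largest Z. Both statistics are reported for every locus; loci with an
#' undefined statistic (all-zero or constant profiles) are never called.
#'
#' @param mat Numeric matrix, loci x tissues, replicate-mean TPM; column
#'   names are tissue labels.
#' @param modh_max,zmax_min Calling thresholds.
#' @return data.frame with locus, H, modH, zmax, tissue, specific.
#' @export
call_tissue_specific <- function(mat, modh_max = 1.8, zmax_min = 3) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  tissues <- colnames(mat)
  if (is.null(tissues)) tissues <- paste0("tissue", seq_len(ncol(mat)))
  res <- lapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    h <- shannon_entropy(x)
    mh <- if (is.na(h)) NA_real_ else mod_entropy(x)
    zs <- if (sum(x) == 0) list(z = NA, zmax = NA_real_) else zscores(x)
    target <- if (all(is.na(zs$z))) NA_character_ else
      tissues[which.max(zs$z)]
    spec <- !is.na(mh) && !is.na(zs$zmax) &&
      mh < modh_max && zs$zmax > zmax_min
    data.frame(H = h, modH = mh, zmax = zs$zmax, tissue = target,
               specific = spec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ids <- rownames(mat)
  out <- cbind(locus = if (is.null(ids)) as.character(seq_len(nrow(mat)))
               else ids, out)
  rownames(out) <- NULL
  out
}
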