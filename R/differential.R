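#' Test differential chromatin accessibility between two groups
#'
#' Insertion counts per consensus peak are normalised for library size
#' (counts per million), log2 fold changes computed with a pseudocount of 1,
#' and each peak tested with a negative-binomial likelihood-ratio test
#' (group means vs a common mean) at a common dispersion shared across
#' peaks. The dispersion is estimated by method of moments, pooling over all
#' peaks with a ratio-of-sums estimator; when the estimate is non-positive
#' (counts at or below Poisson variability, or a single sample per group)
#' the test reduces to Poisson. P-values are BH-adjusted.
#'
#' For fixed dispersion the maximum-likelihood estimate of a
#' negative-binomial mean is the sample mean, so the LRT has closed form.
#' The NB log-likelihood is evaluated through lgamma and therefore accepts
#' the non-integer library-size-scaled counts.
#'
#' @param count_matrix integer matrix, peaks x samples, rownames = peak ids.
#' @param group_a,group_b column names (or indices) of the two groups.
#' @param pseudocount added to CPM before log2 (default 1).
#' @return tibble of class `fatac_da`: peak_id, mean_a, mean_b (CPM),
#'   log2FC, p, FDR; attributes `dispersion` and `model` ("nb" or
#'   "poisson").
#' @export
differential_accessibility <- function(count_matrix, group_a, group_b,
                                       pseudocount = 1) {
  if (is.null(rownames(count_matrix))) {
    rownames(count_matrix) <- sprintf("peak%05d", seq_len(nrow(count_matrix)))
  }
  a <- count_matrix[, group_a, drop = FALSE]
  b <- count_matrix[, group_b, drop = FALSE]
  if (ncol(a) < 1 || ncol(b) < 1) abort("each group needs at least one sample")

  lib <- colSums(count_matrix)
  if (any(lib == 0)) abort("a sample has zero total counts")
  # scale counts to the mean library size (keeps the count scale for the
  # NB model while removing depth differences)
  sf <- lib / mean(lib)
  ya <- sweep(a, 2, sf[group_a], "/")
  yb <- sweep(b, 2, sf[group_b], "/")

  ma <- rowMeans(ya)
  mb <- rowMeans(yb)
  m0 <- rowMeans(cbind(ya, yb))

  phi <- estimate_common_dispersion(ya, yb)
  model <- if (phi > 0) "nb" else "poisson"

  ll <- function(y, mu) {
    mu <- pmax(mu, 1e-8)
    if (phi > 0) {
      r <- 1 / phi
      sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
            r * log(r / (r + mu)) + y * log(pmax(mu, 1e-12) / (r + mu)))
    } else {
      sum(y * log(mu) - mu - lgamma(y + 1))
    }
  }
  n_peak <- nrow(count_matrix)
  lrt <- vapply(seq_len(n_peak), function(i) {
    y1 <- as.numeric(ya[i, ]); y2 <- as.numeric(yb[i, ])
    2 * (ll(y1, ma[i]) + ll(y2, mb[i]) - ll(c(y1, y2), m0[i]))
  }, numeric(1))
  p <- pchisq(pmax(lrt, 0), df = 1, lower.tail = FALSE)

  cpm_a <- ma / mean(lib) * 1e6
  cpm_b <- mb / mean(lib) * 1e6
  out <- tibble(
    peak_id = rownames(count_matrix),
    mean_a = cpm_a,
    mean_b = cpm_b,
    log2FC = log2(cpm_a + pseudocount) - log2(cpm_b + pseudocount),
    p = p,
    FDR = p.adjust(p, method = "BH")
  )
  attr(out, "dispersion") <- max(phi, 0)
  attr(out, "model") <- model
  structure(out, class = c("fatac_da", class(out)))
}

# pooled method-of-moments common dispersion: sum over peaks and groups of
# (within-group variance - mean) over sum of squared means
estimate_common_dispersion <- function(ya, yb) {
  num <- 0
  den <- 0
  for (y in list(ya, yb)) {
    if (ncol(y) < 2) next
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  if (den == 0) return(0)
  num / den
}

#' @method glance fatac_da
#' @export
glance.fatac_da <- function(x, ...) {
  tibble(
    n_peaks = nrow(x),
    n_significant = sum(x$FDR < 0.05),
    dispersion = attr(x, "dispersion"),
    model = attr(x, "model")
  )
}

#' @method tidy fatac_da
#' @export
tidy.fatac_da <- function(x, ...) as_tibble(x)
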