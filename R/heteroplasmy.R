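#' Exact binomial (Clopper-Pearson) confidence interval on q
#'
#' The number of fusion-supporting reads is modelled as Bin(`r`, `q`), where
#' `r` is the mitochondrial read count and `q` the proportion of reads
#' harboring the fusion.  The two-sided `1 - alpha` interval on `q` is the
#' exact (Clopper-Pearson) one, computed from F-distribution quantiles:
#' \deqn{\left(\frac{1}{1+\frac{r-n+1}{n}F_{2(r-n+1),2n}},\;
#'   \frac{\frac{n+1}{r-n}F_{2(n+1),2(r-n)}}{1+\frac{n+1}{r-n}F_{2(n+1),2(r-n)}}\right)}
#' where each `F` is the upper `alpha/2` quantile.  Edge conventions:
#' `n = 0` gives a lower bound of exactly 0, `n = r` an upper bound of 1.
#'
#' @param n Number of fusion-supporting reads (`0 <= n <= r`).
#' @param r Number of mitochondrial reads (`>= 1`).
#' @param alpha Two-sided error level in (0, 1); default 0.05.
#' @return Numeric vector `c(low, high)` on the `q` scale.
#' @examples
#' clopper_pearson_ci(96, 1115366)
#' @export
clopper_pearson_ci <- function(n, r, alpha = 0.05) {
  stopifnot(r >= 1, n >= 0, n <= r, alpha > 0, alpha < 1)
  low <- if (n == 0) {
    0
  } else {
    1 / (1 + (r - n + 1) / n * stats::qf(1 - alpha / 2,
                                         2 * (r - n + 1), 2 * n))
  }
  high <- if (n == r) {
    1
  } else {
    fq <- stats::qf(1 - alpha / 2, 2 * (n + 1), 2 * (r - n))
    ((n + 1) / (r - n) * fq) / (1 + (n + 1) / (r - n) * fq)
  }
  c(low, high)
}

#' Estimate deletion heteroplasmy from read counts
#'
#' A read drawn from a deleted haplotype harbors the fusion point with
#' probability `l / L` (there are `L` possible read start positions, `l` of
#' which overlap any given junction), so the haplotype fraction —
#' heteroplasmy — is estimated by inflating the read fraction:
#' \deqn{\hat{q} = n / r, \qquad \widehat{het} = \hat{q} \times L / l.}
#' The confidence interval on `q` from [clopper_pearson_ci()] is transformed
#' to the heteroplasmy scale by the same factor.  Values are capped at 1
#' (with a flag), since the plug-in estimator can exceed 100% for small `r`.
#'
#' Note that `l` is the *effective* read length of the reads counted in `r`;
#' when a pair is effectively counted as one fragment, `l` can be twice the
#' nominal read length, which materially changes the estimate.
#'
#' @inheritParams clopper_pearson_ci
#' @param read_length Effective read length `l` in nt.
#' @param genome_length Mitochondrial genome length `L` (default 16,569).
#' @param conf_int Compute the confidence interval? Default `TRUE`.
#' @return An object of class `mito_het`: a list with `q_hat`,
#'   `heteroplasmy`, `ci_q`, `ci_heteroplasmy`, `capped` plus the inputs.
#'   Use [tidy()] for a one-row tibble.
#' @examples
#' estimate_heteroplasmy(96, 1115366, read_length = 200)
#' @export
estimate_heteroplasmy <- function(n, r, read_length,
                                  genome_length = 16569, alpha = 0.05,
                                  conf_int = TRUE) {
  stopifnot(read_length >= 1, genome_length >= 1)
  if (r == 0) stop("r = 0: no mitochondrial reads to normalize against",
                   call. = FALSE)
  stopifnot(n >= 0, n <= r)
  scale <- genome_length / read_length
  q_hat <- n / r
  het_raw <- q_hat * scale
  ci_q <- NULL
  ci_het_raw <- NULL
  if (conf_int) {
    ci_q <- clopper_pearson_ci(n, r, alpha)
    ci_het_raw <- ci_q * scale
  }
  capped <- het_raw > 1 || (conf_int && any(ci_het_raw > 1))
  structure(
    list(
      n = n, r = r, read_length = read_length,
      genome_length = genome_length, alpha = alpha,
      q_hat = q_hat,
      heteroplasmy = min(het_raw, 1),
      ci_q = ci_q,
      ci_heteroplasmy = if (conf_int) pmin(ci_het_raw, 1) else NULL,
      capped = capped
    ),
    class = "mito_het"
  )
}

#' @export
print.mito_het <- function(x, ...) {
  cat(sprintf("Heteroplasmy estimate: %.2f%%", 100 * x$heteroplasmy))
  if (!is.null(x$ci_heteroplasmy)) {
    cat(sprintf(" (%d%% CI %.2f%%-%.2f%%)", round(100 * (1 - x$alpha)),
                100 * x$ci_heteroplasmy[1], 100 * x$ci_heteroplasmy[2]))
  }
  cat(sprintf("\n  n = %s fusion reads / r = %s mtDNA reads, l = %d nt, L = %d bp\n",
              format(x$n, big.mark = ","), format(x$r, big.mark = ","),
              x$read_length, x$genome_length))
  if (x$capped) cat("  note: estimate or interval truncated at 100%\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mito_het <- function(x, ...) {
  tibble::tibble(
    q_hat = x$q_hat,
    heteroplasmy = x$heteroplasmy,
    conf.low = if (is.null(x$ci_heteroplasmy)) NA_real_ else x$ci_heteroplasmy[1],
    conf.high = if (is.null(x$ci_heteroplasmy)) NA_real_ else x$ci_heteroplasmy[2],
    capped = x$capped
  )
}

#' @exportS3Method generics::glance
glance.mito_het <- function(x, ...) {
  tibble::tibble(
    n = x$n, r = x$r, read_length = x$read_length,
    genome_length = x$genome_length, alpha = x$alpha
  )
}
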