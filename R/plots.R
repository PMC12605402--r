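#' Manhattan plot of GWAS results
#'
#' Base-graphics Manhattan plot with the Bonferroni and suggestive
#' (10th-lowest observed p) thresholds.
#'
#' @param results [lmm_assoc()] output with `chrom`, `pos`, `p`
#' @param bonferroni genome-wide threshold to draw (or `NULL`)
#' @param k_suggestive rank defining the suggestive line (default 10)
#' @param ... passed to [graphics::plot()]
#' @return invisibly, the cumulative positions used
#' @export
plot_manhattan <- function(results, bonferroni = NULL,
                           k_suggestive = 10L, ...) {
  res <- as.data.table(results)
  setorder(res, chrom, pos)
  offs <- c(0, cumsum(tapply(res$pos, res$chrom, max)))
  res[, x := pos + offs[match(chrom, unique(res$chrom))]]
  cols <- (match(res$chrom, unique(res$chrom)) %% 2L) + 1L
  graphics::plot(res$x, -log10(res$p), pch = 20,
                 col = c("grey30", "steelblue")[cols],
                 xlab = "genome position", ylab = "-log10(p)", ...)
  if (!is.null(bonferroni)) {
    graphics::abline(h = -log10(bonferroni), lty = 3)
  }
  if (nrow(res) >= k_suggestive) {
    sug <- sort(res$p)[k_suggestive]
    graphics::abline(h = -log10(sug), col = "grey60")
  }
  invisible(res$x)
}

#' Quantile-quantile plot of GWAS p-values
#'
#' @param p_values numeric p-values
#' @param ... passed to [graphics::plot()]
#' @return invisibly, the genomic inflation factor
#' @export
plot_qq <- function(p_values, ...) {
  p <- sort(p_values)
  n <- length(p)
  exp_p <- (seq_len(n) - 0.5) / n
  graphics::plot(-log10(exp_p), -log10(p), pch = 20,
                 xlab = "expected -log10(p)",
                 ylab = "observed -log10(p)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(inflation_factor(p_values))
}
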