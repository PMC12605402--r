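#' Genotype quality control
#'
#' Applies the routine marker/animal filters in a fixed order: (1) markers
#' missing in more than `max_marker_missing` of animals, (2) animals with
#' call rate below `min_call_rate`, (3) animals with heterozygosity more
#' than 3 standard deviations above the mean, (4) markers deviating from
#' Hardy-Weinberg proportions at `hwe_p`, (5) markers with minor allele
#' frequency below `min_maf`. A per-step removal report is attached.
#'
#' @param dosages numeric matrix (individuals x markers, 0/1/2, `NA`
#'   missing), rownames = ids
#' @param map optional [marker_map()] subset along with the markers
#' @param max_marker_missing marker missingness threshold (default 0.05)
#' @param min_call_rate animal call-rate threshold (default 0.95)
#' @param het_sd heterozygosity outlier threshold in SDs (default 3)
#' @param hwe_p Hardy-Weinberg exact-test threshold (default 1e-6)
#' @param min_maf minor-allele-frequency threshold (default 0.01)
#' @return list `dosages` (filtered), `map` (filtered, if given),
#'   `report` (`data.table` step, removed, remaining)
#' @export
qc_genotypes <- function(dosages, map = NULL, max_marker_missing = 0.05,
                         min_call_rate = 0.95, het_sd = 3,
                         hwe_p = 1e-6, min_maf = 0.01) {
  X <- dosages
  steps <- list()
  note <- function(step, removed) {
    steps[[length(steps) + 1L]] <<- data.table(
      step = step, removed = removed,
      markers_left = ncol(X), animals_left = nrow(X))
  }
  miss_m <- colMeans(is.na(X))
  drop <- miss_m > max_marker_missing
  X <- X[, !drop, drop = FALSE]; note("marker_missingness", sum(drop))
  call_a <- rowMeans(!is.na(X))
  drop <- call_a < min_call_rate
  X <- X[!drop, , drop = FALSE]; note("animal_call_rate", sum(drop))
  het <- rowMeans(X == 1L, na.rm = TRUE)
  thr <- mean(het) + het_sd * sd(het)
  drop <- het > thr
  X <- X[!drop, , drop = FALSE]; note("heterozygosity", sum(drop))
  hwe <- apply(X, 2L, function(g) {
    hwe_exact_test(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                   sum(g == 2L, na.rm = TRUE))
  })
  drop <- hwe < hwe_p
  X <- X[, !drop, drop = FALSE]; note("hwe", sum(drop))
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop <- maf < min_maf
  X <- X[, !drop, drop = FALSE]; note("maf", sum(drop))
  if (ncol(X) == 0L) stop("all markers removed by QC", call. = FALSE)
  list(dosages = X,
       map = if (!is.null(map)) map[marker_id %in% colnames(X)],
       report = rbindlist(steps))
}

#' Genomic relationship matrix
#'
#' Allele-count standardized GRM with equal marker weights:
#' `G_jk = (1/m) * sum_i (x_ji - 2 p_i)(x_ki - 2 p_i) / (2 p_i (1 - p_i))`.
#' Missing dosages are mean-imputed per marker; monomorphic markers are
#' excluded with a warning. On Hardy-Weinberg data the mean diagonal is
#' close to 1.
#'
#' @param dosages numeric matrix (individuals x markers)
#' @return dense symmetric GRM with individual dimnames
#' @export
compute_grm <- function(dosages) {
  X <- dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) excluded from GRM")
    X <- X[, !mono, drop = FALSE]; p <- p[!mono]
  }
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- 2 * p[j]
    X[, j] <- (xj - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
  }
  G <- tcrossprod(X) / ncol(X)
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  G
}

# exact 1-D REML for y = Xb + u + e, u ~ N(0, G s2u), via the
# eigendecomposition of G (rotate once, profile the variance ratio)
null_lmm_reml <- function(y, X, eig) {
  Ut <- t(eig$vectors)
  yt <- as.numeric(Ut %*% y)
  Xt <- Ut %*% X
  lam <- pmax(eig$values, 0)
  n <- length(y); p <- ncol(X)
  negll <- function(log_delta) {
    # delta = s2e / s2u; total V = s2u (lam + delta)
    delta <- exp(log_delta)
    w <- 1 / (lam + delta)
    XtWX <- crossprod(Xt, Xt * w)
    b <- solve(XtWX, crossprod(Xt, yt * w))
    r <- yt - as.numeric(Xt %*% b)
    rss <- sum(r^2 * w)
    s2u <- rss / (n - p)
    0.5 * ((n - p) * log(s2u) + sum(log(lam + delta)) +
             determinant(XtWX)$modulus[1] + (n - p))
  }
  opt <- optimize(negll, c(-12, 12))
  delta <- exp(opt$minimum)
  w <- 1 / (lam + delta)
  XtWX <- crossprod(Xt, Xt * w)
  b <- solve(XtWX, crossprod(Xt, yt * w))
  r <- yt - as.numeric(Xt %*% b)
  s2u <- sum(r^2 * w) / (n - p)
  list(s2u = s2u, s2e = s2u * delta, delta = delta, beta = as.numeric(b))
}

#' Single-marker linear mixed-model association
#'
#' Two-stage approximation of the per-marker LMM
#' `y* = mu + b g + u + e`, `u ~ N(0, G s2u)`: variance components are
#' estimated once on the null model (no marker) by exact REML on the
#' eigendecomposition of the GRM, then every marker is tested by
#' generalized least squares at that fixed covariance. Wald p-values.
#' With `s2u` fixed at 0 the test reduces to ordinary least squares.
#'
#' @param y_star named numeric of corrected phenotypes (names = ids,
#'   aligned to or a subset of the GRM ids)
#' @param dosages dosage matrix (individuals x markers); missing values
#'   mean-imputed per marker
#' @param grm genomic relationship matrix covering the phenotyped ids
#' @param map optional [marker_map()] for chromosome/position columns
#' @param varcomp optional `c(u=, e=)` to skip the null REML
#' @return `data.table`: `marker`, `chrom`, `pos`, `freq`, `b`, `se`,
#'   `p`, plus `varcomp` attribute
#' @export
lmm_assoc <- function(y_star, dosages, grm, map = NULL, varcomp = NULL) {
  ids <- intersect(names(y_star), rownames(grm))
  ids <- intersect(ids, rownames(dosages))
  if (length(ids) < 3L) stop("too few phenotyped genotyped individuals",
                             call. = FALSE)
  y <- y_star[ids]
  G <- grm[ids, ids]
  X <- matrix(1, length(ids), 1L)
  eig <- eigen(G, symmetric = TRUE)
  if (min(eig$values) < -1e-6) {
    eig$values <- eig$values + abs(min(eig$values)) + 1e-8
  }
  if (is.null(varcomp)) {
    vc <- null_lmm_reml(y, X, eig)
  } else {
    vc <- list(s2u = varcomp[["u"]], s2e = varcomp[["e"]])
    vc$delta <- if (vc$s2u <= 0) Inf else vc$s2e / vc$s2u
  }
  Ut <- t(eig$vectors)
  yt <- as.numeric(Ut %*% y)
  # weights on the rotated scale: V = s2u*lam + s2e
  wv <- 1 / (vc$s2u * pmax(eig$values, 0) + vc$s2e)
  M <- dosages[ids, , drop = FALSE]
  pfreq <- colMeans(M, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(M)) > 0L)) {
    M[is.na(M[, j]), j] <- 2 * pfreq[j]
  }
  # markers can go monomorphic on the phenotyped subset even after
  # panel-wide QC; their effect is undefined
  poly <- col_vars(M) > 0
  if (!all(poly)) {
    ls_log(sum(!poly), " marker(s) monomorphic among phenotyped ",
           "individuals; dropped from association")
    M <- M[, poly, drop = FALSE]
    pfreq <- pfreq[poly]
  }
  Mt <- Ut %*% M
  onet <- as.numeric(Ut %*% rep(1, length(ids)))
  # per-marker GLS with intercept, vectorized over markers
  sw <- sum(wv * onet^2)
  swy <- sum(wv * onet * yt)
  gW1 <- as.numeric(crossprod(Mt, wv * onet))
  gWy <- as.numeric(crossprod(Mt, wv * yt))
  gWg <- colSums(Mt^2 * wv)
  det_ <- sw * gWg - gW1^2
  bhat <- (sw * gWy - gW1 * swy) / det_
  # per-marker residual scale on the whitened data (close to 1 when the
  # null covariance is right; makes the s2u = 0 case exactly OLS)
  mu_hat <- (gWg * swy - gW1 * gWy) / det_
  syy <- sum(wv * yt^2)
  # (mu, b) solve the normal equations, so RSS = y'Wy - mu X'Wy - b g'Wy
  rss <- syy - mu_hat * swy - bhat * gWy
  n_ <- length(ids)
  scale2 <- pmax(rss, 0) / (n_ - 2L)
  se <- sqrt(scale2 * sw / det_)
  z <- bhat / se
  pval <- 2 * stats::pt(-abs(z), df = n_ - 2L)
  res <- data.table(marker = colnames(M), freq = pfreq,
                    b = bhat, se = se, p = pval)
  if (!is.null(map)) {
    res <- merge(res, map[, .(marker = marker_id, chrom, pos)],
                 by = "marker", sort = FALSE)
    setcolorder(res, c("marker", "chrom", "pos", "freq", "b", "se", "p"))
  }
  setattr(res, "varcomp", c(u = vc$s2u, e = vc$s2e))
  res[]
}

#' Bonferroni genome-wide threshold
#'
#' @param alpha family-wise error rate
#' @param n_tests number of tests
#' @return `alpha / n_tests`
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Suggestive associations: the k lowest p-values
#'
#' Ties at the cutoff are broken by (chromosome, position, marker id) so
#' the selection is deterministic.
#'
#' @param results [lmm_assoc()] output
#' @param k number of markers (default 10)
#' @return `data.table` sorted ascending by p
#' @export
suggestive_hits <- function(results, k = 10L) {
  res <- as.data.table(results)
  if (!"chrom" %in% names(res)) res[, chrom := ""]
  if (!"pos" %in% names(res)) res[, pos := 0L]
  setorder(res, p, chrom, pos, marker)
  head(res, k)
}

#' Linkage disequilibrium r-squared between two markers
#'
#' On phased input, the squared correlation of haplotype allele
#' indicators (the direct haplotype-frequency definition,
#' `r2 = D^2 / (pA pa pB pb)`); on a dosage matrix the squared genotype
#' correlation is used and flagged as a fallback.
#'
#' @param x a [phased_genotypes()] object or dosage matrix
#' @param marker_a,marker_b marker ids
#' @return `r2` with attribute `method` (`"haplotype"` or `"dosage"`)
#' @export
ld_r2 <- function(x, marker_a, marker_b) {
  if (inherits(x, "phased_genotypes")) {
    a <- x$H[, marker_a]; b <- x$H[, marker_b]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    method <- "haplotype"
  } else {
    a <- x[, marker_a]; b <- x[, marker_b]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    method <- "dosage"
  }
  if (var(a) == 0 || var(b) == 0) {
    stop("monomorphic marker: r2 undefined", call. = FALSE)
  }
  r2 <- suppressWarnings(stats::cor(a, b)^2)
  attr(r2, "method") <- method
  r2
}

#' Co-locate suggestive GWAS hits with HHD haplotypes
#'
#' For each suggestive marker, emits the HHD haplotypes on the same
#' chromosome whose interval, padded by `pad_bp` on each side (1 Mb by
#' default, measured from the haplotype start/end), contains the marker.
#' The maximum r-squared between the marker and the markers inside the
#' haplotype window is attached; `linked = r2 > 0.5`.
#'
#' @param hits [suggestive_hits()] output
#' @param hhd_records [hhd_scan()] output
#' @param pg a [phased_genotypes()] object (for r-squared)
#' @param pad_bp padding around the haplotype interval (default 1e6)
#' @param r2_linked linkage threshold (default 0.5)
#' @return `data.table`: marker, chrom, pos, haplotype id, haplotype
#'   start/end, `distance_bp` (0 if inside the interval), `r2`, `linked`
#' @export
colocate <- function(hits, hhd_records, pg, pad_bp = 1e6,
                     r2_linked = 0.5) {
  out <- list()
  hits <- as.data.table(hits); hh <- as.data.table(hhd_records)
  for (i in seq_len(nrow(hits))) {
    mk <- hits[i]
    cand <- hh[chrom == mk$chrom & mk$pos >= start - pad_bp &
                 mk$pos <= end + pad_bp]
    for (j in seq_len(nrow(cand))) {
      hp <- cand[j]
      win_markers <- pg$map[chrom == hp$chrom & pos >= hp$start &
                              pos <= hp$end, marker_id]
      r2s <- vapply(win_markers, function(m) {
        if (m == mk$marker) return(1)
        tryCatch(as.numeric(ld_r2(pg, mk$marker, m)),
                 error = function(e) NA_real_)
      }, numeric(1))
      r2max <- if (all(is.na(r2s))) NA_real_ else max(r2s, na.rm = TRUE)
      dist <- if (mk$pos >= hp$start && mk$pos <= hp$end) 0L else
        as.integer(min(abs(mk$pos - hp$start), abs(mk$pos - hp$end)))
      out[[length(out) + 1L]] <- data.table(
        marker = mk$marker, chrom = mk$chrom, pos = mk$pos,
        haplotype = hp$id, hap_start = hp$start, hap_end = hp$end,
        distance_bp = dist, r2 = r2max,
        linked = !is.na(r2max) & r2max > r2_linked)
    }
  }
  if (!length(out)) {
    return(data.table(marker = character(), chrom = character(),
                      pos = integer(), haplotype = character(),
                      hap_start = integer(), hap_end = integer(),
                      distance_bp = integer(), r2 = numeric(),
                      linked = logical()))
  }
  rbindlist(out)
}

# column variances without extra dependencies
col_vars <- function(M) {
  n <- nrow(M)
  (colSums(M^2) - n * colMeans(M)^2) / (n - 1L)
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`: the median
#' association chi-square over its null median (0.4549).
#'
#' @param p_values numeric vector of p-values
#' @return lambda
#' @export
inflation_factor <- function(p_values) {
  stopifnot(length(p_values) > 0L)
  median(qchisq(1 - p_values, df = 1)) / qchisq(0.5, df = 1)
}
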