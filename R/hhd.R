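#' Build marker windows
#'
#' Cuts each chromosome into consecutive, non-overlapping windows of
#' `length_markers` markers starting after `offset` markers. A terminal
#' remainder keeps its own window when it holds at least half a window of
#' markers, otherwise it is merged into the previous window. Chromosomes
#' with fewer than 2 markers are skipped with a warning.
#'
#' @param map a [marker_map()]
#' @param length_markers window length in markers (75 or 25 in routine
#'   scans; any value >= 2 accepted)
#' @param offset markers to skip at the start of each chromosome
#' @return `data.table` with columns `window_id`, `chrom`, `start_marker`,
#'   `end_marker` (1-based indices into the chromosome's marker list,
#'   after the offset convention), `start_bp`, `end_bp`, `n_markers`
#' @export
build_windows <- function(map, length_markers, offset = 0L) {
  stopifnot(length_markers >= 2L, offset >= 0L)
  out <- list()
  widx <- 0L
  for (ch in unique(map$chrom)) {
    sub <- map[chrom == ch]
    if (nrow(sub) < 2L) {
      warning("chromosome ", ch, " has fewer than 2 markers; skipped")
      next
    }
    m <- nrow(sub) - offset
    if (m < 2L) next
    starts <- seq(offset + 1L, offset + m, by = length_markers)
    ends <- pmin(starts + length_markers - 1L, offset + m)
    if (length(starts) > 1L) {
      last_n <- ends[length(ends)] - starts[length(starts)] + 1L
      if (last_n < length_markers / 2) {
        # merge remainder into previous window
        ends[length(ends) - 1L] <- ends[length(ends)]
        starts <- starts[-length(starts)]
        ends <- ends[-length(ends)]
      }
    }
    for (k in seq_along(starts)) {
      widx <- widx + 1L
      out[[length(out) + 1L]] <- data.table(
        window_id = sprintf("w%d", widx), chrom = ch,
        start_marker = starts[k], end_marker = ends[k],
        start_bp = sub$pos[starts[k]], end_bp = sub$pos[ends[k]],
        n_markers = ends[k] - starts[k] + 1L)
    }
  }
  if (!length(out)) return(data.table(window_id = character(),
                                      chrom = character(),
                                      start_marker = integer(),
                                      end_marker = integer(),
                                      start_bp = integer(),
                                      end_bp = integer(),
                                      n_markers = integer()))
  rbindlist(out)
}

#' Call window haplotypes
#'
#' Labels the two haplotypes of every individual within a marker window by
#' the rank (1 = most frequent) of the distinct allele strings observed.
#' Individuals with any missing allele in the window are excluded from the
#' window's `N`; retained frequencies sum to 1 over the counted
#' chromosomes. Haplotypes below `min_frequency` are flagged discarded
#' (1% for 75-marker windows, 5% for 25-marker windows in routine scans).
#'
#' @param pg a [phased_genotypes()] object
#' @param window one row of [build_windows()] output
#' @param min_frequency discard threshold on haplotype frequency
#' @return list with `labels` (integer matrix `N x 2` of haplotype ranks,
#'   rownames = counted individual ids), `freq` (`data.table` rank,
#'   haplotype string, count, frequency, discarded flag) and `N`
#' @export
call_window_haplotypes <- function(pg, window, min_frequency = 0) {
  cols <- which(pg$map$chrom == window$chrom)
  cols <- cols[cols >= cols[1] + window$start_marker - 1L &
                 cols <= cols[1] + window$end_marker - 1L]
  sub <- pg$H[, cols, drop = FALSE]
  n <- length(pg$ids)
  a <- sub[seq(1L, 2L * n, 2L), , drop = FALSE]
  b <- sub[seq(2L, 2L * n, 2L), , drop = FALSE]
  ok <- !(rowSums(is.na(a)) > 0L | rowSums(is.na(b)) > 0L)
  if (!any(ok)) {
    return(list(labels = matrix(integer(0), 0, 2),
                freq = data.table(rank = integer(), haplotype = character(),
                                  count = integer(), frequency = numeric(),
                                  discarded = logical()),
                N = 0L))
  }
  sa <- apply(a[ok, , drop = FALSE], 1L, paste, collapse = "")
  sb <- apply(b[ok, , drop = FALSE], 1L, paste, collapse = "")
  all_h <- c(sa, sb)
  tab <- sort(table(all_h), decreasing = TRUE)
  # deterministic rank: descending count, ties by haplotype string
  ord <- order(-as.integer(tab), names(tab))
  haps <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  rank_of <- setNames(seq_along(haps), haps)
  labels <- cbind(rank_of[sa], rank_of[sb])
  dimnames(labels) <- list(pg$ids[ok], c("A", "B"))
  freq <- data.table(rank = seq_along(haps), haplotype = haps,
                     count = counts,
                     frequency = counts / sum(counts))
  freq[, discarded := frequency < min_frequency]
  list(labels = labels, freq = freq, N = sum(ok))
}

#' Count carriers and homozygotes of one haplotype
#'
#' @param labels integer matrix `N x 2` of per-individual haplotype ranks
#'   (both labels called)
#' @param hap_rank the haplotype rank to count
#' @return list `n_carriers` (>= 1 copy), `obs_hom` (2 copies), `N`
#' @export
count_carriers_homozygotes <- function(labels, hap_rank) {
  copies <- (labels[, 1L] == hap_rank) + (labels[, 2L] == hap_rank)
  list(n_carriers = sum(copies >= 1L), obs_hom = sum(copies == 2L),
       N = nrow(labels))
}

#' Expected homozygotes under random mating (the simple method)
#'
#' With haplotype frequency `p`, the carrier frequency is `C = 2p` and the
#' expected number of homozygotes among `N` genotyped animals is
#' `(C^2/4) * N = p^2 * N`. The probability of observing zero homozygotes
#' is `P = (1 - C^2/4)^N = (1 - p^2)^N`, evaluated in log space.
#'
#' @param p haplotype frequency in `[0, 1]`
#' @param N number of genotyped animals
#' @return list `exp_random`, `p_random`
#' @export
expected_random <- function(p, N) {
  stopifnot(all(p >= 0 & p <= 1), all(N >= 0))
  list(exp_random = p^2 * N,
       p_random = exp(N * log1p(-p^2)))
}

#' Cumulative insemination loss from independent recessive lethals
#'
#' Under random mating, a lethal at frequency `p` makes a fraction `p^2`
#' of conceptions homozygous. For several lethals segregating
#' independently, the fraction of inseminations lost is
#' `1 - prod(1 - p_i^2)` (about `sum(p_i^2)` for small frequencies:
#' four lethals at 5% cost about 1% of inseminations).
#'
#' @param freqs vector of haplotype frequencies
#' @return proportion of inseminations lost
#' @export
cumulative_homozygote_loss <- function(freqs) {
  stopifnot(all(freqs >= 0 & freqs <= 1))
  1 - prod(1 - freqs^2)
}

#' Expected homozygotes from carrier matings (the mating method)
#'
#' For each genotyped individual: if both parents are genotyped and both
#' carry the haplotype, the mating counts; otherwise, if the dam is
#' ungenotyped but sire and maternal grand sire are genotyped carriers,
#' it counts (the dam's genotype, when available, takes precedence over
#' the grand sire route). The expected homozygote count is the number of
#' qualifying matings divided by 4 and the zero-homozygote probability is
#' `0.75^count` (each qualifying mating produces a homozygote with
#' probability 1/4).
#'
#' @param carrier_status named logical vector over genotyped individuals
#'   (`TRUE` = carrier); individuals absent from it are ungenotyped
#' @param ped a sorted `pedigree`
#' @return list `n_carrier_matings`, `exp_mating`, `p_mating`
#' @export
expected_mating <- function(carrier_status, ped) {
  genotyped <- names(carrier_status)
  idx <- ped[, .(id = individual, sire, dam)]
  idx[, mgs := setNames(ped$sire, ped$individual)[dam]]
  sub <- idx[id %in% genotyped & !is.na(sire) & sire %in% genotyped]
  carr <- function(x) !is.na(x) & x %in% genotyped &
    carrier_status[x] %in% TRUE
  dam_g <- !is.na(sub$dam) & sub$dam %in% genotyped
  dam_route <- dam_g & carr(sub$sire) & carr(sub$dam)
  mgs_route <- !dam_g & !is.na(sub$dam) & !is.na(sub$mgs) &
    sub$mgs %in% genotyped & carr(sub$sire) & carr(sub$mgs)
  cnt <- sum(dam_route) + sum(mgs_route)
  list(n_carrier_matings = cnt, exp_mating = cnt / 4,
       p_mating = 0.75^cnt)
}

#' Scan phased genotypes for homozygous haplotype deficiency
#'
#' Runs the full HHD scan: windows of `length_markers` markers, haplotype
#' calling with the matching frequency cutoff, and for every retained
#' haplotype with zero observed homozygotes an evidence record holding
#' both expectation methods. Haplotype ids are `hap<window>-<rank>` where
#' `<window>` indexes windows genome-wide and `<rank>` is the frequency
#' rank within the window.
#'
#' @param pg a [phased_genotypes()] object
#' @param ped a sorted `pedigree` (for the mating method)
#' @param length_markers window length (75 or 25 typically)
#' @param min_frequency frequency cutoff; default 0.01 when
#'   `length_markers >= 50`, else 0.05
#' @param offset window offset in markers
#' @return `data.table` with columns `id`, `chrom`, `start`, `end`,
#'   `length_snp`, `freq`, `n_genotyped`, `n_carriers`, `obs_hom`,
#'   `exp_random`, `p_random`, `n_carrier_matings`, `exp_mating`,
#'   `p_mating`, sorted by chromosome then position
#' @export
hhd_scan <- function(pg, ped, length_markers = 25L,
                     min_frequency = if (length_markers >= 50L) 0.01
                       else 0.05,
                     offset = 0L) {
  windows <- build_windows(pg$map, length_markers, offset)
  out <- list()
  for (w in seq_len(nrow(windows))) {
    win <- windows[w]
    called <- call_window_haplotypes(pg, win, min_frequency)
    if (called$N == 0L) next
    keep <- called$freq[discarded == FALSE & frequency < 1]
    for (r in keep$rank) {
      cc <- count_carriers_homozygotes(called$labels, r)
      if (cc$obs_hom > 0L) next
      er <- expected_random(keep[rank == r, frequency], cc$N)
      copies <- (called$labels[, 1L] == r) + (called$labels[, 2L] == r)
      status <- setNames(copies >= 1L, rownames(called$labels))
      em <- expected_mating(status, ped)
      out[[length(out) + 1L]] <- data.table(
        id = sprintf("hap%d-%d", w, r), chrom = win$chrom,
        start = win$start_bp, end = win$end_bp,
        length_snp = win$n_markers,
        freq = keep[rank == r, frequency],
        n_genotyped = cc$N, n_carriers = cc$n_carriers,
        obs_hom = cc$obs_hom,
        exp_random = er$exp_random, p_random = er$p_random,
        n_carrier_matings = em$n_carrier_matings,
        exp_mating = em$exp_mating, p_mating = em$p_mating)
    }
  }
  if (!length(out)) {
    return(data.table(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      length_snp = integer(), freq = numeric(),
                      n_genotyped = integer(), n_carriers = integer(),
                      obs_hom = integer(), exp_random = numeric(),
                      p_random = numeric(), n_carrier_matings = integer(),
                      exp_mating = numeric(), p_mating = numeric()))
  }
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res[]
}

#' Carrier status for one scanned haplotype
#'
#' Re-calls the marker window of an [hhd_scan()] record and returns the
#' carrier indicator (at least one copy of that haplotype) for every
#' individual fully genotyped in the window.
#'
#' @param pg a [phased_genotypes()] object
#' @param hhd_row one row of [hhd_scan()] output
#' @return named logical vector over the window's genotyped individuals
#' @export
hhd_carriers <- function(pg, hhd_row) {
  hr <- as.data.table(hhd_row)
  rank <- as.integer(sub("^hap\\d+-", "", hr$id))
  sub <- pg$map[chrom == hr$chrom]
  start_marker <- which(sub$pos == hr$start)
  end_marker <- which(sub$pos == hr$end)
  win <- data.table(chrom = hr$chrom, start_marker = start_marker,
                    end_marker = end_marker)
  called <- call_window_haplotypes(pg, win, min_frequency = 0)
  copies <- (called$labels[, 1L] == rank) + (called$labels[, 2L] == rank)
  setNames(copies >= 1L, rownames(called$labels))
}

#' Round an expected count for display
#'
#' Expected homozygote counts are reported at full precision and rounded
#' half-up only for display in the integer evidence column.
#'
#' @param x numeric
#' @return integer vector
#' @export
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Exact test for Hardy-Weinberg proportions
#'
#' Conditional exact test: the probability, given allele counts, of
#' genotype configurations with probability not exceeding the observed
#' one (two-sided).
#'
#' @param n_aa,n_ab,n_bb genotype counts
#' @return p-value
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2L * n_aa + n_ab
  if (n == 0L) return(1)
  hets <- seq(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  # log-probabilities of heterozygote counts conditional on allele counts
  logp <- vapply(hets, function(h) {
    a <- (n_a - h) %/% 2L
    b <- n - a - h
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Deletion screen over an HHD region
#'
#' For every marker in a candidate region, computes the exact
#' Hardy-Weinberg deviation p-value and, when a log R intensity channel is
#' supplied, the mean log R of carriers and non-carriers (a hemizygous
#' deletion depresses carrier intensity). Without intensities the screen
#' returns HWE statistics only, with a notice.
#'
#' @param pg a [phased_genotypes()] object
#' @param region list or one-row table with `chrom`, `start`, `end` (bp,
#'   closed interval)
#' @param carrier_ids character vector of carrier individuals
#' @param intensity optional long `data.table` (marker, individual, logR)
#' @return `data.table` per marker: `marker_id`, `pos`, `hwe_p`,
#'   `mean_logR_carriers`, `mean_logR_noncarriers`
#' @export
deletion_screen <- function(pg, region, carrier_ids, intensity = NULL) {
  sel <- which(pg$map$chrom == region$chrom & pg$map$pos >= region$start &
                 pg$map$pos <= region$end)
  if (!length(sel)) stop("region contains no mapped markers",
                         call. = FALSE)
  dos <- dosage_matrix(pg)[, sel, drop = FALSE]
  if (is.null(intensity)) {
    ls_log("no intensity data supplied; HWE-only deletion screen")
  }
  out <- lapply(seq_along(sel), function(k) {
    g <- dos[, k]
    n_aa <- sum(g == 0L, na.rm = TRUE)
    n_ab <- sum(g == 1L, na.rm = TRUE)
    n_bb <- sum(g == 2L, na.rm = TRUE)
    mid <- pg$map$marker_id[sel[k]]
    mc <- mn <- NA_real_
    if (!is.null(intensity)) {
      sub <- intensity[marker == mid]
      mc <- mean(sub[individual %in% carrier_ids, logR])
      mn <- mean(sub[!(individual %in% carrier_ids), logR])
    }
    data.table(marker_id = mid, pos = pg$map$pos[sel[k]],
               hwe_p = hwe_exact_test(n_aa, n_ab, n_bb),
               mean_logR_carriers = mc, mean_logR_noncarriers = mn)
  })
  rbindlist(out)
}
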