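#' Probability that a conceptus is homozygous for a candidate haplotype
#'
#' Given 0/1 carrier statuses: with a genotyped dam the probability is
#' `0.5 * sire * 0.5 * dam = 0.25 * sire * dam`; when only the maternal
#' grand sire is genotyped it is `0.5 * sire * 0.25 * mgs`, the extra 0.5
#' accounting for transmission from grand sire to the ungenotyped dam.
#'
#' @param sire_carrier,dam_carrier,mgs_carrier 0/1 statuses (`NA` when
#'   ungenotyped)
#' @param dam_genotyped logical; selects the dam route
#' @return probability in `{0, 0.125, 0.25}`
#' @export
p_hom_fetus <- function(sire_carrier, dam_carrier = NA, mgs_carrier = NA,
                        dam_genotyped = !is.na(dam_carrier)) {
  ifelse(dam_genotyped,
         0.25 * sire_carrier * dam_carrier,
         0.125 * sire_carrier * mgs_carrier)
}

#' Assemble homozygous-fetus records for the stillbirth test
#'
#' Joins calving records to carrier statuses: a record is usable when the
#' sire is genotyped and either the dam or the maternal grand sire is
#' genotyped. Adds the parity (0-4), calf sex and year-month covariates.
#'
#' @param calvings calving records (see [read_calving_records()]) already
#'   reduced to analysable stillbirth records (see [derive_stillbirth()]
#'   which retains the needed columns)
#' @param carrier_status named logical over genotyped individuals
#' @param ped a sorted `pedigree`
#' @return `data.table` with `live` (1 = live calf, 0 = dead),
#'   `p_hom_fetus`, `parity`, `sex`, `year_month`
#' @export
build_hom_fetus_records <- function(calvings, carrier_status, ped) {
  genotyped <- names(carrier_status)
  sire_of <- setNames(ped$sire, ped$individual)
  cv <- as.data.table(calvings)
  if (!"dam" %in% names(cv) && "animal" %in% names(cv)) {
    # derive_stillbirth() output: map the trait-table shape back
    cv <- copy(cv)
    setnames(cv, "animal", "dam")
    if (!"calf_sex" %in% names(cv) && "sex" %in% names(cv)) {
      setnames(cv, "sex", "calf_sex")
    }
    if (!"outcome" %in% names(cv) && "value" %in% names(cv)) {
      cv[, outcome := fifelse(value == 1, "live", "stillborn")]
    }
  }
  cv[, sire_g := sire %in% genotyped]
  cv[, dam_g := dam %in% genotyped]
  cv[, mgs := sire_of[dam]]
  cv[, mgs_g := !is.na(mgs) & mgs %in% genotyped]
  use <- cv[sire_g & (dam_g | mgs_g)]
  if (!nrow(use)) return(data.table(live = integer(),
                                    p_hom_fetus = numeric(),
                                    parity = integer(), sex = character(),
                                    year_month = character()))
  sc <- as.numeric(carrier_status[use$sire])
  dc <- ifelse(use$dam_g, as.numeric(carrier_status[use$dam]), NA_real_)
  mc <- ifelse(use$mgs_g, as.numeric(carrier_status[use$mgs]), NA_real_)
  use[, p_hom_fetus := p_hom_fetus(sc, dc, mc, dam_genotyped = dam_g)]
  use[, year_month := format(as.Date(date), "%Y-%m")]
  use[, .(live = as.integer(outcome == "live"), p_hom_fetus,
          parity = pmin(parity, 4L), sex = calf_sex, year_month)]
}

#' Logistic test of a haplotype's effect on stillbirth
#'
#' Fits `live ~ parity + sex + year_month + p_hom_fetus` by maximum
#' likelihood (iteratively reweighted least squares, log-likelihood
#' convergence `1e-8`, at most 50 iterations). The response is the
#' live-calf indicator, so a lethal haplotype gives a negative
#' coefficient; the stillbirth odds ratio `1/exp(beta)` is reported to
#' keep the sign unambiguous. Year-month cells below `min_cell` records
#' are merged into the nearest preceding month to keep the design
#' full-rank. Complete separation or an inestimable slope is flagged and
#' the p-value set to `NA`.
#'
#' @param records output of [build_hom_fetus_records()]
#' @param min_cell minimum year-month class size before merging
#' @return one-row `data.table`: `beta` (live scale), `se`, `z`, `p`,
#'   `or_stillbirth`, `n`, `separation` flag
#' @export
fit_stillbirth_logistic <- function(records, min_cell = 5L) {
  rec <- as.data.table(records)
  if (!nrow(rec) || all(rec$p_hom_fetus == 0)) {
    stop("degenerate design: no record with p_hom_fetus > 0",
         call. = FALSE)
  }
  rec[, year_month := merge_small_classes(year_month, min_cell)]
  rec[, parity := factor(parity)]
  rec[, sex := factor(sex)]
  rec[, year_month := factor(year_month)]
  # drop single-level factors (tiny fixtures)
  terms <- c("parity", "sex", "year_month")
  terms <- terms[vapply(terms, function(t) nlevels(rec[[t]]) > 1L,
                        logical(1))]
  fml <- as.formula(paste("live ~", paste(c(terms, "p_hom_fetus"),
                                          collapse = " + ")))
  fit <- glm(fml, family = binomial(), data = rec,
             control = list(epsilon = 1e-8, maxit = 50L))
  if (!fit$converged) {
    stop("logistic fit did not converge after 50 iterations",
         call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  if (!"p_hom_fetus" %in% rownames(cf)) {
    stop("degenerate design: haplotype effect aliased", call. = FALSE)
  }
  beta <- cf["p_hom_fetus", 1]; se <- cf["p_hom_fetus", 2]
  sep <- isTRUE(fit$boundary) || se > 100 || abs(beta) > 15
  z <- beta / se
  data.table(beta = beta, se = se, z = z,
             p = if (sep) NA_real_ else 2 * pnorm(-abs(z)),
             or_stillbirth = exp(-beta), n = nrow(rec),
             separation = sep)
}

# merge factor cells with < min_n records into the nearest preceding
# level (levels sorted, so year-months merge into adjacent months)
merge_small_classes <- function(x, min_n) {
  x <- as.character(x)
  repeat {
    tab <- table(x)
    small <- names(tab)[tab < min_n]
    if (!length(small) || length(tab) == 1L) break
    lv <- sort(names(tab))
    tgt <- small[1]
    pos <- match(tgt, lv)
    into <- if (pos > 1L) lv[pos - 1L] else lv[2L]
    x[x == tgt] <- into
  }
  x
}

#' Classify an insemination by sire and maternal-grand-sire carrier status
#'
#' Mating types: (1) non-carrier sire x non-carrier maternal grand sire,
#' (2) NC sire x C MGS, (3) C sire x NC MGS, (4) C sire x C MGS.
#'
#' @param sire_carrier,mgs_carrier logical (or 0/1)
#' @return integer 1-4 (`NA` when a status is unknown)
#' @export
classify_mating_type <- function(sire_carrier, mgs_carrier) {
  s <- as.logical(sire_carrier); m <- as.logical(mgs_carrier)
  ifelse(is.na(s) | is.na(m), NA_integer_,
         1L + as.integer(m) + 2L * as.integer(s))
}

#' Background insemination failure rate
#'
#' The weighted mean failure rate (1 - NRR56) over mating types 1 and 2,
#' weighted by record counts — the carrier sire plays no role in these
#' types, so they estimate the failure rate free of the candidate lethal.
#'
#' @param records `data.table` with columns `mating_type`, `nrr56`
#' @return `f`, the background failure proportion
#' @export
background_failure <- function(records) {
  rec <- as.data.table(records)[mating_type %in% c(1L, 2L)]
  if (!nrow(rec) || !all(c(1L, 2L) %in% rec$mating_type)) {
    stop("mating types 1 and 2 must both be non-empty", call. = FALSE)
  }
  mean(1 - rec$nrr56)
}

#' Expected extra insemination failure by mating type
#'
#' For a recessive lethal haplotype at frequency `p` with background
#' failure `f`, the extra failure over background is 0 for mating types 1
#' and 2, `0.25 p (1 - f)` for type 3, and
#' `0.25 * 0.5/(1 - 0.5 p) * (1 - f)` for type 4 (the conditional carrier
#' probability of an ungenotyped dam whose sire is a carrier).
#'
#' @param p haplotype frequency, `0 < p < 0.5`
#' @param f background failure, `0 <= f < 1`
#' @return numeric vector of length 4 named `type1`..`type4`
#' @export
expected_extra_failure <- function(p, f) {
  stopifnot(length(p) == 1L, length(f) == 1L, p > 0, p < 0.5,
            f >= 0, f <= 1)
  c(type1 = 0, type2 = 0,
    type3 = 0.25 * p * (1 - f),
    type4 = 0.25 * 0.5 / (1 - 0.5 * p) * (1 - f))
}

#' Mating-type mixed model for non-return rate at day 56
#'
#' Fits `nrr56 = mu + parity + year + mating_type + u_cow + e` with the
#' cow's additive genetic effect against the pedigree numerator
#' relationship matrix, via Henderson's mixed-model equations. Mating
#' type 4 (carrier sire x carrier maternal grand sire) is the reference
#' level, so the mating-type solutions are deviations from type 4 with
#' standard errors from the inverse coefficient matrix; Wald z and
#' two-sided p are reported per contrast. Variance components are either
#' supplied or estimated by AI-REML.
#'
#' @param records `data.table` with `cow`, `nrr56`, `parity`, `year`,
#'   `mating_type` (1-4; type 4 must be non-empty)
#' @param ped a sorted `pedigree` covering the cows
#' @param varcomp named list/vector `c(u = sigma2_u, e = sigma2_e)`;
#'   `NULL` to estimate by REML
#' @return list with `effects` (`data.table` mating type, n, estimate,
#'   se, z, p), `varcomp`, and the underlying `fit`
#' @export
fit_nrr56_mixed <- function(records, ped, varcomp = NULL) {
  rec <- as.data.table(records)
  rec <- rec[!is.na(mating_type)]
  if (!any(rec$mating_type == 4L)) {
    stop("mating type 4 is the reference level and must be non-empty",
         call. = FALSE)
  }
  rec[, mt := factor(mating_type, levels = c(4L, 1L, 2L, 3L))]
  rec[, parity := factor(parity)]
  rec[, year := factor(year)]
  fixed_terms <- c("mt",
                   if (nlevels(rec$parity) > 1L) "parity",
                   if (nlevels(rec$year) > 1L) "year")
  fit <- fit_mixed_model(
    data = rec, response = "nrr56",
    fixed = as.formula(paste("~", paste(fixed_terms, collapse = " + "))),
    random = list(mm_random("u", factor = "cow", kind = "pedigree",
                            pedigree = ped)),
    varcomp = varcomp)
  cf <- fit$beta
  vc <- fit$beta_vcov
  rows <- grep("^mt", names(cf), value = TRUE)
  counts <- rec[, .N, keyby = mating_type]
  eff <- rbindlist(lapply(rows, function(r) {
    lev <- as.integer(sub("^mt", "", r))
    est <- cf[[r]]; se <- sqrt(vc[r, r])
    data.table(mating_type = lev,
               n = counts[mating_type == lev, N],
               estimate = est, se = se, z = est / se,
               p = 2 * pnorm(-abs(est / se)))
  }))
  setorder(eff, mating_type)
  list(effects = eff[], varcomp = fit$varcomp, fit = fit)
}

#' Mating-type insemination-failure analysis for one haplotype
#'
#' End-to-end wrapper mirroring the field workflow: derive NRR56 records,
#' classify each service period by the carrier status of the service sire
#' and the cow's sire (the conceptus's maternal grand sire), compute the
#' background failure from mating types 1-2, fit the mating-type mixed
#' model, and attach the theoretical extra-failure curve for a recessive
#' lethal at the haplotype's frequency.
#'
#' @param nrr56_records output of [derive_nrr56()]
#' @param calvings calving records (sire of each service period's
#'   conception; periods without a calving fall back to the herd's AI
#'   sires being unknown and are dropped)
#' @param inseminations insemination records with a `sire` column, or
#'   `NULL` when `calvings` carries the service sire
#' @param ped a sorted `pedigree`
#' @param carrier_status named logical over genotyped individuals
#' @param hap_frequency haplotype frequency (for the expected curve)
#' @param varcomp optional fixed variance components for the mixed model
#' @return list `effects`, `f` (background failure), `expected`
#'   (extra-failure curve), `counts` per mating type, `fit`
#' @export
nrr56_mating_analysis <- function(nrr56_records, calvings, inseminations,
                                  ped, carrier_status, hap_frequency,
                                  varcomp = NULL) {
  rec <- as.data.table(nrr56_records)
  genotyped <- names(carrier_status)
  sire_of <- setNames(ped$sire, ped$individual)
  # service sire: taken from the conception's calving record when the
  # period ends in a calving, else from the insemination table
  cv <- as.data.table(calvings)
  key <- cv[, .(animal = dam, parity = parity, service_sire = sire)]
  rec <- merge(rec, unique(key, by = c("animal", "parity")),
               by = c("animal", "parity"), all.x = TRUE)
  if (!is.null(inseminations) && "sire" %in% names(inseminations)) {
    ins <- as.data.table(inseminations)
    fallback <- unique(ins[, .(animal = cow, parity = lactation,
                               alt_sire = sire)],
                       by = c("animal", "parity"))
    rec <- merge(rec, fallback, by = c("animal", "parity"), all.x = TRUE)
    rec[is.na(service_sire), service_sire := alt_sire]
  }
  rec[, mgs := sire_of[animal]]
  rec <- rec[!is.na(service_sire) & service_sire %in% genotyped &
               !is.na(mgs) & mgs %in% genotyped]
  rec[, mating_type := classify_mating_type(carrier_status[service_sire],
                                            carrier_status[mgs])]
  rec <- rec[!is.na(mating_type)]
  rec[, nrr56 := value]
  rec[, cow := animal]
  f <- background_failure(rec)
  expected <- expected_extra_failure(hap_frequency, f)
  fitres <- fit_nrr56_mixed(rec, ped, varcomp = varcomp)
  list(effects = fitres$effects, f = f, expected = expected,
       counts = rec[, .N, keyby = mating_type], fit = fitres$fit,
       records = rec)
}
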