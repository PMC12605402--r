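#' Age in whole months
#'
#' Month arithmetic used by all age filters: floor of days divided by the
#' mean Gregorian month length (30.4375 days).
#'
#' @param birth_date,at_date `Date` vectors
#' @return integer months
#' @export
age_months <- function(birth_date, at_date) {
  as.integer(floor(as.numeric(as.Date(at_date) - as.Date(birth_date)) /
                     30.4375))
}

#' Derive stillbirth phenotypes from calving records
#'
#' Assigns 1 to a live calf and 0 to a dead one (outcome `stillborn`,
#' `died_during_calving` or `died_within_24h`); abortions are not
#' stillbirths and are excluded, as are twin calvings. At most
#' `max_calvings` calvings per dam are kept (4 for association use, 5 for
#' haplotype-effect use), and only records whose dam was strictly more
#' than 19 and strictly less than 37 months old at her first calving
#' (20-36 whole months). Parity is 0-based: 0 = maiden heifer's first
#' calving.
#'
#' @param calvings calving records (see [read_calving_records()])
#' @param ped a `pedigree` providing dam birth dates
#' @param max_calvings calvings kept per dam (default 5)
#' @return `data.table`: `animal` (the dam), `trait` (`"SB"`), `value`
#'   (1 = live), `parity`, plus `calf`, `sire`, `sex`, `date`,
#'   `year_month` and any `herd` column present
#' @export
derive_stillbirth <- function(calvings, ped, max_calvings = 5L) {
  cv <- as.data.table(calvings)
  bad <- setdiff(unique(cv$outcome), calving_outcomes())
  if (length(bad)) stop("validation error: unknown outcome category: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cv[, date := as.Date(date)]
  cv <- cv[outcome != "abortion"]
  setorder(cv, dam, date)
  # age at first calving from the dam's actual first calving (twin or
  # not); twins are then removed and the recorded parity used
  birth <- setNames(ped$birth_date, ped$individual)
  first <- cv[, .(first_calving = date[1]), by = dam]
  first[, afc := age_months(birth[dam], first_calving)]
  cv <- merge(cv, first[, .(dam, afc)], by = "dam")
  cv <- cv[twin == FALSE | twin == 0L]
  cv <- cv[parity < max_calvings]
  cv <- cv[!is.na(afc) & afc > 19L & afc < 37L]
  out <- cv[, .(animal = dam, trait = "SB",
                value = as.integer(outcome == "live"),
                parity = as.integer(parity), calf, sire,
                sex = calf_sex,
                date, year_month = format(date, "%Y-%m"))]
  if ("herd" %in% names(cv)) out[, herd := cv$herd]
  out[]
}

# split a cow's inseminations into service periods delimited by her
# calvings; lactation = number of calvings before the period
service_periods <- function(ins, cvs) {
  ins <- as.data.table(ins)[order(date)]
  cdates <- sort(as.Date(cvs$date))
  ins[, lactation := findInterval(as.numeric(date),
                                  as.numeric(cdates))]
  ins
}

#' Derive conception-rate and interval fertility traits
#'
#' Derives conception rate (CR), calving interval (CI), interval from
#' first to last insemination (IFL) and inseminations per service period
#' (AIS) from insemination and calving records, for maiden heifers
#' (lactation 0) through lactation 3. CR is 1 when IFL is 0-4 days and
#' the cow calves 260-302 days after first insemination; 0 when IFL >= 5
#' days with a calving in that window, or when the cow was inseminated
#' but never calved. Editing limits (records outside are dropped): age at
#' first calving 550-1100 d, CI 280-600 d, age at first insemination
#' 270-900 d, calving to first insemination 20-230 d, IFL 0-365 d,
#' calving to last insemination 20-365 d, gestation 260-302 d, AIS 1-8.
#' Lactation 2 and 3 service periods are dropped when any earlier
#' lactation's period is absent.
#'
#' @param inseminations insemination records (see
#'   [read_insemination_records()])
#' @param calvings calving records of the same cows (as dams)
#' @param ped a `pedigree` providing cow birth dates
#' @return long `data.table`: `animal`, `trait` (CR/CI/IFL/AIS), `value`,
#'   `parity` (= lactation), with `year`, `month`, `age_months`,
#'   `technician` and any `herd` covariates
#' @export
derive_fertility <- function(inseminations, calvings, ped) {
  ins <- as.data.table(inseminations)
  cv <- as.data.table(calvings)
  ins[, date := as.Date(date)]
  cv[, date := as.Date(date)]
  birth <- setNames(ped$birth_date, ped$individual)
  missing_cows <- setdiff(unique(ins$cow), c(cv$dam, ped$individual))
  if (length(missing_cows)) {
    warning(length(missing_cows), " insemination cow id(s) unknown; ",
            "records skipped")
    ins <- ins[!(cow %in% missing_cows)]
  }
  out <- list()
  for (cw in unique(ins$cow)) {
    cvs <- cv[dam == cw][order(date)]
    per <- service_periods(ins[cow == cw], cvs)
    hascol <- "herd" %in% names(per)
    # age-at-first-calving gate (cow level)
    if (nrow(cvs)) {
      afc_d <- as.numeric(cvs$date[1] - as.Date(birth[cw]))
      if (is.na(afc_d) || afc_d < 550 || afc_d > 1100) next
    }
    have_lact <- sort(unique(per$lactation))
    for (lact in intersect(have_lact, 0:3)) {
      if (lact >= 2L && !all((seq_len(lact) - 1L) %in% have_lact)) next
      sp <- per[lactation == lact][order(date)]
      first_ins <- sp$date[1]
      last_ins <- sp$date[nrow(sp)]
      ais <- nrow(sp)
      ifl <- as.numeric(last_ins - first_ins)
      next_calv <- cvs$date[cvs$date > first_ins][1]
      prev_calv <- if (lact >= 1L) cvs$date[lact] else as.Date(NA)
      # editing limits
      if (ais < 1L || ais > 8L) next
      if (ifl < 0 || ifl > 365) next
      if (lact == 0L) {
        afi <- as.numeric(first_ins - as.Date(birth[cw]))
        if (is.na(afi) || afi < 270 || afi > 900) next
      } else {
        cfi <- as.numeric(first_ins - prev_calv)
        if (is.na(cfi) || cfi < 20 || cfi > 230) next
        cli <- as.numeric(last_ins - prev_calv)
        if (cli < 20 || cli > 365) next
      }
      calved <- !is.na(next_calv)
      if (calved) {
        gest <- as.numeric(next_calv - last_ins)
        if (gest < 260 || gest > 302) next
      }
      # CR success is anchored on the first insemination; failure with
      # IFL >= 5 means conception happened at a later insemination, so
      # the gestation window is checked from the last one
      d_first <- if (calved) as.numeric(next_calv - first_ins) else NA
      d_last <- if (calved) as.numeric(next_calv - last_ins) else NA
      cr <- if (calved && ifl <= 4 && d_first >= 260 && d_first <= 302) {
        1L
      } else if (calved && ifl >= 5 && d_last >= 260 && d_last <= 302) {
        0L
      } else if (!calved) 0L else NA_integer_
      covs <- data.table(
        year = as.integer(format(first_ins, "%Y")),
        month = as.integer(format(first_ins, "%m")),
        age_months = age_months(birth[cw], first_ins),
        technician = sp$technician[1])
      if (hascol) covs[, herd := sp$herd[1]]
      add <- function(trait, value) {
        if (is.na(value)) return(NULL)
        cbind(data.table(animal = cw, trait = trait,
                         value = as.numeric(value), parity = lact), covs)
      }
      out[[length(out) + 1L]] <- add("CR", cr)
      out[[length(out) + 1L]] <- add("IFL", ifl)
      out[[length(out) + 1L]] <- add("AIS", ais)
      if (lact >= 1L && calved) {
        ci <- as.numeric(next_calv - prev_calv)
        if (ci >= 280 && ci <= 600) {
          out[[length(out) + 1L]] <- add("CI", ci)
        }
      }
    }
  }
  if (!length(out)) return(data.table(animal = character(),
                                      trait = character(),
                                      value = numeric(),
                                      parity = integer()))
  rbindlist(out, fill = TRUE)
}

#' Derive non-return rate at 56 days
#'
#' One record per cow service period (lactations 0-3): 1 when the cow is
#' not re-inseminated within 56 days of her first insemination, 0 when a
#' re-insemination falls on days 3-55 after it. A re-insemination less
#' than 3 days after the previous insemination is discarded (double
#' recording); service periods whose first-insemination-to-calving
#' interval is under 266 days are removed.
#'
#' @inheritParams derive_fertility
#' @return `data.table`: `animal`, `trait` (`"NRR56"`), `value`,
#'   `parity`, `year`, `month`, `technician` (+ `herd` when present)
#' @export
derive_nrr56 <- function(inseminations, calvings, ped = NULL) {
  ins <- as.data.table(inseminations)
  cv <- as.data.table(calvings)
  ins[, date := as.Date(date)]
  cv[, date := as.Date(date)]
  out <- list()
  for (cw in unique(ins$cow)) {
    cvs <- cv[dam == cw][order(date)]
    per <- service_periods(ins[cow == cw], cvs)
    hascol <- "herd" %in% names(per)
    for (lact in intersect(unique(per$lactation), 0:3)) {
      sp <- per[lactation == lact][order(date)]
      # drop re-inseminations < 3 days after the previous kept one
      keep <- logical(nrow(sp))
      last_kept <- as.Date(NA)
      for (i in seq_len(nrow(sp))) {
        if (is.na(last_kept) ||
              as.numeric(sp$date[i] - last_kept) >= 3) {
          keep[i] <- TRUE
          last_kept <- sp$date[i]
        }
      }
      sp <- sp[keep]
      if (!nrow(sp)) next
      first_ins <- sp$date[1]
      next_calv <- cvs$date[cvs$date > first_ins][1]
      if (!is.na(next_calv) &&
            as.numeric(next_calv - first_ins) < 266) next
      ret <- as.numeric(sp$date - first_ins)
      nrr <- as.integer(!any(ret >= 3 & ret <= 55))
      row <- data.table(animal = cw, trait = "NRR56",
                        value = nrr, parity = lact,
                        year = as.integer(format(first_ins, "%Y")),
                        month = as.integer(format(first_ins, "%m")),
                        technician = sp$technician[1])
      if (hascol) row[, herd := sp$herd[1]]
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(data.table(animal = character(),
                                      trait = character(),
                                      value = integer(),
                                      parity = integer()))
  rbindlist(out, fill = TRUE)
}

#' Enforce a minimum class size on fixed-effect cells
#'
#' Iteratively removes records belonging to any class (joint level of
#' `class_fields`) with fewer than `min_n` observations, until every
#' remaining class satisfies the minimum (removals can shrink other
#' classes, so this runs to a fixed point).
#'
#' @param table a trait table
#' @param class_fields character vector of class-defining columns
#' @param min_n minimum class size (default 10)
#' @return filtered `data.table`
#' @export
enforce_class_minimum <- function(table, class_fields, min_n = 10L) {
  stopifnot(min_n >= 1L)
  dt <- as.data.table(table)
  repeat {
    if (!nrow(dt)) {
      warning("enforce_class_minimum removed every record")
      break
    }
    sizes <- dt[, .N, by = class_fields]
    if (all(sizes$N >= min_n)) break
    small <- sizes[N < min_n][, N := NULL]
    dt <- dt[!small, on = class_fields]
  }
  dt[]
}

#' Derive the infertility phenotype
#'
#' Cows that never calved and were culled for infertility are assigned 0;
#' cows that calved at least once are assigned 1. Cows that neither
#' calved nor were infertility-culled are absent.
#'
#' @param calvings calving records (dams define "calved")
#' @param cullings `data.table` with `cow`, `reason` (the infertility
#'   culling code is `"infertility"`)
#' @return `data.table`: `animal`, `trait` (`"INF"`), `value`
#' @export
derive_infertility <- function(calvings, cullings) {
  cv <- as.data.table(calvings)
  cu <- as.data.table(cullings)
  calved <- unique(cv$dam)
  inf_culled <- unique(cu[reason == "infertility", cow])
  rbind(
    data.table(animal = calved, trait = "INF", value = 1),
    data.table(animal = setdiff(inf_culled, calved), trait = "INF",
               value = 0))
}
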