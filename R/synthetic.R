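#' Derive a labelled child seed from a master seed
#'
#' Every sub-simulation (pedigree, genotypes, phenotypes, ...) seeds its
#' own RNG stream from the master seed and a stage label, so stages are
#' independently reproducible. The result stays below 2^31.
#'
#' @param seed master seed (integer)
#' @param label stage label
#' @return integer seed
#' @export
child_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973) %% 2147483647)
}

#' Specification of an embedded recessive lethal
#'
#' A lethal rides a designated founder haplotype ("tag") spanning a
#' marker window. It acts at conception (embryonic loss: the cow returns
#' to service) or at birth (stillbirth), with the given penetrance.
#'
#' @param chromosome chromosome label
#' @param window_start first marker index (within chromosome) of the tag
#'   window
#' @param window_length tag window length in markers (default 25)
#' @param target_frequency founder frequency of the tag haplotype
#'   (0 < f < 0.5; segregating lethals in cattle run at 2-9%)
#' @param acts_at `"conception"` or `"birth"`
#' @param penetrance probability a homozygote dies (default 1)
#' @return a `lethal_spec`
#' @export
lethal_spec <- function(chromosome, window_start = 1L,
                        window_length = 25L, target_frequency = 0.05,
                        acts_at = c("conception", "birth"),
                        penetrance = 1) {
  acts_at <- match.arg(acts_at)
  stopifnot(target_frequency > 0, target_frequency < 0.5,
            penetrance >= 0, penetrance <= 1)
  structure(list(chromosome = as.character(chromosome),
                 window_start = as.integer(window_start),
                 window_length = as.integer(window_length),
                 target_frequency = target_frequency,
                 acts_at = acts_at, penetrance = penetrance),
            class = "lethal_spec")
}

#' Simulation parameters
#'
#' Defaults encode the data architecture the analyses assume: an
#' AI half-sib pedigree over ~5 generations; a scaled-down SNP map;
#' baseline stillbirth of 26% for heifer calvings and 9.2% for later
#' parities; background insemination failure of 0.32 (a realistic
#' non-return failure rate for AI dairy records); and variance
#' components of the magnitude seen in pedigree analyses of these traits
#' (stillbirth additive ~0.015-0.016 against residual ~0.162 on the 0/1
#' scale; fertility additive ~0.0039 against residual ~0.22).
#'
#' @param n_founders founder animals (generation 0)
#' @param n_generations generations bred after the founders
#' @param sires_per_generation AI sires used per generation
#' @param offspring_per_sire offspring registered per AI sire per
#'   generation
#' @param n_chromosomes,markers_per_chromosome map size
#' @param marker_spacing_bp distance between markers (default 60 kb)
#' @param founder_pool_size distinct founder haplotypes per chromosome
#' @param recombination_rate probability of one crossover per chromosome
#'   per meiosis (at most one); the default 0.2 matches a ~9 Mb (~9 cM)
#'   scaled-down chromosome of 150 markers at 60 kb spacing
#' @param baseline_stillbirth_heifer,baseline_stillbirth_later baseline
#'   stillbirth probabilities by parity group
#' @param background_failure_f background insemination failure
#' @param mean_parities average calvings per cow (1-5)
#' @param n_herds herds for herd-structured fixed effects
#' @param sb_varcomp,fert_varcomp named variance components
#'   (`u` direct additive, `m` maternal additive, `pe`, `e`) on the
#'   observed scale
#' @param sex_effect_sb added stillbirth probability for male calves
#' @param month_amplitude seasonal amplitude on both liabilities
#' @param twin_rate,abortion_rate rates of twin calvings and recorded
#'   abortions (exercise the record filters)
#' @param seed master seed
#' @return a `sim_params` list
#' @export
sim_params <- function(n_founders = 200L, n_generations = 4L,
                       sires_per_generation = 8L,
                       offspring_per_sire = 25L,
                       n_chromosomes = 3L,
                       markers_per_chromosome = 150L,
                       marker_spacing_bp = 60000L,
                       founder_pool_size = 30L,
                       recombination_rate = 0.2,
                       baseline_stillbirth_heifer = 0.26,
                       baseline_stillbirth_later = 0.092,
                       background_failure_f = 0.32,
                       mean_parities = 2.5,
                       n_herds = 25L,
                       sb_varcomp = c(u = 0.015, m = 0.016, pe = 0.005,
                                      e = 0.162),
                       fert_varcomp = c(u = 0.0039, pe = 0.005,
                                        e = 0.22),
                       sex_effect_sb = 0.03,
                       month_amplitude = 0.02,
                       twin_rate = 0.02,
                       abortion_rate = 0.005,
                       seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$recombination_rate, p$baseline_stillbirth_heifer,
             p$baseline_stillbirth_later, p$background_failure_f,
             p$twin_rate, p$abortion_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("parameter error: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  counts <- c(p$n_founders, p$n_generations, p$sires_per_generation,
              p$offspring_per_sire, p$n_chromosomes,
              p$markers_per_chromosome, p$n_herds)
  if (any(counts < 1L)) stop("parameter error: counts must be positive",
                             call. = FALSE)
  structure(p, class = "sim_params")
}

#' Simulate an AI half-sib pedigree
#'
#' Generation 0 is unrelated founders (half male). Each later generation
#' draws a few AI sires from the previous generation's males and mates
#' them to dams of the previous generation, producing large paternal
#' half-sib families. Birth dates advance two years per generation with
#' random calving months.
#'
#' @param params a [sim_params()]
#' @return a sorted `pedigree`; the per-generation AI sire lists are in
#'   `attr(, "ai_sires")` and the generation index in `attr(, "generation")`
#' @export
simulate_pedigree <- function(params) {
  set.seed(child_seed(params$seed, "pedigree"))
  nf <- params$n_founders
  rows <- list(data.table(
    individual = sprintf("F%04d", seq_len(nf)),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), length.out = nf),
    birth_date = as.Date("2000-01-01") +
      sample.int(365L, nf, replace = TRUE) - 1L))
  gen <- list(rows[[1]]$individual)
  ai_sires <- list()
  for (g in seq_len(params$n_generations)) {
    prev <- rbindlist(rows)
    prev_ids <- gen[[g]]
    males <- prev[individual %in% prev_ids & sex == "M", individual]
    females <- prev[individual %in% prev_ids & sex == "F", individual]
    if (!length(males) || !length(females)) {
      stop("parameter error: generation ", g,
           " has no available sires or dams", call. = FALSE)
    }
    sires <- sample(males, min(params$sires_per_generation,
                               length(males)))
    ai_sires[[g]] <- sires
    n_off <- params$offspring_per_sire * length(sires)
    off <- data.table(
      individual = sprintf("G%d_%04d", g, seq_len(n_off)),
      sire = sample(rep(sires, length.out = n_off)),
      dam = sample(females, n_off, replace = TRUE),
      sex = rep(c("M", "F"), length.out = n_off),
      birth_date = as.Date(sprintf("%d-01-01", 2000L + 2L * g)) +
        sample.int(365L, n_off, replace = TRUE) - 1L)
    rows[[g + 1L]] <- off
    gen[[g + 1L]] <- off$individual
  }
  ped <- as_pedigree(rbindlist(rows))
  gen_idx <- integer(nrow(ped))
  for (g in seq_along(gen)) gen_idx[match(gen[[g]], ped$individual)] <-
    g - 1L
  setattr(ped, "generation", setNames(gen_idx, ped$individual))
  setattr(ped, "ai_sires", ai_sires)
  ped
}

# founder haplotype pool for one chromosome: pool member 1 is the tag
# carrier when a lethal sits on the chromosome
make_pool <- function(m, pool_size) {
  freq <- runif(m, 0.1, 0.9)
  pool <- matrix(0L, pool_size, m)
  for (j in seq_len(pool_size)) {
    pool[j, ] <- as.integer(runif(m) < freq)
  }
  pool
}

#' Gene-drop phased genotypes through a pedigree
#'
#' Founders draw chromosome haplotypes from a finite founder pool in
#' which each lethal's tag haplotype has its target frequency; gametes
#' recombine with at most one crossover per chromosome. Pedigree
#' individuals are survivors: a conceptus homozygous for a lethal is
#' redrawn with probability equal to the penetrance, so no parent (or
#' genotyped adult) is homozygous for a fully penetrant lethal. Phase is
#' known by construction.
#'
#' @param ped a sorted `pedigree` from [simulate_pedigree()]
#' @param params a [sim_params()]
#' @param lethals list of [lethal_spec()]s
#' @return a [phased_genotypes()] object; per-lethal truth (carrier copy
#'   counts) in `attr(, "lethal_copies")`, the tag haplotype strings in
#'   `attr(, "tag_haplotypes")`
#' @export
simulate_genotypes <- function(ped, params, lethals = list()) {
  set.seed(child_seed(params$seed, "genotypes"))
  m <- params$markers_per_chromosome
  chroms <- as.character(seq_len(params$n_chromosomes))
  for (lt in lethals) {
    if (!(lt$chromosome %in% chroms) ||
          lt$window_start + lt$window_length - 1L > m) {
      stop("lethal spec error: window outside the marker map",
           call. = FALSE)
    }
  }
  map <- marker_map(
    marker_id = unlist(lapply(chroms, function(c.)
      sprintf("c%s_m%03d", c., seq_len(m)))),
    chrom = rep(chroms, each = m),
    pos = rep(seq_len(m) * params$marker_spacing_bp, params$n_chromosomes))
  pools <- lapply(chroms, function(c.) make_pool(m,
                                                 params$founder_pool_size))
  names(pools) <- chroms
  # pool draw weights: tag gets its target frequency, the rest a gently
  # decaying series (realistic uneven haplotype spectrum)
  weights <- lapply(chroms, function(c.) {
    lt <- Filter(function(l) l$chromosome == c., lethals)
    ptag <- if (length(lt)) lt[[1]]$target_frequency else 0
    w <- 1 / seq_len(params$founder_pool_size - 1L)
    c(ptag, (1 - ptag) * w / sum(w))
  })
  names(weights) <- chroms
  lethal_on <- vapply(lethals, `[[`, character(1), "chromosome")
  n <- nrow(ped)
  pi <- ped_indices(ped)
  ncol_tot <- m * length(chroms)
  H <- matrix(0L, 2L * n, ncol_tot)
  col_of <- function(c.) (match(c., chroms) - 1L) * m + seq_len(m)
  lethal_win <- lapply(lethals, function(lt) {
    (match(lt$chromosome, chroms) - 1L) * m +
      seq(lt$window_start, lt$window_start + lt$window_length - 1L)
  })
  tag_seg <- lapply(seq_along(lethals), function(k) {
    lt <- lethals[[k]]
    pools[[lt$chromosome]][1L, seq(lt$window_start,
                                   lt$window_start + lt$window_length - 1L)]
  })
  is_hom <- function(h1, h2) {
    for (k in seq_along(lethals)) {
      w <- lethal_win[[k]]
      if (all(h1[w] == tag_seg[[k]]) && all(h2[w] == tag_seg[[k]])) {
        return(k)
      }
    }
    0L
  }
  draw_founder_hap <- function() {
    h <- integer(ncol_tot)
    for (c. in chroms) {
      j <- sample.int(params$founder_pool_size, 1L,
                      prob = weights[[c.]])
      h[col_of(c.)] <- pools[[c.]][j, ]
    }
    h
  }
  gamete <- function(parent_idx) {
    h <- integer(ncol_tot)
    r1 <- 2L * parent_idx - 1L
    for (c. in chroms) {
      cols <- col_of(c.)
      top <- sample.int(2L, 1L) == 1L
      a <- if (top) H[r1, cols] else H[r1 + 1L, cols]
      if (runif(1) < params$recombination_rate) {
        cut <- sample.int(m - 1L, 1L)
        b <- if (top) H[r1 + 1L, cols] else H[r1, cols]
        a <- c(a[seq_len(cut)], b[(cut + 1L):m])
      }
      h[cols] <- a
    }
    h
  }
  # The stated world has each lethal currently segregating near its
  # target frequency; with few AI sires per generation, drift through the
  # sire bottleneck would regularly lose (or double) the allele, so the
  # gene-drop is redrawn until every lethal's realized population
  # frequency lies within [0.5, 2] x target (documented in the methods
  # vignette).
  for (try in seq_len(25L)) {
    for (i in seq_len(n)) {
      repeat {
        if (pi$s[i] == 0L || pi$d[i] == 0L) {
          h1 <- draw_founder_hap(); h2 <- draw_founder_hap()
        } else {
          h1 <- gamete(pi$s[i]); h2 <- gamete(pi$d[i])
        }
        k <- if (length(lethals)) is_hom(h1, h2) else 0L
        if (k == 0L) break
        # homozygous conceptus: survives only with prob 1 - penetrance
        if (runif(1) >= lethals[[k]]$penetrance) break
      }
      H[2L * i - 1L, ] <- h1
      H[2L * i, ] <- h2
    }
    if (!length(lethals)) break
    realized <- vapply(seq_along(lethals), function(k) {
      w <- lethal_win[[k]]
      tg <- tag_seg[[k]]
      hits <- colSums(t(H[, w, drop = FALSE]) == tg) == length(tg)
      mean(hits)
    }, numeric(1))
    targets <- vapply(lethals, `[[`, numeric(1), "target_frequency")
    if (all(realized >= 0.5 * targets & realized <= 2 * targets)) break
    if (try == 25L) {
      warning("lethal frequency conditioning failed after 25 gene-drop ",
              "attempts (realized ",
              paste(signif(realized, 3), collapse = ", "), ")")
    }
  }
  pg <- phased_genotypes(ped$individual, map, H)
  copies <- lapply(seq_along(lethals), function(k) {
    w <- lethal_win[[k]]
    a <- H[seq(1L, 2L * n, 2L), w, drop = FALSE]
    b <- H[seq(2L, 2L * n, 2L), w, drop = FALSE]
    tg <- tag_seg[[k]]
    setNames(as.integer(colSums(t(a) == tg) == length(tg)) +
               as.integer(colSums(t(b) == tg) == length(tg)),
             ped$individual)
  })
  setattr(pg, "lethal_copies", copies)
  setattr(pg, "tag_haplotypes", tag_seg)
  pg
}

# pedigree gene-drop of breeding values: founder ~ N(0, s2); offspring =
# parent average + Mendelian sampling
drop_breeding_values <- function(ped, s2) {
  pi <- ped_indices(ped)
  n <- length(pi$s)
  bv <- numeric(n)
  for (i in seq_len(n)) {
    s <- pi$s[i]; d <- pi$d[i]
    pa <- 0; msvar <- s2
    if (s > 0L && d > 0L) { pa <- (bv[s] + bv[d]) / 2; msvar <- s2 / 2 }
    else if (s > 0L) { pa <- bv[s] / 2; msvar <- 0.75 * s2 }
    else if (d > 0L) { pa <- bv[d] / 2; msvar <- 0.75 * s2 }
    bv[i] <- pa + rnorm(1, 0, sqrt(msvar))
  }
  setNames(bv, pi$ids)
}

#' Simulate calving and insemination records
#'
#' Walks each cow through her service periods. Every insemination forms a
#' conceptus from one cow gamete and one service-sire gamete (AI sires of
#' the cow's generation); a conceptus homozygous for a conception-acting
#' lethal fails with probability equal to the penetrance, on top of the
#' background failure built from the cow's additive genetic and permanent
#' environment effects and a seasonal term. Failed conceptions trigger
#' re-insemination after 18-24 days. Conceptions calve at 278-284 days
#' after the last insemination; a conceptus homozygous for a birth-acting
#' lethal is stillborn with probability equal to the penetrance, others
#' through a liability combining the parity baseline, maternal and direct
#' breeding values, permanent environment, calf sex and season. Twin
#' calvings and abortions occur at their nominal rates so the record
#' filters have work to do.
#'
#' @param ped a `pedigree` from [simulate_pedigree()]
#' @param pg genotypes from [simulate_genotypes()] (for lethal truth)
#' @param lethals list of [lethal_spec()]s (must match `pg`)
#' @param params a [sim_params()]
#' @return list `calvings`, `inseminations` (both `data.table`s carrying
#'   `herd`), and `truth` (breeding values and permanent-environment
#'   draws used)
#' @export
simulate_phenotypes <- function(ped, pg, lethals, params) {
  set.seed(child_seed(params$seed, "phenotypes"))
  generation <- attr(ped, "generation")
  ai_sires <- attr(ped, "ai_sires")
  copies <- attr(pg, "lethal_copies") %||% list()
  cows <- ped[sex == "F" & !is.na(sire), individual]
  if (!length(cows)) stop("no breeding cows in pedigree", call. = FALSE)
  herd_of <- setNames(sample.int(params$n_herds, length(cows),
                                 replace = TRUE), cows)
  bv_m <- drop_breeding_values(ped, params$sb_varcomp[["m"]])
  bv_u_sb <- drop_breeding_values(ped, params$sb_varcomp[["u"]])
  bv_f <- drop_breeding_values(ped, params$fert_varcomp[["u"]])
  pe_sb <- setNames(rnorm(length(cows), 0,
                          sqrt(params$sb_varcomp[["pe"]])), cows)
  pe_f <- setNames(rnorm(length(cows), 0,
                         sqrt(params$fert_varcomp[["pe"]])), cows)
  birth <- setNames(ped$birth_date, ped$individual)
  season <- function(date) {
    params$month_amplitude *
      sin(2 * pi * as.integer(format(date, "%j")) / 365)
  }
  cavs <- list(); inss <- list()
  calf_no <- 0L
  for (cw in cows) {
    g <- generation[[cw]]
    sire_pool <- ai_sires[[min(max(g, 1L), length(ai_sires))]]
    n_par <- min(5L, max(1L, stats::rpois(1, params$mean_parities - 1) +
                           1L))
    date <- birth[[cw]] + round(runif(1, 420, 480))
    herd <- herd_of[[cw]]
    for (lact in 0:(n_par - 1L)) {
      if (lact > 3L) break
      sire <- sample(sire_pool, 1L)
      conceived <- FALSE
      for (attempt in seq_len(8L)) {
        inss[[length(inss) + 1L]] <- data.table(
          cow = cw, date = date,
          technician = sprintf("T%02d", 1L + (herd %% 15L)),
          lactation = lact, herd = herd)
        # conceptus lethal-homozygosity per embedded lethal
        hom <- logical(length(lethals))
        if (length(lethals)) {
          for (k in seq_along(lethals)) {
            pc <- copies[[k]][[cw]] / 2
            ps <- copies[[k]][[sire]] / 2
            hom[k] <- (runif(1) < pc) && (runif(1) < ps)
          }
        }
        p_fail <- min(0.98, max(0.02, params$background_failure_f +
                                  bv_f[[cw]] + pe_f[[cw]] +
                                  season(date)))
        fail <- runif(1) < p_fail
        if (!fail && length(lethals)) {
          for (k in seq_along(lethals)) {
            if (hom[k] && lethals[[k]]$acts_at == "conception" &&
                  runif(1) < lethals[[k]]$penetrance) fail <- TRUE
          }
        }
        if (!fail) { conceived <- TRUE; break }
        date <- date + sample(18:24, 1L)
      }
      if (!conceived) break
      calv_date <- date + sample(278:284, 1L)
      calf_no <- calf_no + 1L
      calf_id <- sprintf("CALF%06d", calf_no)
      calf_sex <- sample(c("M", "F"), 1L)
      outcome <- if (runif(1) < params$abortion_rate) {
        "abortion"
      } else {
        sb <- FALSE
        for (k in seq_along(lethals)) {
          if (hom[k] && lethals[[k]]$acts_at == "birth" &&
                runif(1) < lethals[[k]]$penetrance) sb <- TRUE
        }
        if (!sb) {
          base <- if (lact == 0L) params$baseline_stillbirth_heifer else
            params$baseline_stillbirth_later
          u_calf <- (bv_u_sb[[cw]] + bv_u_sb[[sire]]) / 2 +
            rnorm(1, 0, sqrt(params$sb_varcomp[["u"]] / 2))
          p_sb <- min(0.98, max(0.005, base + bv_m[[cw]] + u_calf +
                                  pe_sb[[cw]] +
                                  (calf_sex == "M") *
                                    params$sex_effect_sb +
                                  season(calv_date)))
          sb <- runif(1) < p_sb
        }
        if (sb) sample(c("stillborn", "died_during_calving",
                         "died_within_24h"), 1L,
                       prob = c(0.6, 0.25, 0.15)) else "live"
      }
      cavs[[length(cavs) + 1L]] <- data.table(
        dam = cw, sire = sire, calf = calf_id, date = calv_date,
        parity = lact, calf_sex = calf_sex, outcome = outcome,
        twin = runif(1) < params$twin_rate, herd = herd)
      date <- calv_date + round(runif(1, 55, 95))
    }
  }
  list(calvings = rbindlist(cavs), inseminations = rbindlist(inss),
       truth = list(bv_maternal_sb = bv_m, bv_direct_sb = bv_u_sb,
                    bv_fertility = bv_f, pe_sb = pe_sb,
                    pe_fertility = pe_f, herd = herd_of))
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates a pedigree, phased genotypes (with one embedded
#' conception-acting lethal at 5% on chromosome 1) and record tables, and
#' writes them in the package's file dialects plus a YAML run config.
#' `tiny` stays under 200 individuals on 2 chromosomes; `desk` produces a
#' population with roughly 5,000 genotyped animals and runs the full
#' pipeline in minutes.
#'
#' @param preset `"tiny"` or `"desk"`
#' @param seed master seed
#' @param dir output directory (created if needed)
#' @return invisibly, the named list of file paths
#' @export
make_fixture_bundle <- function(preset = c("tiny", "desk"), seed = 1L,
                                dir = ".") {
  preset <- match.arg(preset)
  params <- fixture_params(preset, seed)
  lethals <- list(lethal_spec("1", window_start = 26L,
                              window_length = 25L,
                              target_frequency = 0.05,
                              acts_at = "conception"))
  ped <- simulate_pedigree(params)
  pg <- simulate_genotypes(ped, params, lethals)
  ph <- simulate_phenotypes(ped, pg, lethals, params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genotypes = file.path(dir, "genotypes.tsv"),
    pedigree = file.path(dir, "pedigree.csv"),
    calvings = file.path(dir, "calvings.csv"),
    inseminations = file.path(dir, "inseminations.csv"),
    config = file.path(dir, "config.yaml"))
  write_hapmatrix(pg, paths$genotypes)
  write_pedigree(ped, paths$pedigree)
  fwrite(ph$calvings, paths$calvings, quote = FALSE)
  fwrite(ph$inseminations, paths$inseminations, quote = FALSE)
  yaml::write_yaml(list(preset = preset, seed = seed,
                        window_length = 25L, min_frequency = 0.05,
                        lethal = list(chromosome = "1",
                                      window_start = 26L,
                                      window_length = 25L,
                                      target_frequency = 0.05,
                                      acts_at = "conception")),
                   paths$config)
  invisible(paths)
}

fixture_params <- function(preset, seed) {
  switch(preset,
         tiny = sim_params(n_founders = 60L, n_generations = 2L,
                           sires_per_generation = 4L,
                           offspring_per_sire = 15L,
                           n_chromosomes = 2L,
                           markers_per_chromosome = 75L,
                           founder_pool_size = 20L, n_herds = 6L,
                           seed = seed),
         desk = sim_params(n_founders = 600L, n_generations = 5L,
                           sires_per_generation = 30L,
                           offspring_per_sire = 32L,
                           n_chromosomes = 5L,
                           markers_per_chromosome = 150L,
                           founder_pool_size = 40L, n_herds = 50L,
                           seed = seed))
}
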