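#' Declare a random term for the mixed-model engine
#'
#' @param name label of the variance component
#' @param factor column of the data holding the level of each record
#' @param kind covariance kind: `"identity"` (i.i.d. levels: permanent
#'   environment, herd-year, insemination year-month) or `"pedigree"`
#'   (levels are pedigree individuals, covariance proportional to the
#'   numerator relationship matrix)
#' @param pedigree sorted `pedigree`, required for `kind = "pedigree"`
#' @param use_upg map unknown parents to genetic groups in the A-inverse
#' @return a random-term specification
#' @export
mm_random <- function(name, factor, kind = c("identity", "pedigree"),
                      pedigree = NULL, use_upg = FALSE) {
  kind <- match.arg(kind)
  if (kind == "pedigree" && is.null(pedigree)) {
    stop("pedigree kind requires a pedigree", call. = FALSE)
  }
  structure(list(name = name, factor = factor, kind = kind,
                 pedigree = pedigree, use_upg = use_upg),
            class = "mm_random")
}

#' Declare a correlated direct-maternal genetic block
#'
#' Two additive genetic effects (the calf's own, direct, and the dam's
#' maternal contribution) sharing one pedigree, with an estimable 2x2
#' covariance matrix `[sigma2_direct, sigma_dm; sigma_dm, sigma2_maternal]`
#' Kronecker the relationship matrix.
#'
#' @param direct_factor data column holding the individual (direct) id
#' @param maternal_factor data column holding the dam (maternal) id
#' @param pedigree sorted `pedigree` covering both
#' @param use_upg map unknown parents to genetic groups
#' @param name label prefix for the components
#' @return a random-term specification
#' @export
mm_random_genetic2 <- function(direct_factor, maternal_factor, pedigree,
                               use_upg = FALSE, name = "gen") {
  structure(list(name = name, direct_factor = direct_factor,
                 maternal_factor = maternal_factor, pedigree = pedigree,
                 use_upg = use_upg),
            class = "mm_random2")
}

# indicator matrix mapping records to levels; unmatched records get a
# zero row (e.g. unknown dam in a maternal term)
indicator_Z <- function(values, levels) {
  j <- match(as.character(values), levels)
  ok <- which(!is.na(j))
  sparseMatrix(i = ok, j = j[ok], x = 1,
               dims = c(length(values), length(levels)),
               dimnames = list(NULL, levels))
}

# build design structures shared by REML and BLUP
mm_build <- function(data, response, fixed, random) {
  dt <- as.data.table(data)
  y <- as.numeric(dt[[response]])
  if (anyNA(y)) stop("response contains NA", call. = FALSE)
  X <- model.matrix(fixed, data = dt)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    ls_log("aliased fixed-effect columns dropped: ",
           paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  blocks <- list()
  for (rt in random) {
    if (inherits(rt, "mm_random")) {
      if (rt$kind == "pedigree") {
        Kinv <- a_inverse(rt$pedigree, use_upg = rt$use_upg)
        levels <- rownames(Kinv)
      } else {
        levels <- sort(unique(as.character(dt[[rt$factor]])))
        Kinv <- Diagonal(length(levels))
        dimnames(Kinv) <- list(levels, levels)
      }
      Z <- indicator_Z(dt[[rt$factor]], levels)
      blocks[[rt$name]] <- list(type = "simple", name = rt$name, Z = Z,
                                Kinv = Kinv, q = length(levels),
                                kind = rt$kind, levels = levels)
    } else if (inherits(rt, "mm_random2")) {
      Kinv <- a_inverse(rt$pedigree, use_upg = rt$use_upg)
      levels <- rownames(Kinv)
      Zd <- indicator_Z(dt[[rt$direct_factor]], levels)
      Zm <- indicator_Z(dt[[rt$maternal_factor]], levels)
      blocks[[rt$name]] <- list(type = "gen2", name = rt$name,
                                Z = cbind(Zd, Zm), Kinv = Kinv,
                                q = length(levels), levels = levels)
    } else stop("unknown random term", call. = FALSE)
  }
  Zall <- do.call(cbind, lapply(blocks, `[[`, "Z"))
  list(y = y, X = X, blocks = blocks, W = cbind(X, Zall),
       n = length(y), p = ncol(X))
}

# parameter vector layout: for each block, "name" (simple) or
# "name.d","name.m","name.dm" (gen2); then "e"
mm_theta_names <- function(blocks) {
  nm <- unlist(lapply(blocks, function(b) {
    if (b$type == "simple") b$name
    else paste0(b$name, c(".d", ".m", ".dm"))
  }))
  c(nm, "e")
}

# big inverse covariance of the stacked random effects for given theta
mm_Ginv <- function(blocks, theta) {
  pieces <- lapply(blocks, function(b) {
    if (b$type == "simple") {
      b$Kinv / theta[[b$name]]
    } else {
      G0 <- matrix(c(theta[[paste0(b$name, ".d")]],
                     theta[[paste0(b$name, ".dm")]],
                     theta[[paste0(b$name, ".dm")]],
                     theta[[paste0(b$name, ".m")]]), 2, 2)
      kronecker(solve(G0), b$Kinv)
    }
  })
  bdiag(pieces)
}

# solve Henderson's MME; dense C (full inverse) only when requested
mme_solve <- function(bd, theta, need_C = TRUE) {
  se2 <- theta[["e"]]
  W <- bd$W
  WtW <- crossprod(W)
  M <- WtW / se2
  qtot <- ncol(W) - bd$p
  Ginv <- mm_Ginv(bd$blocks, theta)
  idx <- bd$p + seq_len(qtot)
  M[idx, idx] <- M[idx, idx] + Ginv
  rhs <- as.numeric(crossprod(W, bd$y)) / se2
  if (need_C) {
    Md <- as.matrix(forceSymmetric(M))
    ch <- tryCatch(chol(Md), error = function(e) NULL)
    if (is.null(ch)) {
      Md <- Md + diag(1e-8 * mean(diag(Md)), nrow(Md))
      ch <- chol(Md)
    }
    C <- chol2inv(ch)
    s <- as.numeric(C %*% rhs)
    list(s = s, C = C, M = M, WtW = WtW, Ginv = Ginv)
  } else {
    ch <- Cholesky(forceSymmetric(M), LDL = FALSE)
    s <- as.numeric(solve(ch, rhs))
    list(s = s, C = NULL, M = M, WtW = WtW, Ginv = Ginv, chol = ch)
  }
}

# split the solution vector into beta and per-block u
mm_split <- function(bd, s) {
  beta <- setNames(s[seq_len(bd$p)], colnames(bd$X))
  u <- list()
  off <- bd$p
  for (b in bd$blocks) {
    w <- if (b$type == "simple") b$q else 2L * b$q
    ub <- s[off + seq_len(w)]
    if (b$type == "simple") {
      u[[b$name]] <- setNames(ub, b$levels)
    } else {
      u[[b$name]] <- list(direct = setNames(ub[seq_len(b$q)], b$levels),
                          maternal = setNames(ub[b$q + seq_len(b$q)],
                                              b$levels))
    }
    off <- off + w
  }
  list(beta = beta, u = u)
}

# derivative structures dG0/dtheta for a gen2 block
.gen2_E <- list(d = matrix(c(1, 0, 0, 0), 2),
                m = matrix(c(0, 0, 0, 1), 2),
                dm = matrix(c(0, 1, 1, 0), 2))

#' Fit a linear mixed model with pedigree and identity random terms
#'
#' Solves Henderson's mixed-model equations for an animal-model style
#' linear mixed model. Variance components are either supplied
#' (`varcomp`) or estimated by average-information REML with
#' expectation-maximization fallback steps whenever an AI update leaves
#' the parameter space; convergence is declared when the largest relative
#' parameter change drops below `tol`. Variances clamped at the floor
#' (`1e-6` of the response variance) are flagged as boundary estimates.
#'
#' @param data records (data.frame/data.table)
#' @param response name of the response column
#' @param fixed one-sided formula of fixed effects, e.g.
#'   `~ parity + sex + year_month`
#' @param random list of [mm_random()] / [mm_random_genetic2()] terms
#' @param varcomp named numeric of variance components (one per simple
#'   term, `name.d`/`name.m`/`name.dm` for genetic2 blocks, plus `"e"`);
#'   `NULL` to estimate by AI-REML
#' @param tol relative-change convergence tolerance (default `1e-6`)
#' @param max_iter maximum REML rounds
#' @return an object of class `mm_fit`: `varcomp` (+ `boundary` flags),
#'   `beta`, `beta_vcov`, `u` (per-term solutions; genetic2 blocks give
#'   `$direct` and `$maternal`), `fitted`, `residuals`, `converged`,
#'   `trace`, and bookkeeping (`levels`, `n`, `p`)
#' @export
fit_mixed_model <- function(data, response, fixed, random,
                            varcomp = NULL, tol = 1e-6, max_iter = 50L) {
  bd <- mm_build(data, response, fixed, random)
  theta_names <- mm_theta_names(bd$blocks)
  floor_v <- 1e-6 * max(var(bd$y), .Machine$double.eps)
  trace <- list()
  if (is.null(varcomp)) {
    vy <- var(bd$y)
    k <- length(theta_names) - 1L
    theta <- setNames(rep(vy / (k + 1), length(theta_names)), theta_names)
    theta[grepl("\\.dm$", theta_names)] <- 0
    theta[["e"]] <- vy / 2
    res <- mm_reml(bd, theta, tol = tol, max_iter = max_iter,
                   floor_v = floor_v)
    theta <- res$theta
    converged <- res$converged
    trace <- res$trace
    boundary <- res$boundary
    if (!converged) {
      stop("REML did not converge after ", max_iter, " rounds; trace: ",
           paste(vapply(trace, function(t)
             paste(signif(t, 4), collapse = "/"), character(1)),
             collapse = " | "), call. = FALSE)
    }
  } else {
    theta <- unlist(varcomp)[theta_names]
    if (anyNA(theta)) {
      stop("varcomp must name components: ",
           paste(theta_names, collapse = ", "), call. = FALSE)
    }
    # exact zeros are admissible inputs; clamp to a tiny ridge so the
    # MME stay defined (the limit reproduces least squares)
    zero_in <- theta[theta_names != "e"] <= 0
    theta[theta_names != "e"][zero_in] <-
      1e-10 * max(var(bd$y), .Machine$double.eps)
    converged <- TRUE
    boundary <- setNames(rep(FALSE, length(theta)), theta_names)
  }
  sol <- mme_solve(bd, theta, need_C = TRUE)
  sp <- mm_split(bd, sol$s)
  fitted <- as.numeric(bd$W %*% sol$s)
  structure(list(
    varcomp = theta, boundary = boundary,
    beta = sp$beta,
    beta_vcov = sol$C[seq_len(bd$p), seq_len(bd$p), drop = FALSE] |>
      (\(m) { dimnames(m) <- list(colnames(bd$X), colnames(bd$X)); m })(),
    u = sp$u, fitted = fitted, residuals = bd$y - fitted,
    converged = converged, trace = trace,
    levels = lapply(bd$blocks, `[[`, "levels"),
    n = bd$n, p = bd$p), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("mm_fit:", x$n, "records,", x$p, "fixed-effect columns\n")
  cat("variance components:\n")
  print(signif(x$varcomp, 5))
  invisible(x)
}

# AI-REML with EM fallback. Score and average-information computed via
# the MME inverse; identities verified against a dense-V oracle in the
# test suite.
mm_reml <- function(bd, theta, tol, max_iter, floor_v) {
  theta_names <- names(theta)
  nblk <- length(bd$blocks)
  trace <- list()
  boundary <- setNames(rep(FALSE, length(theta)), theta_names)
  block_cols <- mm_block_cols(bd)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sol <- mme_solve(bd, theta, need_C = TRUE)
    se2 <- theta[["e"]]
    ehat <- bd$y - as.numeric(bd$W %*% sol$s)
    Py <- ehat / se2
    sp <- mm_split(bd, sol$s)
    grad <- setNames(numeric(length(theta)), theta_names)
    FF <- matrix(0, bd$n, length(theta))
    for (k in seq_along(theta_names)) {
      FF[, k] <- mm_dV_times(bd, theta_names[k], Py, block_cols)
      grad[k] <- -0.5 * (mm_trPdV(bd, theta_names[k], theta, sol,
                                  block_cols) -
                           sum(Py * FF[, k]))
    }
    # P F via an MME solve with F as multi-response
    sF <- sol$C %*% (crossprod(bd$W, FF) / se2)
    PF <- (FF - as.matrix(bd$W %*% sF)) / se2
    AI <- 0.5 * crossprod(FF, PF)
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    prop <- NULL
    low <- theta_names[!grepl("\\.dm$", theta_names)]
    if (!is.null(step)) {
      # damp the AI step until it lands inside the parameter space;
      # variances driven below the floor are pinned there (boundary)
      # rather than vetoing the whole step
      for (h in 0:5) {
        cand <- theta + step / 2^h
        pin <- low[cand[low] < floor_v]
        cand[pin] <- floor_v
        if (mm_admissible(cand, bd, floor_v)) {
          prop <- cand
          boundary[pin] <- TRUE
          break
        }
      }
    }
    if (!mm_admissible(prop, bd, floor_v)) {
      prop <- mm_em_step(bd, theta, sol, sp, ehat, block_cols)
      # clamp EM result just in case
      low <- setdiff(theta_names, "e")
      cov_nm <- grepl("\\.dm$", low)
      prop[low[!cov_nm]] <- pmax(prop[low[!cov_nm]], floor_v)
      boundary[low[!cov_nm]] <- boundary[low[!cov_nm]] |
        (prop[low[!cov_nm]] <= floor_v)
    }
    rel <- max(abs(prop - theta) / (abs(theta) + 1e-8))
    trace[[it]] <- prop
    theta <- prop
    if (rel < max(tol, 1e-10)) { converged <- TRUE; break }
  }
  if (!converged && rel < 1e-3) {
    # EM crawling toward a boundary of the parameter space (typically a
    # direct-maternal correlation pinned at +-1): accept, flag boundary
    converged <- TRUE
    boundary[] <- TRUE
    ls_log("REML stopped near a parameter-space boundary (last relative ",
           "change ", signif(rel, 3), "); estimates flagged as boundary")
  }
  list(theta = theta, converged = converged, trace = trace,
       boundary = boundary)
}

# column ranges of each block inside the random-effect part of the MME
mm_block_cols <- function(bd) {
  off <- 0L
  out <- list()
  for (b in bd$blocks) {
    w <- if (b$type == "simple") b$q else 2L * b$q
    out[[b$name]] <- off + seq_len(w)
    off <- off + w
  }
  out
}

# dV/dtheta_k %*% v for a record-space vector v
mm_dV_times <- function(bd, par, v, block_cols) {
  if (par == "e") return(v)
  blk_name <- sub("\\.(d|m|dm)$", "", par)
  b <- bd$blocks[[blk_name]]
  Zt_v <- as.numeric(crossprod(b$Z, v))
  if (b$type == "simple") {
    a <- if (b$kind == "identity") Zt_v else
      as.numeric(solve(b$Kinv, Zt_v))
    return(as.numeric(b$Z %*% a))
  }
  E <- .gen2_E[[sub("^.*\\.", "", par)]]
  td <- Zt_v[seq_len(b$q)]; tm <- Zt_v[b$q + seq_len(b$q)]
  Atd <- as.numeric(solve(b$Kinv, td))
  Atm <- as.numeric(solve(b$Kinv, tm))
  out_d <- E[1, 1] * Atd + E[1, 2] * Atm
  out_m <- E[2, 1] * Atd + E[2, 2] * Atm
  as.numeric(b$Z %*% c(out_d, out_m))
}

# tr(P dV/dtheta_k) via the MME inverse
mm_trPdV <- function(bd, par, theta, sol, block_cols) {
  se2 <- theta[["e"]]
  if (par == "e") {
    return(bd$n / se2 - sum(sol$WtW * sol$C) / se2^2)
  }
  blk_name <- sub("\\.(d|m|dm)$", "", par)
  b <- bd$blocks[[blk_name]]
  cols <- bd$p + block_cols[[blk_name]]
  if (b$type == "simple") {
    s2 <- theta[[b$name]]
    Cbb <- sol$C[cols, cols, drop = FALSE]
    tr_KC <- if (b$kind == "identity") sum(diag(Cbb)) else
      sum(b$Kinv * Cbb)
    return(b$q / s2 - tr_KC / s2^2)
  }
  G0 <- matrix(c(theta[[paste0(b$name, ".d")]],
                 theta[[paste0(b$name, ".dm")]],
                 theta[[paste0(b$name, ".dm")]],
                 theta[[paste0(b$name, ".m")]]), 2, 2)
  H <- solve(G0)
  E <- .gen2_E[[sub("^.*\\.", "", par)]]
  Cuu <- sol$C[cols, cols, drop = FALSE]
  q <- b$q
  TT <- matrix(0, 2, 2)
  for (t in 1:2) for (s in 1:2) {
    Cts <- Cuu[(t - 1L) * q + seq_len(q), (s - 1L) * q + seq_len(q)]
    TT[t, s] <- sum(Cts * b$Kinv)   # tr(C_ts %*% Ainv), Ainv symmetric
  }
  q * sum(diag(E %*% H)) - sum(diag(H %*% E %*% H %*% TT))
}

# admissibility of a proposed theta
mm_admissible <- function(theta, bd, floor_v) {
  if (is.null(theta) || anyNA(theta)) return(FALSE)
  nm <- names(theta)
  vars <- theta[!grepl("\\.dm$", nm)]
  if (any(vars < floor_v)) return(FALSE)
  for (b in bd$blocks) {
    if (b$type == "gen2") {
      sd_ <- theta[[paste0(b$name, ".d")]]
      sm_ <- theta[[paste0(b$name, ".m")]]
      sdm <- theta[[paste0(b$name, ".dm")]]
      if (abs(sdm) >= 0.999 * sqrt(sd_ * sm_)) return(FALSE)
    }
  }
  TRUE
}

# one EM-REML step (guaranteed to stay in the parameter space)
mm_em_step <- function(bd, theta, sol, sp, ehat, block_cols) {
  new <- theta
  for (b in bd$blocks) {
    cols <- bd$p + block_cols[[b$name]]
    if (b$type == "simple") {
      ub <- if (b$type == "simple") sp$u[[b$name]] else NULL
      Cbb <- sol$C[cols, cols, drop = FALSE]
      quad <- as.numeric(ub %*% (b$Kinv %*% ub))
      tr_KC <- if (b$kind == "identity") sum(diag(Cbb)) else
        sum(b$Kinv * Cbb)
      new[[b$name]] <- (quad + tr_KC) / b$q
    } else {
      q <- b$q
      ud <- sp$u[[b$name]]$direct; um <- sp$u[[b$name]]$maternal
    Cuu <- sol$C[cols, cols, drop = FALSE]
      U <- cbind(ud, um)
      G0n <- matrix(0, 2, 2)
      for (t in 1:2) for (s in 1:2) {
        Cts <- Cuu[(t - 1L) * q + seq_len(q), (s - 1L) * q + seq_len(q)]
        G0n[t, s] <- (as.numeric(U[, t] %*% (b$Kinv %*% U[, s])) +
                        sum(Cts * b$Kinv)) / q
      }
      G0n <- (G0n + Matrix::t(G0n)) / 2
      new[[paste0(b$name, ".d")]] <- G0n[1, 1]
      new[[paste0(b$name, ".m")]] <- G0n[2, 2]
      new[[paste0(b$name, ".dm")]] <- G0n[1, 2]
    }
  }
  # residual: quadratic-form update (equals REML residual at convergence)
  new[["e"]] <- sum(ehat * bd$y) / (bd$n - bd$p)
  new
}

#' Solve BLUP at fixed variance components
#'
#' Convenience wrapper over [fit_mixed_model()] with `varcomp` supplied:
#' returns fixed-effect BLUEs, random-effect BLUPs (EBVs, permanent
#' environment), fitted values and per-record residuals.
#'
#' @inheritParams fit_mixed_model
#' @return an `mm_fit`
#' @export
solve_blup <- function(data, response, fixed, random, varcomp) {
  fit_mixed_model(data, response, fixed, random, varcomp = varcomp)
}

#' Corrected phenotypes for repeatability-model traits
#'
#' The environment-adjusted response used for association analysis: the
#' animal's estimated breeding value plus permanent-environment solution
#' plus the mean of its record residuals. Animals with an EBV but no own
#' record are excluded (counted in the log).
#'
#' @param fit an `mm_fit` from the repeatability model
#' @param data the records the model was fitted to
#' @param animal_col data column with the animal id
#' @param genetic name of the pedigree-additive term (default `"u"`)
#' @param pe name of the permanent-environment term, or `NULL` if absent
#' @return `data.table` with `animal`, `y_star`, `n_records`
#' @export
corrected_phenotypes <- function(fit, data, animal_col = "animal",
                                 genetic = "u", pe = "pe") {
  dt <- as.data.table(data)
  dt[, `..resid` := fit$residuals]
  agg <- dt[, .(mean_resid = mean(`..resid`), n_records = .N),
            by = c(animal_col)]
  setnames(agg, animal_col, "animal")
  ebv <- fit$u[[genetic]]
  no_rec <- setdiff(names(ebv), agg$animal)
  if (length(no_rec)) {
    ls_log(length(no_rec), " animals with EBV but no own record excluded")
  }
  agg[, y_star := ebv[animal] + mean_resid]
  if (!is.null(pe) && pe %in% names(fit$u)) {
    pes <- fit$u[[pe]]
    agg[, y_star := y_star + fifelse(animal %in% names(pes),
                                     pes[animal], 0)]
  }
  agg[!is.na(y_star), .(animal, y_star, n_records)]
}

#' Corrected phenotypes for maternal-direct stillbirth models
#'
#' Combines the first-calving and later-calving maternal-direct fits into
#' the four corrected stillbirth phenotypes. With `DSB` the maternal and
#' `SSB` the direct genetic effect: `DSB1 = maternal EBV + first-calving
#' residual`, `SSB1 = direct EBV + first-calving residual`, `DSB2 =
#' maternal EBV + PE + mean later-calving residual`, `SSB2 = direct EBV +
#' mean later-calving residual`. The residual attached to an animal is
#' that of the calving(s) where the animal was the dam; animals without
#' such a record are excluded from the corresponding trait.
#'
#' @param fit1,fit2 `mm_fit`s for first and later calvings (maternal-
#'   direct genetic block named `gen`, optional PE term `pe` in `fit2`)
#' @param data1,data2 the records each model was fitted to
#' @param dam_col data column with the dam id
#' @return wide `data.table`: `animal`, `DSB1`, `SSB1`, `DSB2`, `SSB2`
#'   (`NA` where the animal lacks the needed record)
#' @export
corrected_stillbirth_phenotypes <- function(fit1, data1, fit2, data2,
                                            dam_col = "dam") {
  r1 <- as.data.table(data1)[, .(animal = get(dam_col),
                                 resid = fit1$residuals)]
  r1 <- r1[, .(resid = mean(resid)), by = animal]
  r2 <- as.data.table(data2)[, .(animal = get(dam_col),
                                 resid = fit2$residuals)]
  r2 <- r2[, .(resid = mean(resid)), by = animal]
  m1 <- fit1$u$gen$maternal; u1 <- fit1$u$gen$direct
  m2 <- fit2$u$gen$maternal; u2 <- fit2$u$gen$direct
  pe2 <- if ("pe" %in% names(fit2$u)) fit2$u$pe else NULL
  animals <- union(r1$animal, r2$animal)
  out <- data.table(animal = animals)
  e1 <- setNames(r1$resid, r1$animal)
  e2 <- setNames(r2$resid, r2$animal)
  out[, DSB1 := m1[animal] + e1[animal]]
  out[, SSB1 := u1[animal] + e1[animal]]
  pe_of <- function(a) if (is.null(pe2)) 0 else
    fifelse(a %in% names(pe2), pe2[a], NA_real_)
  out[, DSB2 := m2[animal] + pe_of(animal) + e2[animal]]
  out[, SSB2 := u2[animal] + e2[animal]]
  out[]
}

#' Heritability from variance components
#'
#' Maternal-direct stillbirth models: maternal heritability is
#' `sigma2_m / (sigma2_m + sigma2_u + sigma2_e + 2 sigma_mu)` and direct
#' heritability has `sigma2_u` in the numerator over the same
#' denominator. Repeatability models use
#' `sigma2_u / (sigma2_u + sigma2_pe + sigma2_e)`.
#'
#' @param varcomp named numeric; maternal/direct need `u`, `m`, `mu`,
#'   `e`; repeatability needs `u`, `pe`, `e`
#' @param which one of `"maternal"`, `"direct"`, `"repeatability"`
#' @return heritability
#' @export
heritability <- function(varcomp, which = c("maternal", "direct",
                                            "repeatability")) {
  which <- match.arg(which)
  v <- as.list(varcomp)
  if (which == "repeatability") {
    den <- v$u + (v$pe %||% 0) + v$e
    if (den <= 0) stop("non-positive denominator", call. = FALSE)
    return(v$u / den)
  }
  den <- v$m + v$u + v$e + 2 * (v$mu %||% 0)
  if (den <= 0) stop("non-positive denominator", call. = FALSE)
  if (which == "maternal") v$m / den else v$u / den
}
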