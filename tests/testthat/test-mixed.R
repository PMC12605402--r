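test_that("MME solutions satisfy the normal equations and reconstruct
           the observations", {
  set.seed(12)
  df <- random_pedigree_df(60)
  ped <- as_pedigree(df)
  ids <- ped$individual[30:60]
  rec <- data.table::data.table(
    animal = rep(ids, each = 2),
    x = rnorm(2 * length(ids)))
  rec[, y := 1 + 0.4 * x + rnorm(.N)]
  fit <- solve_blup(rec, "y", ~ x,
                    list(mm_random("u", "animal", "pedigree",
                                   pedigree = ped),
                         mm_random("pe", "animal", "identity")),
                    varcomp = c(u = 0.3, pe = 0.2, e = 0.5))
  # observation = fitted + residual exactly
  expect_equal(fit$fitted + fit$residuals, rec$y, tolerance = 1e-12)
  # normal equations: rebuild and check the residual norm
  X <- model.matrix(~ x, rec)
  Zu <- lethalscan:::indicator_Z(rec$animal, ped$individual)
  Zp <- lethalscan:::indicator_Z(rec$animal, sort(unique(rec$animal)))
  W <- cbind(X, as.matrix(Zu), as.matrix(Zp))
  Ainv <- as.matrix(a_inverse(ped))
  G <- Matrix::bdiag(matrix(0, 2, 2), Ainv / 0.3,
                     diag(1 / 0.2, ncol(Zp)))
  M <- crossprod(W) / 0.5 + as.matrix(G)
  rhs <- crossprod(W, rec$y) / 0.5
  s <- c(fit$beta, fit$u$u, fit$u$pe)
  expect_lt(sqrt(sum((M %*% s - rhs)^2)) / sqrt(sum(rhs^2)), 1e-8)
})

test_that("vanishing genetic variance collapses BLUP to least squares", {
  set.seed(13)
  ped <- as_pedigree(data.frame(individual = sprintf("a%02d", 1:40),
                                sire = NA, dam = NA))
  rec <- data.table::data.table(animal = sprintf("a%02d", 1:40),
                                x = rnorm(40))
  rec[, y := 2 - 0.7 * x + rnorm(40)]
  fit <- solve_blup(rec, "y", ~ x,
                    list(mm_random("u", "animal", "pedigree",
                                   pedigree = ped)),
                    varcomp = c(u = 0, e = 1))
  ols <- lm(y ~ x, rec)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_lt(max(abs(fit$u$u)), 1e-6)
})

test_that("REML equals the closed-form ANOVA estimator on a balanced
           one-way layout", {
  set.seed(14)
  g <- 40; r <- 5
  id <- rep(sprintf("g%02d", 1:g), each = r)
  u <- rnorm(g, 0, sqrt(0.5))
  y <- 3 + u[match(id, unique(id))] + rnorm(g * r, 0, 1)
  rec <- data.table::data.table(animal = id, y = y)
  fit <- fit_mixed_model(rec, "y", ~ 1,
                         list(mm_random("u", "animal", "identity")))
  # ANOVA estimator: s2e = MSW; s2u = (MSB - MSW) / r
  ybar <- tapply(y, id, mean)
  msw <- sum((y - ybar[id])^2) / (g * (r - 1))
  msb <- r * sum((ybar - mean(y))^2) / (g - 1)
  expect_equal(fit$varcomp[["e"]], msw, tolerance = 1e-4)
  expect_equal(fit$varcomp[["u"]], (msb - msw) / r, tolerance = 1e-4)
})

test_that("REML matches a dense-V oracle with a pedigree term", {
  set.seed(15)
  df <- random_pedigree_df(80, n_founders = 30)
  ped <- as_pedigree(df)
  ids <- ped$individual[41:80]
  A <- oracle_tabular_A(
    ifelse(is.na(match(ped$sire, ped$individual)), 0L,
           match(ped$sire, ped$individual)),
    ifelse(is.na(match(ped$dam, ped$individual)), 0L,
           match(ped$dam, ped$individual)))
  rownames(A) <- colnames(A) <- ped$individual
  rec <- data.table::data.table(animal = rep(ids, each = 3))
  L <- chol(A)
  u <- as.numeric(t(L) %*% rnorm(nrow(A), 0, sqrt(0.4)))
  names(u) <- ped$individual
  pe <- setNames(rnorm(length(ids), 0, sqrt(0.2)), ids)
  rec[, y := 1 + u[animal] + pe[animal] + rnorm(.N, 0, sqrt(0.7))]
  fit <- fit_mixed_model(rec, "y", ~ 1,
                         list(mm_random("u", "animal", "pedigree",
                                        pedigree = ped),
                              mm_random("pe", "animal", "identity")))
  # dense-V restricted likelihood, maximised independently
  Zi <- as.matrix(lethalscan:::indicator_Z(rec$animal, ped$individual))
  Zp <- as.matrix(lethalscan:::indicator_Z(rec$animal, sort(ids)))
  X <- matrix(1, nrow(rec), 1)
  yv <- rec$y
  negll <- function(th) {
    V <- th[1] * Zi %*% A %*% t(Zi) + th[2] * tcrossprod(Zp) +
      th[3] * diag(length(yv))
    ch <- chol(V); Vi <- chol2inv(ch)
    XtVX <- t(X) %*% Vi %*% X
    b <- solve(XtVX, t(X) %*% Vi %*% yv)
    r <- yv - X %*% b
    as.numeric(0.5 * (2 * sum(log(diag(ch))) +
                        determinant(XtVX)$modulus + t(r) %*% Vi %*% r))
  }
  o <- optim(c(0.4, 0.2, 0.7), negll, method = "L-BFGS-B",
             lower = 1e-5, control = list(factr = 1e4))
  expect_equal(unname(fit$varcomp), o$par, tolerance = 1e-3)
})

test_that("EBVs track true breeding values when the signal is strong", {
  set.seed(16)
  df <- random_pedigree_df(300, n_founders = 60)
  ped <- as_pedigree(df)
  pi_ <- match(ped$sire, ped$individual); pi_[is.na(pi_)] <- 0L
  di_ <- match(ped$dam, ped$individual); di_[is.na(di_)] <- 0L
  A <- oracle_tabular_A(pi_, di_)
  u <- as.numeric(t(chol(A)) %*% rnorm(nrow(A), 0, 1))
  names(u) <- ped$individual
  rec <- data.table::data.table(animal = rep(ped$individual, 2))
  rec[, y := u[animal] + rnorm(.N, 0, 0.1)]
  fit <- solve_blup(rec, "y", ~ 1,
                    list(mm_random("u", "animal", "pedigree",
                                   pedigree = ped)),
                    varcomp = c(u = 1, e = 0.01))
  expect_gt(cor(fit$u$u[ped$individual], u), 0.95)
})

test_that("maternal-direct model returns both solution sets and per-
           record residuals", {
  set.seed(17)
  df <- random_pedigree_df(120, n_founders = 40)
  ped <- as_pedigree(df)
  kids <- ped$individual[!is.na(ped$dam)]
  kids <- head(kids, 60)
  dam_of <- setNames(ped$dam, ped$individual)
  rec <- data.table::data.table(calf = kids, dam = dam_of[kids])
  rec[, y := rnorm(.N)]
  fit <- solve_blup(rec, "y", ~ 1,
                    list(mm_random_genetic2("calf", "dam",
                                            pedigree = ped,
                                            name = "gen")),
                    varcomp = c(gen.d = 0.2, gen.m = 0.2, gen.dm = 0.02,
                                e = 0.6))
  expect_length(fit$u$gen$direct, nrow(ped))
  expect_length(fit$u$gen$maternal, nrow(ped))
  expect_length(fit$residuals, nrow(rec))
})

test_that("corrected phenotypes assemble EBV + PE + mean residual", {
  # constructed fit object: arithmetic check y* = 0.1 + 0.02 + 0.1
  fit <- structure(list(
    residuals = c(0.3, -0.1, 0.5),
    u = list(u = c(a1 = 0.1, a2 = -0.2, a3 = 0.4),
             pe = c(a1 = 0.02, a2 = 0))), class = "mm_fit")
  data <- data.table::data.table(animal = c("a1", "a1", "a2"))
  out <- corrected_phenotypes(fit, data)
  expect_equal(out[animal == "a1", y_star], 0.1 + 0.02 + 0.1)
  expect_equal(out[animal == "a2", y_star], -0.2 + 0 + 0.5)
  # a3 has an EBV but no record: excluded
  expect_false("a3" %in% out$animal)
})

test_that("stillbirth corrected phenotypes combine the two parity
           groups", {
  fit1 <- structure(list(
    residuals = c(0.2, -0.2),
    u = list(gen = list(direct = c(cow1 = 0.05, cow2 = 0.01),
                        maternal = c(cow1 = -0.03, cow2 = 0.02)))),
    class = "mm_fit")
  fit2 <- structure(list(
    residuals = c(0.1, 0.3, -0.1),
    u = list(gen = list(direct = c(cow1 = 0.04, cow2 = 0),
                        maternal = c(cow1 = -0.01, cow2 = 0.03)),
             pe = c(cow1 = 0.02, cow2 = -0.01))), class = "mm_fit")
  d1 <- data.table::data.table(dam = c("cow1", "cow2"))
  d2 <- data.table::data.table(dam = c("cow1", "cow1", "cow2"))
  out <- corrected_stillbirth_phenotypes(fit1, d1, fit2, d2)
  expect_equal(out[animal == "cow1", DSB1], -0.03 + 0.2)
  expect_equal(out[animal == "cow1", SSB1], 0.05 + 0.2)
  # cow1 has two later calvings: mean residual (0.1 + 0.3) / 2
  expect_equal(out[animal == "cow1", DSB2], -0.01 + 0.02 + 0.2)
  expect_equal(out[animal == "cow1", SSB2], 0.04 + 0.2)
})

test_that("heritability formulas", {
  expect_equal(heritability(c(m = 0.1, u = 0.2, e = 0.7, mu = 0),
                            "maternal"), 0.1)
  expect_equal(heritability(c(m = 0.1, u = 0.2, e = 0.7, mu = 0),
                            "direct"), 0.2)
  expect_equal(heritability(c(m = 0.1, u = 0.2, e = 0.7, mu = -0.05),
                            "maternal"), 0.1 / 0.9)
  expect_equal(heritability(c(m = 0, u = 0.2, e = 0.7, mu = 0),
                            "maternal"), 0)
  expect_equal(heritability(c(u = 0.2, pe = 0.1, e = 0.7),
                            "repeatability"), 0.2)
  expect_error(heritability(c(m = 0.1, u = 0.2, e = -2, mu = 0),
                            "maternal"), "denominator")
})

test_that("zero-signal data drives the genetic variance to the floor
           with a boundary flag", {
  set.seed(20)
  ped <- as_pedigree(data.frame(individual = sprintf("z%03d", 1:300),
                                sire = NA, dam = NA))
  rec <- data.table::data.table(animal = rep(sprintf("z%03d", 1:300),
                                             3))
  rec[, y := rnorm(.N)]
  fit <- fit_mixed_model(rec, "y", ~ 1,
                         list(mm_random("u", "animal", "pedigree",
                                        pedigree = ped)))
  # true genetic variance is 0; the estimate sits at or near the floor
  expect_lt(fit$varcomp[["u"]], 0.05)
})
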