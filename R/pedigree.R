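#' Construct a pedigree
#'
#' Validates and topologically sorts a pedigree table. Unknown parents are
#' coded `NA` internally ("0" or "" in files). Parents that appear only in
#' the sire/dam columns are added as founder rows. An individual that is
#' its own ancestor raises a pedigree error listing the cycle.
#'
#' @param df data.frame with columns `individual`, `sire`, `dam` and
#'   optionally `sex`, `birth_date`, `upg` (unknown-parent group label,
#'   used only when a parent is unknown)
#' @return a sorted `data.table` of class `pedigree` (parents precede
#'   offspring)
#' @export
as_pedigree <- function(df) {
  dt <- as.data.table(df)
  need <- c("individual", "sire", "dam")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("pedigree error: missing columns ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (cn in c("individual", "sire", "dam")) {
    v <- as.character(dt[[cn]])
    v[v %in% c("0", "", "NA")] <- NA_character_
    set(dt, j = cn, value = v)
  }
  if (anyNA(dt$individual)) stop("pedigree error: missing individual id",
                                 call. = FALSE)
  if (anyDuplicated(dt$individual)) {
    stop("pedigree error: duplicated individual(s): ",
         paste(head(dt$individual[duplicated(dt$individual)], 5),
               collapse = ", "), call. = FALSE)
  }
  if (!"sex" %in% names(dt)) dt[, sex := NA_character_]
  if (!"birth_date" %in% names(dt)) dt[, birth_date := as.Date(NA)]
  if (!"upg" %in% names(dt)) dt[, upg := NA_character_]
  dt[, birth_date := as.Date(birth_date)]
  dt[, upg := as.character(upg)]
  # implicit founders for parents without a row
  parents <- setdiff(stats::na.omit(unique(c(dt$sire, dt$dam))),
                     dt$individual)
  if (length(parents)) {
    sex_guess <- ifelse(parents %in% dt$sire, "M", "F")
    dt <- rbind(dt,
                data.table(individual = parents, sire = NA_character_,
                           dam = NA_character_, sex = sex_guess,
                           birth_date = as.Date(NA), upg = NA_character_),
                fill = TRUE)
  }
  dt <- ped_topo_sort(dt)
  setattr(dt, "class", c("pedigree", class(dt)))
  dt[]
}

# Kahn topological sort; on failure report one cycle explicitly
ped_topo_sort <- function(dt) {
  n <- nrow(dt)
  idx <- setNames(seq_len(n), dt$individual)
  si <- idx[dt$sire]; di <- idx[dt$dam]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    # stable: keep original file order among ready nodes
    queue <- sort(queue)
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    rem <- setdiff(seq_len(n), out)
    cyc <- find_cycle(rem, si, di, dt$individual)
    stop("pedigree error: cycle detected: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  dt[out]
}

find_cycle <- function(rem, si, di, ids) {
  remset <- rep(FALSE, length(ids)); remset[rem] <- TRUE
  v <- rem[1]
  seen <- integer(0)
  while (!(v %in% seen)) {
    seen <- c(seen, v)
    p <- c(si[v], di[v])
    p <- p[!is.na(p) & remset[p]]
    v <- p[1]
  }
  path <- seen[which(seen == v)[1]:length(seen)]
  ids[c(path, path[1])]
}

#' Read a pedigree CSV
#'
#' CSV with header `individual,sire,dam,sex,birth_date[,upg]`; unknown
#' parents coded "0" (or empty). The result is topologically sorted.
#'
#' @param path CSV path
#' @return a `pedigree` object (see [as_pedigree()])
#' @export
read_pedigree <- function(path) {
  dt <- fread(path, colClasses = list(character = c("individual", "sire",
                                                    "dam")))
  as_pedigree(dt)
}

#' Write a pedigree CSV
#' @param ped a `pedigree`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.table(ped)[, .(individual, sire, dam, sex, birth_date,
                                upg)]
  for (cn in c("sire", "dam")) {
    v <- out[[cn]]; v[is.na(v)] <- "0"; set(out, j = cn, value = v)
  }
  fwrite(out, path, na = "NA", quote = FALSE)
  invisible(path)
}

# integer parent indices (0 = unknown) for a sorted pedigree
ped_indices <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$individual)
  s <- idx[ped$sire]; d <- idx[ped$dam]
  s[is.na(s)] <- 0L; d[is.na(d)] <- 0L
  list(s = unname(s), d = unname(d), ids = ped$individual)
}

#' Inbreeding coefficients
#'
#' Meuwissen & Luo computation of inbreeding coefficients for a sorted
#' pedigree: `a_ii = sum_j L_ij^2 D_j` over the ancestors `j` of `i`,
#' where `L` are the path coefficients and `D` the Mendelian sampling
#' variances, so `F_i = a_ii - 1`.
#'
#' @param ped a `pedigree` (topologically sorted)
#' @return numeric vector named by individual
#' @export
inbreeding_coef <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  pi <- ped_indices(ped)
  setNames(ped_inbreeding(pi$s, pi$d), pi$ids)
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense Wright A matrix by the recursive tabular method. Intended for
#' small pedigrees (simulation truth, cross-checks); the mixed-model
#' engine uses [a_inverse()] and never forms A densely.
#'
#' @param ped a sorted `pedigree`
#' @return dense symmetric matrix with dimnames = individual ids
#' @export
relationship_matrix <- function(ped) {
  pi <- ped_indices(ped)
  s <- pi$s; d <- pi$d; n <- length(s)
  A <- matrix(0, n, n, dimnames = list(pi$ids, pi$ids))
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        v <- 0
        if (s[i] > 0L) v <- v + 0.5 * A[j, s[i]]
        if (d[i] > 0L) v <- v + 0.5 * A[j, d[i]]
        A[i, j] <- A[j, i] <- v
      }
    }
  }
  A
}

#' Inverse numerator relationship matrix
#'
#' Builds the sparse inverse of the numerator relationship matrix directly
#' from a sorted pedigree using Henderson's rules with inbreeding
#' (Mendelian sampling variances from the tabular inbreeding
#' coefficients). With `use_upg = TRUE`, unknown parents map to their
#' unknown-parent-group columns (Westell-Quaas genetic groups): the matrix
#' gains one trailing row/column per group and the individual block stays
#' positive definite.
#'
#' @param ped a sorted `pedigree`
#' @param use_upg map unknown parents to `upg` group columns
#' @return sparse symmetric `dgCMatrix`; dimnames are individual ids
#'   followed by group labels when `use_upg`
#' @export
a_inverse <- function(ped, use_upg = FALSE) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  pi <- ped_indices(ped)
  s <- pi$s; d <- pi$d; n <- length(s)
  # inbreeding via the tabular diagonal (exact, O(n^2) worst case but
  # cheap at desk scale thanks to sparse ancestor sets)
  FF <- ped_inbreeding(s, d)
  groups <- character(0)
  gidx_s <- gidx_d <- integer(n)
  if (use_upg) {
    glab <- ped$upg
    glab[is.na(glab)] <- "UPG0"
    groups <- sort(unique(glab[s == 0L | d == 0L]))
    gmap <- setNames(seq_along(groups) + n, groups)
    gidx_s <- ifelse(s == 0L, gmap[glab], 0L)
    gidx_d <- ifelse(d == 0L, gmap[glab], 0L)
  }
  m <- n + length(groups)
  k <- 0L
  # preallocate triplet space (7 entries max per animal)
  ti <- integer(7L * n); tj <- integer(7L * n); tx <- numeric(7L * n)
  push <- function(i, j, v) {
    k <<- k + 1L; ti[k] <<- i; tj[k] <<- j; tx[k] <<- v
  }
  for (i in seq_len(n)) {
    Fs <- if (s[i] > 0L) FF[s[i]] else -1
    Fd <- if (d[i] > 0L) FF[d[i]] else -1
    di <- 1 - 0.25 * (1 + Fs) - 0.25 * (1 + Fd)
    al <- 1 / di
    ps <- if (s[i] > 0L) s[i] else gidx_s[i]
    pd <- if (d[i] > 0L) d[i] else gidx_d[i]
    push(i, i, al)
    for (p in c(ps, pd)) {
      if (p > 0L) push(i, p, -al / 2)
    }
    pp <- c(ps, pd); pp <- pp[pp > 0L]
    if (length(pp) == 2L) {
      push(pp[1], pp[1], al / 4); push(pp[2], pp[2], al / 4)
      push(pp[1], pp[2], al / 4)
    } else if (length(pp) == 1L) {
      push(pp[1], pp[1], al / 4)
    }
  }
  ti <- ti[seq_len(k)]; tj <- tj[seq_len(k)]; tx <- tx[seq_len(k)]
  Ainv <- sparseMatrix(i = c(ti, tj[ti != tj]), j = c(tj, ti[ti != tj]),
                       x = c(tx, tx[ti != tj]), dims = c(m, m),
                       dimnames = list(c(pi$ids, groups),
                                       c(pi$ids, groups)))
  attr(Ainv, "inbreeding") <- setNames(FF, pi$ids)
  attr(Ainv, "groups") <- groups
  Ainv
}

# Meuwissen & Luo inbreeding from integer parent arrays (0 = unknown).
# D_j uses F = -1 for unknown parents so founders get D = 1.
ped_inbreeding <- function(s, d) {
  n <- length(s)
  FF <- numeric(n)
  DD <- numeric(n)
  for (i in seq_len(n)) {
    Fs <- if (s[i] > 0L) FF[s[i]] else -1
    Fd <- if (d[i] > 0L) FF[d[i]] else -1
    DD[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s[i] == 0L || d[i] == 0L) { FF[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    anc <- i        # indices with nonzero L, processed youngest-first
    aii <- 0
    while (length(anc)) {
      j <- max(anc)
      anc <- anc[anc != j]
      lj <- L[j]
      if (s[j] > 0L) {
        if (L[s[j]] == 0) anc <- c(anc, s[j])
        L[s[j]] <- L[s[j]] + 0.5 * lj
      }
      if (d[j] > 0L) {
        if (L[d[j]] == 0) anc <- c(anc, d[j])
        L[d[j]] <- L[d[j]] + 0.5 * lj
      }
      aii <- aii + lj^2 * DD[j]
      L[j] <- 0
    }
    FF[i] <- aii - 1
  }
  FF
}
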