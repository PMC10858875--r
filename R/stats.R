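#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum(|x_i - x_j|) / sum(x_i + x_j)` over populations. Two
#' all-zero samples get distance 0 with a warning.
#'
#' @param abundance Long abundance tibble or a populations-by-samples
#'   matrix (see [abundance_matrix()]); values must be nonnegative.
#' @return Symmetric numeric matrix with zero diagonal, dimnames =
#'   sample IDs.
#' @export
bray_curtis <- function(abundance) {
  m <- if (is.matrix(abundance)) abundance else abundance_matrix(abundance)
  if (any(m < 0)) stop("abundances must be >= 0")
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- sum(m[, i] + m[, j])
      if (tot == 0) {
        if (!warned) {
          warning("all-zero sample pair(s): distance set to 0")
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / tot
      }
    }
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2` (Gower centering) and eigendecomposes it;
#' axes are ordered by decreasing eigenvalue, negative eigenvalues are
#' reported but their axes dropped. On a Euclidean configuration the
#' coordinates reproduce the input distances exactly.
#'
#' @param d Square symmetric distance matrix (n >= 3).
#' @return Object of class `phagedyn_pcoa` with `points` (n x k
#'   coordinate matrix), `eigenvalues` (all n) and `prop_explained` (over
#'   positive eigenvalues).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 samples")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(abs(diag(d)) > 1e-12)) {
    stop("d must be symmetric with zero diagonal")
  }
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- eig$values > max(1e-9, 1e-9 * abs(eig$values[1]))
  pts <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), nrow = sum(pos))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(points = pts, eigenvalues = eig$values,
                 prop_explained = eig$values[pos] / sum(eig$values[pos])),
            class = "phagedyn_pcoa")
}

permanova_f <- function(d2, groups, group_levels) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in group_levels) {
    idx <- which(groups == g)
    sub <- d2[idx, idx]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  a <- length(group_levels)
  f <- (ss_among / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_among / ss_total)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Pseudo-F from among/within sums of squared distances in the adonis
#' formulation; the p-value uses the +1 permutation correction
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so it is never exactly
#' zero. Groups of size 1 are rejected.
#'
#' @param d Distance matrix.
#' @param groups Factor-like vector of group labels, one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return Object of class `phagedyn_permanova` with `r_squared`,
#'   `pseudo_f`, `p_value`, `df` and the call parameters; has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  d2 <- d^2
  obs <- permanova_f(d2, groups, lev)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      permanova_f(d2, sample(groups), lev)[["f"]] >= obs[["f"]]
    }, logical(1)))
  })
  structure(list(
    r_squared = obs[["r2"]], pseudo_f = obs[["f"]],
    p_value = (1 + exceed) / (1 + n_perm),
    df = c(among = length(lev) - 1, within = nrow(d) - length(lev)),
    n_perm = n_perm, n = nrow(d)
  ), class = "phagedyn_permanova")
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation over the lower-triangle entries; the permutation
#' p-value (same +1 correction as [permanova()]) permutes the rows and
#' columns of the second matrix jointly. A constant matrix leaves r
#' undefined (`NA`, flagged by a warning).
#'
#' @param d1,d2 Distance matrices over the same samples.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble with `r`, `p_value`, `n_perm`.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  lt <- lower.tri(d1)
  x <- d1[lt]
  if (stats::sd(x) == 0 || stats::sd(d2[lt]) == 0) {
    warning("constant distance matrix: Mantel r undefined")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          n_perm = n_perm))
  }
  r_obs <- stats::cor(x, d2[lt])
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample(nrow(d2))
      stats::cor(x, d2[p, p][lt]) >= r_obs
    }, logical(1)))
  })
  tibble::tibble(r = r_obs, p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH as implemented by `stats::p.adjust(method = "BH")`:
#' `q_(i) = min_(j >= i) (p_(j) * n / j)`, capped at 1, returned in input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' @export
print.phagedyn_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (one factor, %d permutations)\n  R2 = %.4f, pseudo-F = %.3f, p = %.4g\n",
    x$n_perm, x$r_squared, x$pseudo_f, x$p_value))
  invisible(x)
}

#' Tidy a PERMANOVA fit
#'
#' @param x A `phagedyn_permanova` object.
#' @param ... Unused.
#' @return A tibble with one row per term (among-group term plus
#'   residual).
#' @export
tidy.phagedyn_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("groups", "residual"),
    df = unname(x$df),
    R2 = c(x$r_squared, 1 - x$r_squared),
    statistic = c(x$pseudo_f, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' Glance at a PERMANOVA fit
#'
#' @inheritParams tidy.phagedyn_permanova
#' @return One-row tibble of fit summaries.
#' @export
glance.phagedyn_permanova <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, statistic = x$pseudo_f,
                 p.value = x$p_value, n = x$n, n.perm = x$n_perm)
}

#' Tidy a shared-SNP similarity fit
#'
#' @param x A `phagedyn_snp_fit` object.
#' @param ... Unused.
#' @return Per-lifestyle tibble of slope, intercept, adjusted R-squared.
#' @export
tidy.phagedyn_snp_fit <- function(x, ...) {
  x$fits
}

#' Glance at a shared-SNP similarity fit
#'
#' @inheritParams tidy.phagedyn_snp_fit
#' @return One-row tibble with the number of series points and lifestyles.
#' @export
glance.phagedyn_snp_fit <- function(x, ...) {
  tibble::tibble(n = nrow(x$series),
                 n_lifestyles = nrow(x$fits),
                 n_lags = dplyr::n_distinct(x$series$lag_days))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
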