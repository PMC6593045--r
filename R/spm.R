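# Permutation-based one-dimensional statistical parametric mapping.
#
# Pointwise t statistics along the 101-node gait continuum, with family-wise
# significance controlled by the permutation distribution of the maximum
# absolute t over the continuum (max-statistic method). Permutation is exact
# (full enumeration) whenever the number of relabelings / sign patterns does
# not exceed `n_permutations`, which covers the small group sizes typical of
# rodent studies (e.g. 8 vs 4 curves -> 495 relabelings); otherwise a random
# subset seeded by `seed` is used, always including the observed labeling.

make_spm_result <- function(t_curve, threshold, max_stats, alpha,
                            n_permutations, exact, seed, test) {
  B <- length(max_stats)
  above <- abs(t_curve) > threshold
  clusters <- data.frame(start = integer(0), end = integer(0),
                         max_t = numeric(0), p = numeric(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      cmax <- max(abs(t_curve[starts[k]:ends[k]]))
      p <- (sum(max_stats >= cmax) + 1) / (B + 1)
      clusters <- rbind(clusters,
                        data.frame(start = starts[k] - 1L, end = ends[k] - 1L,
                                   max_t = cmax, p = p))
    }
  }
  structure(list(t_curve = t_curve, threshold = threshold,
                 clusters = clusters, alpha = alpha,
                 n_permutations = n_permutations, exact = exact,
                 seed = seed, test = test, max_stats = max_stats),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("SPM %s t-test: threshold |t*| = %.3f (alpha = %g, %d %s permutations)\n",
              x$test, x$threshold, x$alpha, x$n_permutations,
              if (x$exact) "exhaustive" else "random"))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %d-%d%% of cycle, max |t| = %.2f, p = %.4f\n",
                  i, x$clusters$start[i], x$clusters$end[i],
                  x$clusters$max_t[i], x$clusters$p[i]))
  }
  invisible(x)
}

# (1-alpha) permutation critical value: the floor((1-alpha)*B)-th order
# statistic of the B max statistics; rejection when the observed maximum
# strictly exceeds it gives rejection probability (B - floor((1-alpha)B))/B,
# e.g. 25/495 = 0.0505 at alpha = 0.05 with full enumeration of 8v4 labels.
perm_threshold <- function(max_stats, alpha) {
  s <- sort(max_stats)
  k <- max(1L, floor((1 - alpha) * length(s)))
  s[k]
}

two_sample_t_rows <- function(sumA, ssqA, nA, sumB, ssqB, nB) {
  mA <- sumA / nA
  mB <- sumB / nB
  ssA <- ssqA - nA * mA^2
  ssB <- ssqB - nB * mB^2
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
}

#' Two-sample SPM t-test on gait-cycle continua
#'
#' Pointwise two-sample pooled-variance t statistic at each of the 101 cycle
#' nodes, with the critical threshold taken from the permutation distribution
#' of the maximum absolute t under group-label exchange. Supra-threshold
#' clusters are reported with cluster p-values
#' `(b + 1) / (B + 1)` where `b` counts permutations whose maximum |t|
#' reaches the cluster maximum.
#'
#' @param groupA,groupB Numeric matrices of curves, `n x 101` (one row per
#'   animal/curve).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_permutations Permutation budget (default 10000); all labelings
#'   are enumerated when their count does not exceed it.
#' @param seed Seed for random permutations (ignored under full
#'   enumeration).
#' @return An `spm_result`: `t_curve`, `threshold`, `clusters`
#'   (start/end node, max |t|, p), `alpha`, `n_permutations`, `exact`,
#'   `seed`.
#' @export
spm_ttest2 <- function(groupA, groupB, alpha = 0.05, n_permutations = 10000L,
                       seed = 1L) {
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2 || nB < 2)
    rg_stop("each group needs at least 2 curves", "ratgait_error_sample_size")
  if (ncol(A) != ncol(B))
    rg_stop("groups must share the node count", "ratgait_error_contract")
  D <- rbind(A, B)
  n <- nA + nB
  nperm_all <- choose(n, nA)
  exact <- nperm_all <= n_permutations
  if (exact) {
    sel <- utils::combn(n, nA)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    sel <- cbind(seq_len(nA),
                 replicate(n_permutations - 1L, sample.int(n, nA)))
  }
  Bn <- ncol(sel)
  P <- matrix(0, Bn, n)
  P[cbind(rep(seq_len(Bn), each = nA), as.vector(sel))] <- 1
  D2 <- D^2
  sumsA <- P %*% D
  ssqA <- P %*% D2
  totS <- matrix(colSums(D), Bn, ncol(D), byrow = TRUE)
  totQ <- matrix(colSums(D2), Bn, ncol(D), byrow = TRUE)
  Tmat <- two_sample_t_rows(sumsA, ssqA, nA, totS - sumsA, totQ - ssqA, nB)
  if (any(!is.finite(Tmat[1, ])))
    rg_stop("zero pooled variance at one or more nodes",
            "ratgait_error_degenerate_variance")
  max_stats <- apply(abs(Tmat), 1, max)
  t_obs <- if (exact) {
    # locate the observed labeling (first nA rows as group A)
    obs_row <- which(apply(P[, seq_len(nA), drop = FALSE] == 1, 1, all) &
                       rowSums(P) == nA)[1]
    Tmat[obs_row, ]
  } else {
    Tmat[1, ]
  }
  thr <- perm_threshold(max_stats, alpha)
  make_spm_result(t_obs, thr, max_stats, alpha, Bn, exact, seed,
                  test = "two-sample")
}

#' Paired SPM t-test on gait-cycle continua
#'
#' Pointwise paired t statistic on the row-wise difference curves, with the
#' permutation distribution generated by random sign flips of whole
#' difference curves (exact enumeration of all `2^n` sign patterns when
#' affordable).
#'
#' @param before,after Numeric matrices `n x 101`, paired by row.
#' @inheritParams spm_ttest2
#' @return An `spm_result`.
#' @export
spm_paired <- function(before, after, alpha = 0.05, n_permutations = 10000L,
                       seed = 1L) {
  X <- as.matrix(before); Y <- as.matrix(after)
  if (!all(dim(X) == dim(Y)))
    rg_stop("before/after must have identical dimensions",
            "ratgait_error_contract")
  n <- nrow(X)
  if (n < 2)
    rg_stop("paired SPM needs at least 2 pairs", "ratgait_error_sample_size")
  D <- Y - X
  nperm_all <- 2^n
  exact <- nperm_all <= n_permutations
  if (exact) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    S <- rbind(rep(1, n),
               matrix(sample(c(1, -1), (n_permutations - 1L) * n, TRUE),
                      ncol = n))
  }
  Bn <- nrow(S)
  means <- (S %*% D) / n
  q <- matrix(colSums(D^2), Bn, ncol(D), byrow = TRUE)
  v <- (q - n * means^2) / (n - 1)
  Tmat <- means / sqrt(v / n)
  if (any(!is.finite(Tmat[1, ])))
    rg_stop("zero variance of differences at one or more nodes",
            "ratgait_error_degenerate_variance")
  max_stats <- apply(abs(Tmat), 1, max)
  obs_row <- if (exact) which(apply(S == 1, 1, all))[1] else 1L
  thr <- perm_threshold(max_stats, alpha)
  make_spm_result(Tmat[obs_row, ], thr, max_stats, alpha, Bn, exact, seed,
                  test = "paired")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Paired t-test on scalar gait parameters
#'
#' Classical two-sided paired t-test (df = n - 1), with an explicit
#' degenerate-variance error when all pairwise differences are equal.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    rg_stop("paired t-test needs two equal-length vectors, n >= 2",
            "ratgait_error_sample_size")
  d <- y - x
  if (stats::sd(d) == 0)
    rg_stop("zero variance of paired differences", "ratgait_error_degenerate_variance")
  ht <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way ANOVA with Fisher's LSD post-hoc comparisons
#'
#' Fits the one-way fixed-effects ANOVA via `stats::aov` and reports
#' Fisher's least-significant-difference pairwise tests:
#' `t_ij = (mean_i - mean_j) / sqrt(MS_within (1/n_i + 1/n_j))` with
#' `df = N - k` and unadjusted two-sided p-values (Fisher's LSD applies no
#' multiplicity correction beyond the omnibus test).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return Object of class `anova_lsd`: `F`, `df_between`, `df_within`, `p`,
#'   `ms_within`, `pairwise` (data frame: group_i, group_j, mean_diff,
#'   t, p).
#' @export
anova_fisher_lsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2)
    rg_stop("need at least 2 groups", "ratgait_error_sample_size")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2))
    rg_stop("every group needs at least 2 values", "ratgait_error_sample_size")
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups), ns),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  msw <- tab["Residuals", "Mean Sq"]
  if (msw <= 0 || !is.finite(msw))
    rg_stop("zero within-group variance", "ratgait_error_degenerate_variance")
  Fval <- tab[1, "F value"]
  dfb <- tab[1, "Df"]
  dfw <- tab["Residuals", "Df"]
  means <- vapply(groups, mean, 0)
  pairs <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- means[[i]] - means[[j]]
    se <- sqrt(msw * (1 / ns[[i]] + 1 / ns[[j]]))
    tval <- diff / se
    data.frame(group_i = i, group_j = j, mean_diff = diff, t = tval,
               p = 2 * stats::pt(-abs(tval), dfw))
  }))
  structure(list(F = Fval, df_between = dfb, df_within = dfw,
                 p = tab[1, "Pr(>F)"], ms_within = msw, alpha = alpha,
                 pairwise = pw),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  cat("Fisher's LSD pairwise comparisons:\n")
  print(transform(x$pairwise, mean_diff = round(mean_diff, 4),
                  t = round(t, 3), p = signif(p, 4)), row.names = FALSE)
  invisible(x)
}

#' Write an SPM result to CSV
#'
#' One row per cycle node: node (0-100), t, threshold, cluster id (NA when
#' not in a cluster), cluster p.
#'
#' @param spm An `spm_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spm_csv <- function(spm, path) {
  node <- seq_along(spm$t_curve) - 1L
  cluster <- rep(NA_integer_, length(node))
  cluster_p <- rep(NA_real_, length(node))
  for (i in seq_len(nrow(spm$clusters))) {
    idx <- (spm$clusters$start[i]:spm$clusters$end[i]) + 1L
    cluster[idx] <- i
    cluster_p[idx] <- spm$clusters$p[i]
  }
  utils::write.csv(data.frame(node = node, t = spm$t_curve,
                              threshold = spm$threshold, cluster = cluster,
                              cluster_p = cluster_p),
                   path, row.names = FALSE)
  invisible(path)
}
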