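# Pooled-variance two-sample t statistics for many permutations at once.
# M is a (n_splits x n) 0/1 membership matrix for group A; X is
# (n x n_signals). Returns (n_splits x n_signals) t values.
t_stat_matrix <- function(M, X, na, nb) {
  n <- na + nb
  S <- colSums(X)
  SS <- colSums(X^2)
  SA <- M %*% X
  SSA <- M %*% (X^2)
  SB <- rep(1, nrow(M)) %o% S - SA
  SSB <- rep(1, nrow(M)) %o% SS - SSA
  mA <- SA / na
  mB <- SB / nb
  vA <- (SSA - SA^2 / na) / (na - 1)
  vB <- (SSB - SB^2 / nb) / (nb - 1)
  sp2 <- ((na - 1) * vA + (nb - 1) * vB) / (n - 2)
  (mA - mB) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Build the permutation schedule: a 0/1 matrix of group-A memberships.
# Exhaustive when the number of distinct assignments fits in n_perm,
# otherwise n_perm uniform random assignments (first row = observed labels
# is NOT included; the observed labeling is handled by the +1 convention).
permutation_schedule <- function(n, na, n_perm, seed) {
  n_total <- choose(n, na)
  exhaustive <- n_total <= n_perm
  if (exhaustive) {
    combs <- utils::combn(n, na)
    M <- matrix(0, ncol(combs), n)
    M[cbind(rep(seq_len(ncol(combs)), each = na), as.vector(combs))] <- 1
  } else {
    M <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) {
        m <- numeric(n); m[sample.int(n, na)] <- 1; m
      }, numeric(n)))
    })
  }
  attr(M, "exhaustive") <- exhaustive
  M
}

#' Two-sample permutation t test
#'
#' Two-tailed nonparametric test of a group difference: the observed
#' pooled-variance Student t statistic is compared against its distribution
#' under random relabelings of group membership. When the number of
#' distinct label assignments does not exceed `n_perm` the null
#' distribution is enumerated exhaustively and
#' `p = #\{|t*| >= |t_obs|\} / n_assignments` (the identity relabeling
#' included); otherwise `n_perm` random relabelings are drawn and
#' `p = (1 + #\{|t*| >= |t_obs|\}) / (1 + n_perm)`, so p is never zero.
#'
#' @param a,b numeric samples for the two groups (each of length >= 2).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the sampled schedule.
#' @return list (class `perm_ttest`): `t_obs`, `p_perm`, `n_permutations`,
#'   `exhaustive`, `seed`.
#' @export
permutation_ttest <- function(a, b, n_perm = 10000, seed = 1L) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop_invalid("each group needs >= 2 observations")
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  x <- c(a, b)
  if (stats::var(a) + stats::var(b) == 0)
    stop_undefined("zero pooled variance: t statistic undefined")
  M <- permutation_schedule(na + nb, na, n_perm, seed)
  obs <- matrix(0, 1, na + nb); obs[1, seq_len(na)] <- 1
  t_obs <- as.vector(t_stat_matrix(obs, cbind(x), na, nb))
  t_null <- as.vector(t_stat_matrix(M, cbind(x), na, nb))
  tol <- 1e-8 * max(1, abs(t_obs))
  hits <- sum(abs(t_null) >= abs(t_obs) - tol, na.rm = TRUE)
  exhaustive <- attr(M, "exhaustive")
  p <- if (exhaustive) hits / nrow(M) else (1 + hits) / (1 + nrow(M))
  structure(list(t_obs = t_obs, p_perm = p, n_permutations = nrow(M),
                 exhaustive = exhaustive, seed = seed),
            class = "perm_ttest")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR control over the supplied family of p-values (any shape;
#' the family is the flattened set). Rejections are `q <= level`.
#'
#' @param p numeric vector or matrix of p-values in (0, 1].
#' @param level FDR level (default 0.05).
#' @return list with `q` (same shape as `p`) and `rejected` (logical, same
#'   shape).
#' @export
fdr_correct <- function(p, level = 0.05) {
  pv <- as.vector(p)
  if (any(!is.finite(pv)) || any(pv <= 0) || any(pv > 1))
    stop_invalid("p-values must lie in (0, 1]")
  q <- stats::p.adjust(pv, method = "BH")
  rejected <- q <= level
  if (is.matrix(p)) {
    q <- matrix(q, nrow(p), ncol(p), dimnames = dimnames(p))
    rejected <- matrix(rejected, nrow(p), ncol(p), dimnames = dimnames(p))
  }
  list(q = q, rejected = rejected)
}

#' Feature matrix for group statistics
#'
#' @param values numeric 3-D array, subjects x signals x features (feature
#'   dimension named by [feature_names()] or a subset).
#' @param subjects data.frame with a `group` column (and covariates);
#'   rows align with the first array dimension.
#' @param signal_meta data.frame describing the signals (sensor layout or
#'   region table), rows aligned with the second dimension.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, subjects, signal_meta = NULL) {
  if (length(dim(values)) != 3)
    stop_invalid("values must be subjects x signals x features")
  if (nrow(subjects) != dim(values)[1])
    stop_invalid("subject table rows (%d) != subjects dimension (%d)",
                 nrow(subjects), dim(values)[1])
  if (is.null(subjects$group) || anyNA(subjects$group))
    stop_invalid("every subject needs a group label")
  structure(list(values = values, subjects = subjects,
                 signal_meta = signal_meta),
            class = "feature_matrix")
}

#' Assemble a feature matrix from per-subject features
#'
#' @param feature_list list of `spectral_features` data.frames, one per
#'   subject, all over the same signals.
#' @param subjects subject table aligned with `feature_list`.
#' @param signal_meta optional signal metadata.
#' @param features which feature columns to stack.
#' @export
stack_features <- function(feature_list, subjects, signal_meta = NULL,
                           features = feature_names()) {
  nsig <- nrow(feature_list[[1]])
  arr <- array(NA_real_, c(length(feature_list), nsig, length(features)),
               dimnames = list(subjects$subject_id,
                               feature_list[[1]]$signal_id, features))
  for (i in seq_along(feature_list))
    for (j in seq_along(features))
      arr[i, , j] <- feature_list[[i]][[features[j]]]
  feature_matrix(arr, subjects, signal_meta)
}

#' Group comparison over all signals and features
#'
#' Runs the two-tailed permutation t test for every signal x feature cell
#' using one shared permutation schedule (the same label shuffles across
#' all cells, preserving their dependence), then applies
#' Benjamini-Hochberg FDR correction over the chosen family: `"joint"`
#' (all signals x all features, the default) or `"per_feature"` (signals
#' within each feature).
#'
#' @param fm a [feature_matrix()] with exactly two groups.
#' @param n_perm permutations (default 10000).
#' @param seed schedule seed.
#' @param level FDR level.
#' @param fdr_family `"joint"` or `"per_feature"`.
#' @return A `perm_test_result`: data.frame `table` (signal_id, feature,
#'   t, p, q, rejected) plus `n_permutations`, `exhaustive`, `seed`,
#'   `level`, `family_size`.
#' @export
group_compare <- function(fm, n_perm = 10000, seed = 1L, level = 0.05,
                          fdr_family = c("joint", "per_feature")) {
  fdr_family <- match.arg(fdr_family)
  groups <- unique(fm$subjects$group)
  if (length(groups) != 2)
    stop_invalid("need exactly two groups, got %d", length(groups))
  ga <- fm$subjects$group == groups[1]
  na <- sum(ga); nb <- sum(!ga)
  d <- dim(fm$values)
  X <- matrix(fm$values[c(which(ga), which(!ga)), , ], d[1], d[2] * d[3])
  degen <- apply(X, 2, function(col)
    stats::var(col[seq_len(na)]) + stats::var(col[-seq_len(na)]) == 0)
  if (any(degen))
    stop_undefined("%d signal x feature cell(s) have zero pooled variance",
                   sum(degen))
  M <- permutation_schedule(d[1], na, n_perm, seed)
  obs <- matrix(0, 1, d[1]); obs[1, seq_len(na)] <- 1
  t_obs <- as.vector(t_stat_matrix(obs, X, na, nb))
  t_null <- abs(t_stat_matrix(M, X, na, nb))
  tol <- 1e-8 * pmax(1, abs(t_obs))
  hits <- colSums(t_null >= rep(abs(t_obs) - tol, each = nrow(M)))
  exhaustive <- attr(M, "exhaustive")
  p <- if (exhaustive) hits / nrow(M) else (1 + hits) / (1 + nrow(M))
  pm <- matrix(p, d[2], d[3])
  if (fdr_family == "joint") {
    fdr <- fdr_correct(pm, level)
  } else {
    fdr <- list(q = pm, rejected = pm > 1)
    for (j in seq_len(d[3])) {
      fj <- fdr_correct(pm[, j], level)
      fdr$q[, j] <- fj$q
      fdr$rejected[, j] <- fj$rejected
    }
  }
  sig_ids <- dimnames(fm$values)[[2]] %||% sprintf("S%03d", seq_len(d[2]))
  feats <- dimnames(fm$values)[[3]] %||% sprintf("F%d", seq_len(d[3]))
  tab <- data.frame(signal_id = rep(sig_ids, times = d[3]),
                    feature = rep(feats, each = d[2]),
                    t = t_obs, p = p, q = as.vector(fdr$q),
                    rejected = as.vector(fdr$rejected))
  structure(list(table = tab, n_permutations = nrow(M),
                 exhaustive = exhaustive, seed = seed, level = level,
                 family_size = if (fdr_family == "joint") d[2] * d[3] else d[2],
                 fdr_family = fdr_family,
                 groups = c(a = groups[1], b = groups[2])),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("<perm_test_result> %s vs %s, %d perms%s, FDR %s (family %d): %d rejected\n",
              x$groups["a"], x$groups["b"], x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else "",
              x$fdr_family, x$family_size, sum(x$table$rejected)))
  invisible(x)
}

#' Pearson correlation with pairwise-complete observations
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform on n - 2 degrees of freedom. Pairs with missing values are
#' dropped (not imputed) and the retained n is reported.
#'
#' @param x,y paired numeric vectors.
#' @return list (class `correlation_result`): `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must be paired")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_invalid("need >= 3 complete pairs, got %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_undefined("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' Lateralization index
#'
#' `LI = (left - right) / (left + right)` for a positive-valued feature
#' measured on a homologous left/right pair; lies in (-1, 1) and is
#' antisymmetric under swapping hemispheres. Vectorized over pairs.
#'
#' @param left,right positive values.
#' @export
lateralization_index <- function(left, right) {
  if (any(left <= 0) || any(right <= 0))
    stop_invalid("lateralization index requires positive inputs")
  (left - right) / (left + right)
}
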