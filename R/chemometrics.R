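#' Principal component analysis of a spectra set
#'
#' Column-mean-centered PCA via singular value decomposition (no scaling:
#' SNV already standardises spectra row-wise). Explained fractions are
#' sigma_i^2 / sum sigma^2 over all possible components. Component signs are
#' fixed by the convention that each loading's largest-magnitude element is
#' positive, so results are reproducible across platforms.
#'
#' @param set A `spectra_set` (pre-processed).
#' @param k Number of components to keep, `<= min(n_spectra - 1, n_points)`.
#' @return A `pca_result`: `scores` (n x k), `loadings` (k x n_points),
#'   `explained_fraction` (length k), `center` (mean spectrum), `sdev2_total`
#'   and `meta` (per-spectrum metadata carried through for grouping).
#' @export
pca <- function(set, k = 3) {
  stopifnot(inherits(set, "spectra_set"))
  n <- n_spectra(set)
  if (n < 2) stop("PCA needs at least 2 spectra", call. = FALSE)
  kmax <- min(n - 1L, ncol(set$matrix))
  if (k > kmax)
    stop(sprintf("k = %d exceeds the maximum of %d components", k, kmax),
         call. = FALSE)
  ctr <- colMeans(set$matrix)
  xc <- sweep(set$matrix, 2, ctr)
  sv <- svd(xc, nu = k, nv = k)
  d2 <- sv$d^2
  expl <- d2[seq_len(k)] / sum(d2)
  loadings <- t(sv$v)                     # k x n_points
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {                 # deterministic sign convention
    if (loadings[j, which.max(abs(loadings[j, ]))] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(set$meta$spectrum_id, paste0("PC", seq_len(k)))
  rownames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained_fraction = expl, center = ctr,
                 sdev2_total = sum(d2), meta = set$meta),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d spectra, %d components | explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", ")))
  invisible(x)
}

#' Kruskal-Wallis rank test over groups
#'
#' Tie-corrected Kruskal-Wallis one-way test, the non-parametric check that
#' culture day affects a per-spectrum statistic (typically the first PCA
#' score). Ranks use midranks for ties;
#' `H = (12 / (N(N+1)) * sum R_j^2 / n_j - 3(N+1)) / (1 - sum(t^3 - t) / (N^3 - N))`
#' with the p-value from the chi-square approximation on (groups - 1)
#' degrees of freedom.
#'
#' @param values Numeric per-observation statistic.
#' @param groups Group labels, same length (coerced to factor; for day
#'   grouping, pass the day index).
#' @return A `kw_result`: `H`, `df`, `p_value`, `group_stats` (group, n,
#'   mean_rank, median_rank), plus the ranks and tie correction needed by
#'   [pairwise_rank_comparison()].
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  ok <- is.finite(values)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2)
    stop("Kruskal-Wallis needs at least 2 groups", call. = FALSE)
  if (length(unique(values)) < 2)
    stop("all values tied; Kruskal-Wallis is degenerate", call. = FALSE)
  n <- length(values)
  r <- rank(values)                        # midranks
  rsum <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  h_raw <- 12 / (n * (n + 1)) * sum(rsum^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  correction <- 1 - tie_term / (n^3 - n)
  h <- h_raw / correction
  df <- nlevels(groups) - 1L
  gs <- data.frame(group = levels(groups), n = nj,
                   mean_rank = as.numeric(tapply(r, groups, mean)),
                   median_rank = as.numeric(tapply(r, groups, stats::median)),
                   stringsAsFactors = FALSE)
  structure(list(H = h, df = df,
                 p_value = stats::pchisq(h, df, lower.tail = FALSE),
                 group_stats = gs, n_total = n,
                 tie_correction = correction, ranks = r, groups = groups),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("<kw_result> H = %.4f, df = %d, p = %.3g (%d groups, N = %d)\n",
              x$H, x$df, x$p_value, nrow(x$group_stats), x$n_total))
  invisible(x)
}

#' Dunn-type pairwise rank comparisons after Kruskal-Wallis
#'
#' For each compared pair of groups, the z statistic on the mean-rank
#' difference with tie correction,
#' `z = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T/(12(N-1))) * (1/n_a + 1/n_b))`
#' with `T = sum(t^3 - t)`, and Bonferroni family-wise control over the pairs
#' actually compared. Adjacent groups (consecutive culture days) by default;
#' all pairs optionally.
#'
#' @param kw A `kw_result`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param pairs `"adjacent"` (default) or `"all"`.
#' @return data.frame with columns group_a, group_b, rank_diff, z, p, p_adj,
#'   significant.
#' @export
pairwise_rank_comparison <- function(kw, alpha = 0.05,
                                     pairs = c("adjacent", "all")) {
  stopifnot(inherits(kw, "kw_result"))
  pairs <- match.arg(pairs)
  gs <- kw$group_stats
  g <- nrow(gs)
  combs <- if (pairs == "adjacent")
    cbind(seq_len(g - 1), seq_len(g - 1) + 1L)
  else t(utils::combn(g, 2))
  n <- kw$n_total
  ties <- table(as.numeric(kw$ranks))
  tie_term <- sum(ties^3 - ties)
  var_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  out <- do.call(rbind, lapply(seq_len(nrow(combs)), function(i) {
    a <- combs[i, 1]; b <- combs[i, 2]
    diff <- gs$mean_rank[a] - gs$mean_rank[b]
    se <- sqrt(var_base * (1 / gs$n[a] + 1 / gs$n[b]))
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = gs$group[a], group_b = gs$group[b],
               rank_diff = diff, z = z, p = p, stringsAsFactors = FALSE)
  }))
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_adj <= alpha
  attr(out, "alpha") <- alpha
  attr(out, "pairs") <- pairs
  out
}
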