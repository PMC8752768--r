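#' @include AllClasses.R evodynamics.R
NULL

## the six trajectory features of the correlation analysis and their
## display names
trajectoryFeatureMap <- c(growth = "growthRate", aspect = "meanAR",
                          length = "meanL", width = "meanW",
                          logArea = "meanLogA", logVol = "meanLogV")

#' Pairwise feature correlations along a trajectory
#'
#' Pearson (or Spearman) correlations between all pairs of the six
#' trajectory features -- growth rate, aspect ratio, relative cell length
#' and width, and the logarithms of area and volume -- over the measured
#' transfers of one lineage, with two-sided p-values per pair. Pairs
#' involving a constant feature are undefined and reported as `r = NA`,
#' `p = 1`. No multiple-testing correction is applied by default (pairs are
#' reported individually); pass the matrix to [stats::p.adjust()] if
#' desired.
#'
#' @param trajectory a [LineageTrajectory-class], or a data.frame of
#'   records (e.g. several lineages pooled).
#' @param features named character vector mapping display names to record
#'   columns; default the six standard features.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a [CorrelationMatrix-class].
#' @export
featureCorrelations <- function(trajectory,
                                features = trajectoryFeatureMap,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rec <- if (is(trajectory, "LineageTrajectory")) trajectory@records
         else as.data.frame(trajectory)
  if (!all(features %in% names(rec)))
    stop("missing trajectory columns: ",
         paste(setdiff(features, names(rec)), collapse = ", "))
  if (nrow(rec) < 4L) stop("need at least 4 measured transfers")
  k <- length(features)
  nm <- names(features)
  r <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  X <- as.matrix(rec[, features, drop = FALSE])
  const <- apply(X, 2, function(v) stats::sd(v) < 1e-12)
  for (i in seq_len(k)) {
    if (!const[i]) { r[i, i] <- 1; p[i, i] <- 0 }
    for (j in seq_len(k)) {
      if (j <= i || const[i] || const[j]) next
      ct <- stats::cor.test(X[, i], X[, j], method = method, exact = FALSE)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  new("CorrelationMatrix", features = nm, r = r, p = p,
      n = nrow(rec), method = method)
}

#' Plot a correlation-significance heatmap
#'
#' Renders the pairwise correlation significance as a heatmap of
#' `-log10(p)`, darker meaning more significant, with the correlation
#' coefficients printed in the cells.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param file optional PNG path; when `NULL`, plots to the active device.
#' @param pFloor smallest p-value distinguished on the colour scale.
#' @return the `-log10(p)` matrix, invisibly.
#' @export
plotCorrelationHeatmap <- function(cm, file = NULL, pFloor = 1e-10) {
  stopifnot(is(cm, "CorrelationMatrix"))
  s <- -log10(pmax(cm@p, pFloor))
  lab <- matrix(sprintf("%.2f", cm@r), nrow(cm@r),
                dimnames = dimnames(cm@r))
  lab[is.na(cm@r)] <- ""
  pal <- grDevices::colorRampPalette(c("lightyellow", "steelblue",
                                       "midnightblue"))(100)
  args <- list(mat = s, cluster_rows = FALSE, cluster_cols = FALSE,
               display_numbers = lab, color = pal,
               main = sprintf("correlation significance (-log10 p), n = %d",
                              cm@n))
  if (!is.null(file)) {
    args$filename <- file
    do.call(pheatmap::pheatmap, args)
  } else {
    do.call(pheatmap::pheatmap, args)
  }
  invisible(s)
}

#' Compare two groups of population measurements
#'
#' Exact permutation test (shared with the fold-change analysis) on the
#' difference of group means, or a sign-flip permutation test on paired
#' differences when `paired = TRUE`, together with the summary statistics
#' used for boxplot reporting.
#'
#' @param a,b numeric groups (at least 3 values each; equal length if
#'   paired).
#' @param paired logical.
#' @param nPerm Monte Carlo permutations when enumeration is infeasible.
#' @return list with `statistic`, `p`, `exact`, `medians`, `means`, `n`.
#' @export
compareGroups <- function(a, b, paired = FALSE, nPerm = 10000L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) stop("need at least 3 values per group")
  if (paired) {
    if (length(a) != length(b)) stop("paired groups must have equal length")
    d <- a - b
    obs <- mean(d)
    tol <- 1e-12 * max(1, abs(obs), stats::sd(c(a, b)))
    n <- length(d)
    if (n <= 14L) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      stats <- as.vector(signs %*% d) / n
      p <- mean(abs(stats) >= abs(obs) - tol)
      exact <- TRUE; nS <- 2^n
    } else {
      cnt <- 0L
      for (i in seq_len(nPerm)) {
        st <- mean(d * sample(c(-1, 1), n, replace = TRUE))
        if (abs(st) >= abs(obs) - tol) cnt <- cnt + 1L
      }
      p <- (cnt + 1) / (nPerm + 1); exact <- FALSE; nS <- nPerm
    }
    res <- list(statistic = obs, p = p, exact = exact, nSplits = nS)
  } else {
    res <- permutationTest(a, b, nPerm = nPerm)
  }
  c(res, list(medians = c(a = stats::median(a), b = stats::median(b)),
              means = c(a = mean(a), b = mean(b)),
              n = c(a = length(a), b = length(b))))
}

#' Boxplot summary statistics per group
#'
#' Exact order statistics per labelled group: quartiles (linear
#' interpolation, quantile type 7), median, mean, extremes and group size.
#'
#' @param values numeric vector.
#' @param groups group labels, recycled against `values`.
#' @return data.frame, one row per group.
#' @examples
#' summarizeBoxes(1:5, rep("a", 5))
#' @export
summarizeBoxes <- function(values, groups) {
  if (!length(values)) stop("no values")
  groups <- rep_len(as.character(groups), length(values))
  sp <- split(as.numeric(values), groups)
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), min = min(v), q1 = q[1],
               median = q[2], q3 = q[3], max = max(v), mean = mean(v))
  })
  do.call(rbind, rows)
}
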