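# Ensemble eigenanalysis of correlation matrices: decomposition, large-
# eigenvalue selection, reflection-aware Ward clustering of eigenvectors,
# deduplication, alignment/averaging, and Scheffe group comparison.

#' Eigendecomposition of a correlation matrix
#'
#' Real symmetric eigendecomposition with eigenvalues sorted in decreasing
#' order and orthonormal eigenvectors. rho(q, s) matrices are not
#' guaranteed positive semidefinite: negative eigenvalues are legitimate
#' and are never clipped. For a unit-diagonal p x p matrix the eigenvalues
#' sum to p (trace conservation).
#'
#' @param x a \linkS4class{DCCMatrix} or a symmetric numeric matrix.
#' @return list with `values` (decreasing) and `vectors` (columns,
#'   orthonormal).
#' @export
eigenDecompose <- function(x) {
  v <- if (is(x, "DCCMatrix")) x@values else as.matrix(x)
  if (max(abs(v - t(v))) > 1e-10 * max(1, max(abs(v))))
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  e <- eigen((v + t(v)) / 2, symmetric = TRUE)
  # enforce unit norm exactly within floating tolerance
  e$vectors <- sweep(e$vectors, 2L, sqrt(colSums(e$vectors^2)), "/")
  list(values = e$values, vectors = e$vectors)
}

#' Pool eigenpairs of many correlation matrices into an ensemble
#'
#' Decomposes each matrix and stacks all eigenpairs, tagging every entry
#' with its configuration row (subject, tod, task, phase, ...) and a
#' matrix identifier.
#'
#' @param matrices list of \linkS4class{DCCMatrix} objects with identical
#'   region ordering.
#' @param config data.frame with one row per matrix (factor labels).
#' @return An \linkS4class{EigenEnsemble} (unclustered).
#' @export
eigenEnsemble <- function(matrices, config) {
  stopifnot(length(matrices) >= 1L, nrow(config) == length(matrices))
  labels <- rownames(matrices[[1L]]@values)
  vals <- numeric()
  vecs <- NULL
  rows <- list()
  for (i in seq_along(matrices)) {
    if (!identical(rownames(matrices[[i]]@values), labels))
      stop("matrices must share region ordering", call. = FALSE)
    e <- eigenDecompose(matrices[[i]])
    vals <- c(vals, e$values)
    vecs <- cbind(vecs, e$vectors)
    cf <- config[rep(i, length(e$values)), , drop = FALSE]
    cf$matrixId <- i
    cf$rank <- seq_along(e$values)
    rows[[i]] <- cf
  }
  cfg <- do.call(rbind, rows)
  rownames(cfg) <- NULL
  rownames(vecs) <- labels
  new("EigenEnsemble", values = vals, vectors = vecs, config = cfg,
      clusterLabels = rep(NA_integer_, length(vals)),
      clusterOrder = integer())
}

#' @rdname eigenvalues
#' @export
#' @aliases eigenvalues,EigenEnsemble-method
setMethod("eigenvalues", "EigenEnsemble", function(x) x@values)

#' @rdname eigenvectors
#' @export
#' @aliases eigenvectors,EigenEnsemble-method
setMethod("eigenvectors", "EigenEnsemble", function(x) x@vectors)

#' @rdname clusterLabels
#' @export
#' @aliases clusterLabels,EigenEnsemble-method
setMethod("clusterLabels", "EigenEnsemble", function(x) x@clusterLabels)

#' @rdname clusterOrder
#' @export
#' @aliases clusterOrder,EigenEnsemble-method
setMethod("clusterOrder", "EigenEnsemble", function(x) x@clusterOrder)

#' @rdname ensembleConfig
#' @export
#' @aliases ensembleConfig,EigenEnsemble-method
setMethod("ensembleConfig", "EigenEnsemble", function(x) x@config)

setMethod("show", "EigenEnsemble", function(object) {
  cat(sprintf("EigenEnsemble: %d entries over %d regions",
              length(object@values), nrow(object@vectors)))
  if (length(object@clusterOrder))
    cat(sprintf(", %d ordered clusters", length(object@clusterOrder)))
  cat("\n")
})

#' Retain entries with large eigenvalues
#'
#' Keeps entries with eigenvalue strictly above `cutoff` (default 2: above
#' the usual Q3 + 1.5 IQR outlier fence of a correlation-matrix spectrum).
#' An empty result is allowed. Per-configuration retained counts are
#' available via \code{\link{perConfigCounts}}.
#'
#' @param ensemble an \linkS4class{EigenEnsemble}.
#' @param cutoff eigenvalue threshold (default 2).
#' @return the filtered \linkS4class{EigenEnsemble}.
#' @export
selectLarge <- function(ensemble, cutoff = 2.0) {
  keep <- ensemble@values > cutoff
  new("EigenEnsemble", values = ensemble@values[keep],
      vectors = ensemble@vectors[, keep, drop = FALSE],
      config = ensemble@config[keep, , drop = FALSE],
      clusterLabels = ensemble@clusterLabels[keep],
      clusterOrder = integer())
}

#' Entries per configuration
#'
#' @param ensemble an \linkS4class{EigenEnsemble}.
#' @return integer table of entry counts per matrix identifier.
#' @export
perConfigCounts <- function(ensemble) {
  table(ensemble@config$matrixId)
}

#' Reflection-aware squared Euclidean distance between eigenvectors
#'
#' d~(u, v) = min(d(u, v), d(-u, v)) with d the squared Euclidean distance:
#' eigenvector opposites represent the same correlation pattern, so u and
#' -u are treated as identical. For unit vectors this equals
#' 2 - 2 |u . v|.
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar distance; zero iff u = v or u = -v.
#' @export
reflectionDistance <- function(u, v) {
  if (length(u) != length(v))
    stop("'u' and 'v' must have equal length", call. = FALSE)
  min(sum((u - v)^2), sum((u + v)^2))
}

# Full reflection-aware dissimilarity matrix for unit-norm columns,
# via the identity d~ = 2 - 2|u'v|.
reflectionDissimilarity <- function(V) {
  G <- crossprod(V)
  D <- 2 - 2 * abs(G)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Cluster ensemble eigenvectors with reflection-aware Ward linkage
#'
#' Agglomerative hierarchical clustering (Ward's minimum-variance update
#' applied to the stored reflection-aware squared distances d~, i.e.
#' `hclust(method = "ward.D")` on d~) cut at `nClusters` clusters. Within
#' each cluster, when several entries share one (subject, tod, task, phase)
#' configuration only the entry with the largest eigenvalue is kept (ties:
#' first in input order); the rest are marked dropped (label NA). Cluster
#' ids are then ordered by decreasing mean member eigenvalue.
#'
#' Note d~ is treated as a generic dissimilarity: after reflection
#' minimisation it is not guaranteed to embed in Euclidean space, so this
#' is the stored-dissimilarity Ward update rather than textbook Euclidean
#' Ward.
#'
#' @param ensemble an \linkS4class{EigenEnsemble} (usually after
#'   \code{\link{selectLarge}}).
#' @param nClusters number of clusters (default 15).
#' @return the \linkS4class{EigenEnsemble} with `clusterLabels` and
#'   `clusterOrder` filled in.
#' @export
clusterEigenvectors <- function(ensemble, nClusters = 15L) {
  n <- length(ensemble@values)
  if (n < nClusters)
    stop(sprintf("ensemble has %d entries, fewer than %d clusters",
                 n, nClusters), call. = FALSE)
  D <- reflectionDissimilarity(ensemble@vectors)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D")
  labels <- stats::cutree(hc, k = nClusters)

  # deduplication: one entry per (cluster, subject, tod, task, phase)
  cfgCols <- intersect(c("subject", "tod", "task", "phase"),
                       names(ensemble@config))
  key <- if (length(cfgCols))
    do.call(paste, c(ensemble@config[cfgCols], sep = "\r")) else
    as.character(ensemble@config$matrixId)
  lab <- as.integer(labels)
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    for (k in unique(key[idx])) {
      dup <- idx[key[idx] == k]
      if (length(dup) > 1L) {
        keepOne <- dup[which.max(ensemble@values[dup])]
        lab[setdiff(dup, keepOne)] <- NA_integer_
      }
    }
  }

  meanByCluster <- vapply(seq_len(nClusters), function(cl)
    mean(ensemble@values[which(lab == cl)]), numeric(1))
  ord <- order(meanByCluster, decreasing = TRUE)

  out <- ensemble
  out@clusterLabels <- lab
  out@clusterOrder <- as.integer(ord)
  out
}

#' Align and average the eigenvectors of one cluster
#'
#' Members are sign-flipped to have non-negative inner product with the
#' reference member (the one with the largest eigenvalue; the global sign
#' of the result is therefore only defined up to +/-), then averaged
#' element-wise. The mean is reported as-is, without renormalisation, with
#' element-wise standard errors over the aligned members.
#'
#' @param ensemble a clustered \linkS4class{EigenEnsemble}.
#' @param cluster cluster id (as in `clusterLabels`).
#' @return list with `mean` (named numeric), `se` (named numeric),
#'   `eigenvalues` (member eigenvalues) and `n` (member count).
#' @export
alignAndAverage <- function(ensemble, cluster) {
  idx <- which(ensemble@clusterLabels == cluster)
  if (!length(idx)) stop("cluster has no members", call. = FALSE)
  V <- ensemble@vectors[, idx, drop = FALSE]
  ref <- V[, which.max(ensemble@values[idx])]
  signs <- ifelse(colSums(V * ref) < 0, -1, 1)
  A <- sweep(V, 2L, signs, "*")
  mu <- rowMeans(A)
  se <- if (length(idx) > 1L)
    apply(A, 1L, sd) / sqrt(length(idx)) else
    setNames(rep(0, nrow(A)), rownames(A))
  list(mean = mu, se = se, eigenvalues = ensemble@values[idx],
       n = length(idx))
}

#' Scheffe-adjusted pairwise comparison of group means
#'
#' One-way layout: for each pair of groups the contrast mean difference is
#' tested with the Scheffe criterion, F = diff^2 / (MSE (1/n1 + 1/n2)
#' (k - 1)) on (k - 1, N - k) degrees of freedom, which controls the
#' family-wise error over all contrasts. Groups with fewer than 2
#' observations are excluded with a warning.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor).
#' @return data.frame with columns level1, level2, diff (mean level1 -
#'   mean level2), F, p, sig ('***' p < 0.001, '**' < 0.01, '*' < 0.05).
#' @export
scheffePairwise <- function(values, groups) {
  groups <- factor(groups)
  cnt <- table(groups)
  small <- names(cnt)[cnt < 2L]
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups with >= 2 observations",
                   call. = FALSE)
  N <- length(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  sse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  mse <- sse / (N - k)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d <- unname(means[a] - means[b])
    if (mse == 0) {
      Fs <- if (d == 0) 0 else Inf
    } else {
      Fs <- d^2 / (mse * (1 / ns[[a]] + 1 / ns[[b]]) * (k - 1))
    }
    p <- pf(Fs, k - 1, N - k, lower.tail = FALSE)
    data.frame(level1 = a, level2 = b, diff = d, F = unname(Fs),
               p = unname(p),
               sig = if (p < 0.001) "***" else if (p < 0.01) "**"
                     else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare clustered eigenvalues across factor levels
#'
#' For every ordered cluster, groups the member eigenvalues by a
#' configuration factor (e.g. task) and reports all pairwise group mean
#' differences with Scheffe-adjusted significance flags.
#'
#' @param ensemble a clustered \linkS4class{EigenEnsemble}.
#' @param factorName column of the ensemble config to group by
#'   (default "task").
#' @return data.frame with columns cluster (position in `clusterOrder`,
#'   1 = largest mean eigenvalue), clusterId, level1, level2, diff, F, p,
#'   sig.
#' @export
compareClusteredEigenvalues <- function(ensemble, factorName = "task") {
  if (!factorName %in% names(ensemble@config))
    stop("no configuration column '", factorName, "'", call. = FALSE)
  if (!length(ensemble@clusterOrder))
    stop("ensemble is not clustered", call. = FALSE)
  out <- list()
  for (pos in seq_along(ensemble@clusterOrder)) {
    cl <- ensemble@clusterOrder[pos]
    idx <- which(ensemble@clusterLabels == cl)
    g <- ensemble@config[[factorName]][idx]
    if (length(unique(g[duplicated(g) | duplicated(g, fromLast = TRUE)]))
        < 2L)
      next
    tab <- tryCatch(scheffePairwise(ensemble@values[idx], g),
                    error = function(e) NULL)
    if (is.null(tab)) next
    tab <- cbind(cluster = pos, clusterId = cl, tab)
    out[[length(out) + 1L]] <- tab
  }
  if (!length(out))
    return(data.frame(cluster = integer(), clusterId = integer(),
                      level1 = character(), level2 = character(),
                      diff = numeric(), F = numeric(), p = numeric(),
                      sig = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Outlier fence of the ensemble's eigenvalue distributions
#'
#' The upper Tukey fence Q3 + 1.5 IQR of the eigenvalues, computed per
#' configuration and averaged — context for choosing the
#' \code{\link{selectLarge}} cut-off on a given ensemble rather than
#' assuming a universal value.
#'
#' @param ensemble an \linkS4class{EigenEnsemble} (before selection).
#' @return scalar fence value.
#' @export
eigenvalueFence <- function(ensemble) {
  by <- split(ensemble@values, ensemble@config$matrixId)
  mean(vapply(by, function(v)
    unname(stats::quantile(v, 0.75) + 1.5 * stats::IQR(v)), numeric(1)))
}
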