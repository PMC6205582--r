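#' Deterministic k-means++ (d-k-means++) clustering of peak profiles
#'
#' Fits the deterministic variant of k-means++ to a set of input vectors
#' (per-peak smoothed, optionally concatenated, group time profiles).
#' Instead of the randomized k-means++ sampler, the initial centers are
#' produced by a parsimony rule: a seed vector on the edge of the search
#' space is chosen first ([select_seed()]), then centers are added one at
#' a time on the vector farthest from any existing center
#' ([farthest_point_centers()]), stopping either at `k` centers or, when
#' `D_stop` is given, once every vector lies within `D_stop` of a center
#' (the search space is covered at the preferred minimum cluster
#' radius). Lloyd refinement with mean (k-means) or component-wise
#' median (k-medians) updates follows ([lloyd_refine()]). All ties —
#' seed choice, farthest vector, nearest center — break to the lowest
#' index, so the whole fit is deterministic and needs no repeated runs.
#'
#' Because the seed is deliberately extremal, gross outlier vectors can
#' capture it; they can be removed beforehand with
#' [drop_outlier_vectors()] (with mean updates), or `update = "median"`
#' can be used, which relocates such a center robustly.
#'
#' @param x an `mtb_vectors` matrix (see [build_input_vectors()]) or any
#'   numeric matrix with one vector per row.
#' @param k number of clusters (>= 1). Give `k`, `D_stop`, or both
#'   (stopping at whichever is reached first).
#' @param D_stop coverage radius: center generation stops when the
#'   largest vector-to-nearest-center distance falls below it.
#' @param seed_method `"max_dist_from_mean"` (default) or
#'   `"max_abs_time_correlation"` (see [select_seed()]).
#' @param update `"mean"` (k-means) or `"median"` (k-medians) center
#'   update.
#' @param max_iter,tol Lloyd iteration cap and center-shift tolerance.
#' @return An object of class `dkmeanspp`: list with `centers` (k x d
#'   matrix), `cluster` (per-vector assignment), `D_i` (per-vector
#'   distance to its center), `metrics` (named vector `D`,
#'   `D_closest10`, `silhouette`, `BIC`, `WCSS`), `k`, `D_stop`,
#'   `iterations`, `wcss_trace`, `empty_clusters`, and the fitting
#'   settings. Methods: `print`, `summary`, `coef` (centers), `fitted`
#'   (assigned center per vector), `residuals`, `predict`, `plot`.
#' @examples
#' vs <- matrix(c(0, 1, 9, 10), ncol = 1)
#' fit <- dkmeanspp(vs, k = 2)
#' fit$centers   # 0.5 and 9.5
#' @export
dkmeanspp <- function(x, k = NULL, D_stop = NULL,
                      seed_method = c("max_dist_from_mean",
                                      "max_abs_time_correlation"),
                      update = c("mean", "median"),
                      max_iter = 100L, tol = 1e-9) {
  seed_method <- match.arg(seed_method)
  update <- match.arg(update)
  x <- as_vector_matrix(x)
  seed <- select_seed(x, method = seed_method)
  centers <- farthest_point_centers(x, seed = seed, k = k, D_stop = D_stop)
  fit <- lloyd_refine(x, centers, update = update, max_iter = max_iter,
                      tol = tol)
  fit$seed_index <- seed
  fit$seed_method <- seed_method
  fit$D_stop <- D_stop
  fit$method <- "d-k-means++"
  fit
}

as_vector_matrix <- function(x) {
  m <- unclass(as.matrix(x))
  storage.mode(m) <- "double"
  if (nrow(m) < 1) stop("no input vectors")
  if (anyNA(m)) stop("input vectors contain missing values")
  if (is.null(rownames(m))) rownames(m) <- paste0("v", seq_len(nrow(m)))
  attr(m, "layout") <- attr(x, "layout")
  m
}

#' Select the seed vector on the edge of the search space
#'
#' `max_dist_from_mean` picks the vector with the greatest Euclidean
#' distance to the grand mean vector; `max_abs_time_correlation` picks
#' the vector whose values are most strongly (absolutely) Pearson
#' correlated with their time coordinates — a marked monotone profile.
#' Constant vectors have correlation treated as 0. Ties break to the
#' lowest index.
#'
#' @param x input vectors (matrix or `mtb_vectors`).
#' @param method seeding rule (see above).
#' @param times time coordinate per column; defaults to the `layout`
#'   attribute of an `mtb_vectors` input, else the column index.
#' @return The row index of the seed vector.
#' @export
select_seed <- function(x, method = c("max_dist_from_mean",
                                      "max_abs_time_correlation"),
                        times = NULL) {
  method <- match.arg(method)
  m <- as_vector_matrix(x)
  if (method == "max_dist_from_mean") {
    mu <- colMeans(m)
    d2 <- rowSums(sweep(m, 2, mu)^2)
    return(unname(which.max(d2)))
  }
  if (is.null(times)) {
    lay <- attr(m, "layout")
    times <- if (!is.null(lay)) lay$time else seq_len(ncol(m))
  }
  r <- apply(m, 1, function(v)
    if (stats::sd(v) == 0 || stats::sd(times) == 0) 0
    else abs(stats::cor(v, times)))
  unname(which.max(r))
}

#' Farthest-point generation of initial centers
#'
#' Starting from the seed vector, repeatedly computes each vector's
#' squared distance to its nearest center and promotes the vector
#' attaining the maximum (ties to the lowest index) to a new center.
#' Generation stops after `k` centers, or as soon as the maximum
#' distance drops below `D_stop` (whichever comes first when both are
#' given).
#'
#' @param x input vectors.
#' @param seed row index of the seed vector (see [select_seed()]).
#' @param k target number of centers (<= number of vectors).
#' @param D_stop coverage radius (same units as the vectors).
#' @return A centers matrix (rows are the chosen vectors) with attribute
#'   `indices` giving their row indices in `x`.
#' @export
farthest_point_centers <- function(x, seed = select_seed(x), k = NULL,
                                   D_stop = NULL) {
  m <- as_vector_matrix(x)
  n <- nrow(m)
  if (is.null(k) && is.null(D_stop))
    stop("give k, D_stop, or both")
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1) stop("k must be >= 1")
    if (k > n) stop("k = ", k, " exceeds the number of vectors (", n, ")")
  }
  stopifnot(seed >= 1, seed <= n)
  idx <- as.integer(unname(seed))
  d2 <- rowSums(sweep(m, 2, m[seed, ])^2)
  repeat {
    if (!is.null(k) && length(idx) >= k) break
    if (!is.null(D_stop) && sqrt(max(d2)) < D_stop) break
    if (length(idx) >= n) break
    new <- unname(which.max(d2))  # first max = lowest index on ties
    idx <- c(idx, new)
    d2 <- pmin(d2, rowSums(sweep(m, 2, m[new, ])^2))
  }
  centers <- m[idx, , drop = FALSE]
  rownames(centers) <- NULL
  attr(centers, "indices") <- idx
  centers
}

# n x k squared Euclidean distances from rows of m to rows of centers
dist2_to_centers <- function(m, centers) {
  cc <- tcrossprod(m, centers)                    # n x k
  d2 <- outer(rowSums(m^2), rowSums(centers^2), "+") - 2 * cc
  pmax(d2, 0)
}

#' Lloyd refinement of a set of centers
#'
#' Alternates nearest-center assignment (Euclidean, ties to the lowest
#' center index) with center updates (component-wise mean for k-means or
#' median for k-medians) until the assignment is stable, the largest
#' center shift falls below `tol`, or `max_iter` is reached. A cluster
#' left empty keeps its center unchanged and is flagged, preserving
#' determinism.
#'
#' @param x input vectors.
#' @param centers initial centers matrix (e.g. from
#'   [farthest_point_centers()]).
#' @param update `"mean"` or `"median"`.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   maximum center displacement.
#' @return A `dkmeanspp` model object (see [dkmeanspp()]).
#' @export
lloyd_refine <- function(x, centers, update = c("mean", "median"),
                         max_iter = 100L, tol = 1e-9) {
  update <- match.arg(update)
  m <- as_vector_matrix(x)
  centers <- as.matrix(centers)
  if (nrow(centers) < 1) stop("no initial centers")
  if (ncol(centers) != ncol(m)) stop("center/vector dimension mismatch")
  k <- nrow(centers)
  f <- if (update == "mean") colMeans else function(b) apply(b, 2, stats::median)

  assign_old <- rep(-1L, nrow(m))
  wcss_trace <- numeric(0)
  empty <- integer(0)
  iter <- 0L
  repeat {
    d2 <- dist2_to_centers(m, centers)
    assignment <- max.col(-d2, ties.method = "first")
    wcss_trace <- c(wcss_trace, sum(d2[cbind(seq_len(nrow(m)), assignment)]))
    if (identical(assignment, assign_old) || iter >= max_iter) break
    assign_old <- assignment
    new_centers <- centers
    for (j in seq_len(k)) {
      rows <- which(assignment == j)
      if (length(rows) == 0) empty <- union(empty, j)
      else new_centers[j, ] <- f(m[rows, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    iter <- iter + 1L
    if (shift < tol) {
      d2 <- dist2_to_centers(m, centers)
      assignment <- max.col(-d2, ties.method = "first")
      wcss_trace <- c(wcss_trace,
                      sum(d2[cbind(seq_len(nrow(m)), assignment)]))
      break
    }
  }
  new_cluster_model(m, centers, assignment, update = update,
                    iterations = iter, wcss_trace = wcss_trace,
                    empty_clusters = sort(empty))
}

new_cluster_model <- function(m, centers, assignment, update, iterations,
                              wcss_trace, empty_clusters = integer(0),
                              method = "d-k-means++") {
  d2 <- dist2_to_centers(m, centers)
  D_i <- sqrt(d2[cbind(seq_len(nrow(m)), assignment)])
  names(D_i) <- rownames(m)
  k <- nrow(centers)
  rownames(centers) <- paste0("c", seq_len(k))
  sil <- if (k >= 2 && length(unique(assignment)) >= 2)
    mean(sil_widths(assignment, m))
  else NA_real_
  model <- structure(
    list(centers = centers, cluster = stats::setNames(assignment, rownames(m)),
         D_i = D_i, k = k, update = update, method = method,
         iterations = iterations, wcss_trace = wcss_trace,
         empty_clusters = empty_clusters,
         n = nrow(m), d = ncol(m), x = m,
         layout = attr(m, "layout")),
    class = "dkmeanspp")
  model$metrics <- c(D = mean(D_i),
                     D_closest10 = dispersion(model, 0.10),
                     silhouette = sil,
                     BIC = bic_score(model),
                     WCSS = sum(d2[cbind(seq_len(nrow(m)), assignment)]))
  model
}

#' Best-of-runs randomized k-means baseline
#'
#' Standard Lloyd k-means started from `runs` uniform-random draws of
#' `k` distinct input vectors, keeping the run with the lowest
#' within-cluster sum of squares. Fully reproducible from `rng_seed`.
#' Serves as the stochastic reference the deterministic fit is compared
#' against.
#'
#' @param x input vectors.
#' @param k number of clusters.
#' @param runs number of random restarts (>= 1).
#' @param rng_seed integer seed driving all restarts.
#' @return A `dkmeanspp` model object with `method = "kmeans"`.
#' @export
kmeans_baseline <- function(x, k, runs = 100L, rng_seed = 1L) {
  m <- as_vector_matrix(x)
  if (k > nrow(m)) stop("k exceeds the number of vectors")
  stopifnot(runs >= 1)
  best <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  for (r in seq_len(runs)) {
    idx <- sample.int(nrow(m), k)
    init <- m[idx, , drop = FALSE]
    # a 1x1 centers matrix would be read by stats::kmeans as a count
    if (all(dim(init) == c(1, 1))) init <- 1L
    km <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = init,
                                     iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("no k-means run succeeded (duplicate vectors?)")
  centers <- unname(best$centers)
  # enforce the package's assignment invariant (nearest center, ties low)
  d2 <- dist2_to_centers(m, centers)
  assignment <- max.col(-d2, ties.method = "first")
  new_cluster_model(m, centers, assignment, update = "mean",
                    iterations = best$iter,
                    wcss_trace = best$tot.withinss, method = "kmeans")
}

#' Mean distance of the closest fraction of vectors to their centers
#'
#' `dispersion(model, 1)` is D, the mean distance of every vector to its
#' assigned center; `dispersion(model, 0.1)` is D_closest10, the mean
#' over the 10\% of vectors closest to their centers — a measure of how
#' tight the cluster cores are irrespective of stragglers.
#'
#' @param model a `dkmeanspp` model.
#' @param fraction fraction of vectors, in (0, 1]; the
#'   `ceiling(fraction * n)` vectors with smallest distance are used.
#' @return The mean distance.
#' @export
dispersion <- function(model, fraction = 1) {
  stopifnot(inherits(model, "dkmeanspp"), fraction > 0, fraction <= 1)
  d <- sort(model$D_i)
  mean(d[seq_len(ceiling(fraction * length(d)))])
}

#' Silhouette widths of a cluster model
#'
#' Standard silhouette `s = (b - a) / max(a, b)` with Euclidean
#' distances (a: mean distance to the own cluster, b: mean distance to
#' the nearest other cluster); vectors in singleton clusters score 0.
#'
#' @param model a `dkmeanspp` model with k >= 2.
#' @return List with `widths` (per vector) and `mean`.
#' @export
silhouette_width <- function(model) {
  stopifnot(inherits(model, "dkmeanspp"))
  if (model$k < 2) stop("silhouette needs k >= 2")
  widths <- stats::setNames(sil_widths(unname(model$cluster), model$x),
                            names(model$cluster))
  list(widths = widths, mean = mean(widths))
}

# cluster::silhouette gives NA (not a matrix) when every cluster is a
# singleton; the 0-by-convention then applies to all vectors
sil_widths <- function(assignment, m) {
  if (all(tabulate(assignment) <= 1)) return(rep(0, nrow(m)))
  cluster::silhouette(assignment, stats::dist(m))[, "sil_width"]
}

#' Spherical-Gaussian BIC of a cluster model
#'
#' Scores the clustering under an equal-variance spherical Gaussian
#' model: the pooled maximum-likelihood variance over all
#' vector-to-center residuals gives the log-likelihood, penalized by
#' `(q / 2) * log(n)` with `q = k * d + 1` free parameters (k centers of
#' dimension d plus the shared variance). Higher is better; comparing
#' across k selects the cluster count. The variance is floored at 1e-12;
#' a fit at the floor (e.g. k = n) is flagged degenerate via the
#' `"degenerate"` attribute.
#'
#' @param model a `dkmeanspp` model.
#' @return The BIC value (attribute `degenerate` is TRUE at the variance
#'   floor).
#' @export
bic_score <- function(model) {
  stopifnot(inherits(model, "dkmeanspp"))
  n <- model$n
  d <- model$d
  rss <- sum(model$D_i^2)
  sigma2 <- rss / (n * d)
  degenerate <- sigma2 < 1e-12
  sigma2 <- max(sigma2, 1e-12)
  loglik <- -(n * d / 2) * log(2 * pi * sigma2) - rss / (2 * sigma2)
  q <- model$k * d + 1
  structure(loglik - (q / 2) * log(n), degenerate = degenerate)
}

#' Drop extreme outlier vectors before clustering
#'
#' Optional pre-step for mean-update clustering: the seed rule favors
#' extremal vectors, so gross outliers can distort seeding. Vectors
#' whose distance to the grand mean exceeds `z` standard deviations of
#' the distance distribution are removed.
#'
#' @param x input vectors.
#' @param z z-score threshold (default 3).
#' @return The retained vectors (same class/attributes), with attribute
#'   `dropped` naming the removed ones.
#' @export
drop_outlier_vectors <- function(x, z = 3) {
  m <- as_vector_matrix(x)
  d <- sqrt(rowSums(sweep(m, 2, colMeans(m))^2))
  keep <- d <= mean(d) + z * stats::sd(d)
  out <- x[keep, , drop = FALSE]
  attr(out, "layout") <- attr(x, "layout")
  attr(out, "mode") <- attr(x, "mode")
  class(out) <- class(x)
  attr(out, "dropped") <- rownames(m)[!keep]
  out
}

#' Fit d-k-means++ (or the baseline) over a range of k
#'
#' Convenience sweep for choosing the number of clusters: fits each k
#' and tabulates mean silhouette, BIC, D and D_closest10.
#'
#' @param x input vectors.
#' @param ks integer vector of cluster counts to try (k >= 2).
#' @param ... passed to [dkmeanspp()].
#' @return Data frame with one row per k.
#' @export
sweep_k <- function(x, ks, ...) {
  rows <- lapply(ks, function(k) {
    fit <- dkmeanspp(x, k = k, ...)
    data.frame(k = k, D = fit$metrics[["D"]],
               D_closest10 = fit$metrics[["D_closest10"]],
               silhouette = fit$metrics[["silhouette"]],
               BIC = as.numeric(fit$metrics[["BIC"]]))
  })
  do.call(rbind, rows)
}

#' @export
print.dkmeanspp <- function(x, ...) {
  cat(x$method, " clustering: ", x$n, " vectors, k = ", x$k,
      " (", x$update, " update)\n", sep = "")
  cat("  D = ", signif(x$metrics[["D"]], 4),
      ", D_closest10 = ", signif(x$metrics[["D_closest10"]], 4),
      if (!is.na(x$metrics[["silhouette"]]))
        paste0(", mean silhouette = ", signif(x$metrics[["silhouette"]], 4)),
      "\n", sep = "")
  cat("  cluster sizes: ", paste(tabulate(x$cluster, x$k), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.dkmeanspp <- function(object, ...) {
  sizes <- tabulate(object$cluster, object$k)
  per <- data.frame(cluster = seq_len(object$k), size = sizes,
                    D = as.numeric(tapply(object$D_i, factor(object$cluster,
                                          levels = seq_len(object$k)), mean)))
  out <- list(call_method = object$method, k = object$k, n = object$n,
              metrics = object$metrics, per_cluster = per,
              empty_clusters = object$empty_clusters,
              iterations = object$iterations)
  class(out) <- "summary.dkmeanspp"
  out
}

#' @export
print.summary.dkmeanspp <- function(x, ...) {
  cat(x$call_method, ": k = ", x$k, ", n = ", x$n, ", ",
      x$iterations, " Lloyd iterations\n", sep = "")
  print(round(x$metrics, 4))
  cat("per cluster:\n")
  print(x$per_cluster, row.names = FALSE)
  if (length(x$empty_clusters))
    cat("empty clusters (centers frozen): ",
        paste(x$empty_clusters, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.dkmeanspp <- function(object, ...) object$centers

#' @export
fitted.dkmeanspp <- function(object, ...)
  object$centers[object$cluster, , drop = FALSE]

#' @export
residuals.dkmeanspp <- function(object, ...)
  object$x - fitted(object)

#' Assign new vectors to the fitted centers
#'
#' @param object a `dkmeanspp` model.
#' @param newdata matrix of vectors (columns matching the training
#'   layout); defaults to the training vectors.
#' @param ... unused.
#' @return Integer vector of cluster assignments (nearest center,
#'   ties to the lowest index).
#' @export
predict.dkmeanspp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$cluster)
  m <- as_vector_matrix(newdata)
  if (ncol(m) != object$d) stop("newdata dimension mismatch")
  d2 <- dist2_to_centers(m, object$centers)
  stats::setNames(max.col(-d2, ties.method = "first"), rownames(m))
}

#' Small-multiple plot of the fitted clusters
#'
#' One panel per cluster: member profiles in grey, the center in color.
#' Concatenated group blocks (from the vectors' layout) are separated by
#' dotted vertical lines.
#'
#' @param x a `dkmeanspp` model.
#' @param max_panels largest number of panels to draw.
#' @param ... passed to `matplot`.
#' @export
plot.dkmeanspp <- function(x, max_panels = 25, ...) {
  k <- min(x$k, max_panels)
  nc <- ceiling(sqrt(k))
  nr <- ceiling(k / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2, 2, 1.5, 0.5))
  on.exit(graphics::par(op))
  lay <- x$layout
  breaks <- if (!is.null(lay) && length(unique(lay$group)) > 1)
    which(diff(as.integer(factor(lay$group, levels = unique(lay$group)))) != 0) + 0.5
  else NULL
  for (j in seq_len(k)) {
    rows <- which(x$cluster == j)
    ylim <- range(x$x[rows, , drop = FALSE], x$centers[j, ])
    graphics::matplot(t(x$x[rows, , drop = FALSE]), type = "l", lty = 1,
                      col = grDevices::adjustcolor("grey40", 0.4),
                      ylim = ylim, xlab = "", ylab = "",
                      main = paste0("cluster ", j, " (n=", length(rows), ")"),
                      ...)
    graphics::lines(x$centers[j, ], col = "firebrick", lwd = 2)
    if (!is.null(breaks)) graphics::abline(v = breaks, lty = 3)
  }
  invisible(x)
}

#' Write a cluster model's assignments, centers and metrics
#'
#' @param model a `dkmeanspp` model.
#' @param dir output directory; writes `assignments.csv`, `centers.csv`
#'   and `metrics.json`.
#' @return Invisibly, the three paths.
#' @export
write_cluster_model <- function(model, dir) {
  stopifnot(inherits(model, "dkmeanspp"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ap <- file.path(dir, "assignments.csv")
  cp <- file.path(dir, "centers.csv")
  mp <- file.path(dir, "metrics.json")
  utils::write.csv(data.frame(vector = names(model$cluster),
                              cluster = as.integer(model$cluster),
                              D_i = model$D_i, row.names = NULL),
                   ap, row.names = FALSE)
  utils::write.csv(data.frame(cluster = seq_len(model$k), model$centers,
                              check.names = FALSE),
                   cp, row.names = FALSE)
  jsonlite::write_json(as.list(c(model$metrics,
                                 k = model$k, n = model$n,
                                 iterations = model$iterations)),
                       mp, auto_unbox = TRUE, digits = NA)
  invisible(c(assignments = ap, centers = cp, metrics = mp))
}
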