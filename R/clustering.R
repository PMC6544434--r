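# Functional cell-type discovery: over-cluster trial-averaged deconvolved
# response profiles with Ward linkage on Euclidean distances, prune clusters
# whose homogeneity (mean pairwise Pearson correlation) is at or below 0.4
# into a non-responsive pool, then re-aggregate pooled cells whose profile
# correlates > 0.4 with a kept cluster centroid.

#' Mean pairwise Pearson correlation per cluster
#'
#' Cluster homogeneity: mean over all unordered member pairs of the Pearson
#' correlation between their profile vectors. Singleton clusters are defined
#' as perfectly homogeneous (1). Zero-variance profiles contribute
#' correlation 0 to their pairs (with a warning).
#'
#' @param profiles neurons x features matrix.
#' @param labels integer cluster id per neuron (0 = pool, ignored).
#' @return named numeric vector, one value per non-pool cluster id.
#' @export
homogeneity <- function(profiles, labels) {
  ids <- sort(unique(labels[labels > 0]))
  warned <- FALSE
  out <- vapply(ids, function(k) {
    members <- which(labels == k)
    if (length(members) < 2) return(1)
    X <- t(profiles[members, , drop = FALSE])
    sds <- apply(X, 2L, stats::sd)
    C <- suppressWarnings(stats::cor(X))
    if (any(sds == 0)) {
      if (!warned) {
        warning("zero-variance profile(s); their correlations set to 0")
        warned <<- TRUE
      }
      C[sds == 0, ] <- 0
      C[, sds == 0] <- 0
    }
    mean(C[upper.tri(C)])
  }, numeric(1))
  names(out) <- ids
  out
}

#' Percentage of variance explained by the centroid assignment
#'
#' `100 * (1 - SS_residual / SS_total)` over clustered (non-pool) neurons,
#' where the residual is each profile minus its assigned centroid and the
#' total sum of squares is about the grand mean profile. Invariant to a
#' global positive rescaling of the dataset.
#'
#' @param profiles neurons x features matrix.
#' @param labels cluster id per neuron (0 = pool, excluded).
#' @param centroids cluster id x features matrix with rownames = cluster ids.
#' @return percentage in `[0, 100]` (can be negative for absurd assignments).
#' @export
explained_variance <- function(profiles, labels, centroids) {
  idx <- which(labels > 0)
  if (length(idx) == 0) return(NA_real_)
  X <- profiles[idx, , drop = FALSE]
  R <- X - centroids[as.character(labels[idx]), , drop = FALSE]
  grand <- colMeans(X)
  sst <- sum(sweep(X, 2L, grand)^2)
  if (sst == 0) return(100)
  100 * (1 - sum(R^2) / sst)
}

cluster_centroids <- function(profiles, labels) {
  ids <- sort(unique(labels[labels > 0]))
  ctr <- t(vapply(ids, function(k) {
    colMeans(profiles[labels == k, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(ctr) <- ids
  ctr
}

#' Over-cluster response profiles (Ward linkage, Euclidean metric)
#'
#' Agglomerative hierarchical clustering of per-neuron concatenated response
#' profiles, cut at `n_over` clusters. Over-clustering (25 for V1-like data,
#' 100 for auditory-cortex-like data) ensures each response type is
#' represented by at least one cluster; pruning and re-aggregation follow.
#' Deterministic given the input order.
#'
#' @param profiles neurons x features matrix (finite; NaN rejected with the
#'   offending neurons named).
#' @param n_over number of clusters to cut at.
#' @return object of class `ClusterModel`: `labels` (cluster id per neuron,
#'   0 reserved for the pool), `centroids`, `homogeneity`,
#'   `explained_variance_pct` (per cluster and total), `linkage_tree`
#'   (hclust), `n_over`.
#' @export
cluster_profiles <- function(profiles, n_over) {
  profiles <- as.matrix(profiles)
  bad <- which(apply(profiles, 1L, function(x) any(!is.finite(x))))
  if (length(bad) > 0) {
    xmv1_stop(paste0("non-finite profile(s) for neuron(s): ",
                     paste(bad, collapse = ", ")), "xmv1_bad_profiles")
  }
  if (nrow(profiles) < n_over) {
    xmv1_stop("need at least n_over neurons", "xmv1_bad_argument")
  }
  hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  labels <- stats::cutree(hc, k = n_over)
  ctr <- cluster_centroids(profiles, labels)
  hom <- homogeneity(profiles, labels)
  ev_per <- vapply(rownames(ctr), function(k) {
    sub <- labels == as.integer(k)
    explained_variance(profiles[sub, , drop = FALSE],
                       rep(as.integer(k), sum(sub)),
                       ctr[k, , drop = FALSE])
  }, numeric(1))
  structure(list(labels = labels, centroids = ctr, homogeneity = hom,
                 explained_variance_pct = list(
                   per_cluster = ev_per,
                   total = explained_variance(profiles, labels, ctr)),
                 linkage_tree = hc, n_over = n_over),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  kept <- sum(x$labels > 0)
  cat(sprintf("ClusterModel: %d clusters, %d/%d neurons clustered, total EV %.1f%%\n",
              nrow(x$centroids), kept, length(x$labels),
              x$explained_variance_pct$total))
  invisible(x)
}

#' Prune inhomogeneous clusters into the non-responsive pool
#'
#' Clusters whose homogeneity is at or below `hom_threshold` (default 0.4),
#' plus any cluster on the manual exclusion list (for clusters that capture
#' correlated noise), are merged into pool 0. Kept clusters are unchanged.
#'
#' @param model a `ClusterModel`.
#' @param profiles the profile matrix the model was fitted on.
#' @param hom_threshold homogeneity threshold (default 0.4; keep if strictly
#'   greater).
#' @param exclude integer ids of clusters to force into the pool.
#' @return updated `ClusterModel` (labels, centroids, homogeneity restricted
#'   to kept clusters; `pruned` records the discarded ids).
#' @export
prune_clusters <- function(model, profiles, hom_threshold = 0.4,
                           exclude = integer(0)) {
  stopifnot(inherits(model, "ClusterModel"))
  ids <- as.integer(names(model$homogeneity))
  drop_ids <- union(ids[model$homogeneity <= hom_threshold],
                    as.integer(exclude))
  labels <- model$labels
  labels[labels %in% drop_ids] <- 0L
  keep_ids <- setdiff(ids, drop_ids)
  model$labels <- labels
  model$centroids <- model$centroids[as.character(keep_ids), , drop = FALSE]
  model$homogeneity <- model$homogeneity[as.character(keep_ids)]
  model$pruned <- drop_ids
  model$hom_threshold <- hom_threshold
  if (length(keep_ids) > 0) {
    model$explained_variance_pct$total <-
      explained_variance(profiles, labels, model$centroids)
  } else {
    model$explained_variance_pct$total <- NA_real_
  }
  model
}

#' Re-aggregate pooled neurons onto kept cluster centroids
#'
#' Each pooled neuron whose profile correlates more than `corr_threshold`
#' with some kept centroid is assigned to the best-correlated cluster;
#' otherwise it stays in the pool. Centroids are NOT recomputed (the
#' stability of centroids under re-aggregation is a testable property, not an
#' assumption).
#'
#' @param model pruned `ClusterModel`.
#' @param profiles profile matrix.
#' @param corr_threshold correlation threshold (default 0.4).
#' @return updated model; `n_reaggregated` counts the rescued neurons.
#' @export
reaggregate <- function(model, profiles, corr_threshold = 0.4) {
  stopifnot(inherits(model, "ClusterModel"))
  pool <- which(model$labels == 0L)
  if (length(pool) == 0 || nrow(model$centroids) == 0) {
    model$n_reaggregated <- 0L
    return(model)
  }
  ctr <- t(model$centroids)
  n_re <- 0L
  for (i in pool) {
    p <- profiles[i, ]
    if (stats::sd(p) == 0) next
    cc <- suppressWarnings(stats::cor(p, ctr))
    cc[!is.finite(cc)] <- 0
    j <- which.max(cc)
    if (cc[j] > corr_threshold) {
      model$labels[i] <- as.integer(colnames(ctr)[j])
      n_re <- n_re + 1L
    }
  }
  model$n_reaggregated <- n_re
  model
}

#' Fractions of neurons per functional label
#'
#' Fractions over clustered neurons (pool excluded), summing to one.
#'
#' @param labels cluster id per neuron (0 = pool).
#' @param type_map named character vector mapping cluster id (as character)
#'   to functional label; must cover every kept cluster.
#' @return named numeric vector of fractions per functional label.
#' @export
type_fractions <- function(labels, type_map) {
  used <- labels[labels > 0]
  if (length(used) == 0) return(stats::setNames(numeric(0), character(0)))
  unmapped <- setdiff(as.character(unique(used)), names(type_map))
  if (length(unmapped) > 0) {
    xmv1_stop(paste0("unmapped cluster id(s): ",
                     paste(unmapped, collapse = ", ")), "xmv1_unmapped_cluster")
  }
  f <- table(factor(type_map[as.character(used)],
                    levels = unique(unname(type_map))))
  f <- f / sum(f)
  stats::setNames(as.numeric(f), names(f))
}

#' Label kept clusters with functional archetypes
#'
#' Rule-based labelling: each kept centroid is matched to the canonical
#' archetype whose rate template (defined purely by peak-timing and
#' stimulus-preference rules, see [make_rate_templates()]) it correlates with
#' best, after passing the templates through the same calcium-kernel
#' convolution, deconvolution and smoothing as the data. The paper's manual
#' inspection step becomes this reproducible nearest-archetype rule.
#'
#' @param model pruned `ClusterModel`.
#' @param templates archetype templates from [make_rate_templates()].
#' @param stimuli stimulus order used to build the profile matrix.
#' @param smooth_window smoothing window applied to the data profiles (s).
#' @return named character vector: functional label per kept cluster id.
#' @export
label_clusters <- function(model, templates, stimuli,
                           smooth_window = 0.190) {
  fr <- attr(templates, "frame_rate")
  types <- setdiff(names(templates), "nonresponsive")
  arche <- t(vapply(types, function(ty) {
    v <- unlist(templates[[ty]][stimuli], use.names = FALSE)
    smooth_traces(v, fr, smooth_window)
  }, numeric(length(stimuli) * length(attr(templates, "time")))))
  out <- character(0)
  for (k in rownames(model$centroids)) {
    cc <- suppressWarnings(stats::cor(model$centroids[k, ], t(arche)))
    cc[!is.finite(cc)] <- 0
    out[k] <- types[which.max(cc)]
  }
  out
}

#' Match cluster labels to ground-truth types
#'
#' Best cluster-to-type matching by majority vote: each kept cluster maps to
#' the most frequent ground-truth label among its members; the pool maps to
#' "nonresponsive". Accuracy is the fraction of neurons whose mapped label
#' equals their true label.
#'
#' @param labels cluster id per neuron (0 = pool).
#' @param truth character vector of ground-truth type labels.
#' @return list: `accuracy`, `mapping` (named character vector per cluster),
#'   `mapped` (per-neuron mapped labels).
#' @export
match_to_truth <- function(labels, truth) {
  ids <- sort(unique(labels[labels > 0]))
  mapping <- vapply(ids, function(k) {
    names(which.max(table(truth[labels == k])))
  }, character(1))
  names(mapping) <- ids
  mapped <- ifelse(labels == 0, "nonresponsive", mapping[as.character(labels)])
  list(accuracy = mean(mapped == truth), mapping = mapping, mapped = mapped)
}

#' Full clustering pipeline: over-cluster, prune, re-aggregate
#'
#' @param profiles neurons x features matrix.
#' @param n_over over-clustering cut (default 25, V1-like).
#' @param hom_threshold,reagg_threshold,exclude stage parameters.
#' @return final `ClusterModel` (with `model$initial` holding the
#'   pre-pruning labels).
#' @export
cluster_pipeline <- function(profiles, n_over = 25, hom_threshold = 0.4,
                             reagg_threshold = 0.4, exclude = integer(0)) {
  m0 <- cluster_profiles(profiles, n_over)
  m <- prune_clusters(m0, profiles, hom_threshold, exclude)
  m <- reaggregate(m, profiles, reagg_threshold)
  m$explained_variance_pct$total <-
    explained_variance(profiles, m$labels, m$centroids)
  m$initial <- m0$labels
  m
}
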