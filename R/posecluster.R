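# Clustering of heterodimer docking poses.
#
# All poses are first placed in a common frame by rigid Procrustes
# superposition (rotation + translation, no scaling, no reflection) of
# their reference subunits. Two poses are then "similar" when (i) the angle
# at the reference centroid between the directions to their two mobile
# centroids is below 45 degrees AND (ii) the minimum over X/Y/Z of the
# per-axis Pearson correlation of their mobile coordinates exceeds 0.5.
# Clusters are maximal cliques of at least four pairwise-similar poses,
# merged while any two cliques share a pose.

#' Rigid (Kabsch) superposition of one point set onto another
#'
#' Least-squares rotation + translation, scaling excluded. The rotation is
#' forced to be proper (determinant +1) by sign-correcting the smallest
#' singular direction, so a reflection can never be returned. Collinear or
#' coincident source points make the rotation ill-determined and raise an
#' error.
#'
#' @param x Numeric matrix (n x 3), points to move.
#' @param target Numeric matrix (n x 3), points to match.
#' @return List with \code{rot} (3 x 3, det +1), \code{shift} (length 3);
#'   the fitted map is \code{x \%*\% t(rot) + shift}.
#' @export
kabsch <- function(x, target) {
  x <- as.matrix(x); target <- as.matrix(target)
  if (!all(dim(x) == dim(target)) || ncol(x) != 3L)
    stop_nodkey("point sets must both be n x 3 with equal n")
  cx <- centroid(x); ct <- centroid(target)
  xc <- sweep(x, 2, cx); tc <- sweep(target, 2, ct)
  h <- crossprod(xc, tc)
  sv <- svd(h)
  scale_ref <- sv$d[1L]
  if (scale_ref == 0 || sv$d[2L] / scale_ref < 1e-8)
    stop_nodkey("degenerate (collinear or coincident) points: ",
                "rotation is ill-determined")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rot = rot, shift = as.numeric(ct - rot %*% cx))
}

apply_rigid <- function(m, rot, shift) {
  m %*% t(rot) + matrix(shift, nrow(m), 3, byrow = TRUE)
}

# Canonical frame of a point cloud: centroid at the origin, coordinate
# axes along the principal axes (decreasing variance), each axis signed so
# the cloud's third moment along it is non-negative, and the third axis
# completed as a cross product so the frame is always right-handed. The
# construction depends only on the cloud's internal geometry, which makes
# downstream per-axis correlations invariant to any global rigid motion
# applied before superposition.
canonical_frame <- function(x) {
  ctr <- centroid(x)
  xc <- sweep(x, 2, ctr)
  eig <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  v <- eig$vectors                 # columns ordered by decreasing variance
  for (k in 1:2) {
    skew <- sum((xc %*% v[, k])^3)
    if (skew < 0) v[, k] <- -v[, k]
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  list(rot = t(v), shift = as.numeric(-t(v) %*% ctr))
}

#' Superpose all poses onto a reference pose
#'
#' Each pose's reference subunit is fitted onto the reference pose's
#' reference subunit by \code{\link{kabsch}}; the same rigid map is applied
#' to its mobile subunit. The common frame is then canonicalized from the
#' reference subunit's own geometry (centroid at the origin, principal
#' axes as coordinate axes), so all downstream measures are independent of
#' the frame the poses happened to arrive in.
#'
#' @param poses A \code{\link{dimer_poses}} set with equal reference-atom
#'   counts.
#' @param reference_pose_id Pose to align onto; defaults to the first.
#' @return The superposed \code{dimer_poses} set, with attribute
#'   \code{superposed_on}.
#' @export
superpose_poses <- function(poses, reference_pose_id = NULL) {
  stopifnot(inherits(poses, "dimer_poses"))
  ids <- names(poses)
  reference_pose_id <- reference_pose_id %||% ids[1L]
  if (!reference_pose_id %in% ids)
    stop_nodkey("reference pose not found: ", reference_pose_id)
  n_ref <- nrow(poses[[reference_pose_id]]$ref)
  target <- poses[[reference_pose_id]]$ref
  canon <- canonical_frame(target)
  target <- apply_rigid(target, canon$rot, canon$shift)
  out <- lapply(poses, function(p) {
    if (nrow(p$ref) != n_ref)
      stop_nodkey("pose ", p$pose_id, ": reference-atom count (",
                  nrow(p$ref), ") differs from reference pose (", n_ref, ")")
    fit <- kabsch(p$ref, target)
    p$ref <- apply_rigid(p$ref, fit$rot, fit$shift)
    p$mob <- apply_rigid(p$mob, fit$rot, fit$shift)
    p
  })
  res <- dimer_poses(out)
  attr(res, "superposed_on") <- reference_pose_id
  res
}

#' Angle between two mobile-subunit placements
#'
#' The angle at \code{vertex} (the shared reference-subunit centroid after
#' superposition) between the vectors pointing to the two mobile-subunit
#' centroids, in degrees within \code{[0, 180]}.
#'
#' @param pose_i,pose_j \code{\link{dimer_pose}} objects in a common frame.
#' @param vertex Numeric length-3 vertex of the angle.
#' @return Angle in degrees.
#' @export
pose_angle <- function(pose_i, pose_j, vertex) {
  u <- centroid(pose_i$mob) - vertex
  v <- centroid(pose_j$mob) - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_nodkey("mobile-subunit centroid coincides with the angle vertex")
  acos(min(1, max(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# Pearson correlation tolerating zero-variance axes:
# both constant -> 1, one constant -> 0 (with a warning).
axis_correlation <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    warning("zero-variance coordinate axis in correlation", call. = FALSE)
    return(if (sa == 0 && sb == 0) 1 else 0)
  }
  stats::cor(a, b)
}

#' Minimum per-axis correlation between two mobile subunits
#'
#' Pearson correlation of corresponding atoms' X, Y and Z coordinates;
#' the minimum of the three is returned.
#'
#' @inheritParams pose_angle
#' @return A number in \code{[-1, 1]}.
#' @export
pose_min_correlation <- function(pose_i, pose_j) {
  a <- pose_i$mob; b <- pose_j$mob
  if (nrow(a) != nrow(b))
    stop_nodkey("mobile-subunit atom counts differ between poses ",
                pose_i$pose_id, " and ", pose_j$pose_id)
  min(vapply(1:3, function(k) axis_correlation(a[, k], b[, k]), numeric(1)))
}

#' Pairwise similarity of superposed poses
#'
#' @param poses A superposed \code{\link{dimer_poses}} set (see
#'   \code{\link{superpose_poses}}).
#' @param angle_max Angle threshold in degrees; similarity requires a
#'   strictly smaller angle.
#' @param corr_min Correlation threshold; similarity requires a strictly
#'   larger minimum axis correlation.
#' @return Symmetric logical matrix (diagonal \code{FALSE}) with attributes
#'   \code{angle} and \code{corr} holding the measure matrices.
#' @export
similarity_matrix <- function(poses, angle_max = 45, corr_min = 0.5) {
  stopifnot(inherits(poses, "dimer_poses"))
  ref_id <- attr(poses, "superposed_on")
  if (is.null(ref_id))
    stop_nodkey("poses must be superposed first (see superpose_poses)")
  vertex <- centroid(poses[[ref_id]]$ref)
  n <- length(poses)
  ids <- names(poses)
  ang <- matrix(0, n, n, dimnames = list(ids, ids))
  cor_ <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    ang[i, j] <- ang[j, i] <- pose_angle(poses[[i]], poses[[j]], vertex)
    cor_[i, j] <- cor_[j, i] <- pose_min_correlation(poses[[i]], poses[[j]])
  }
  sim <- ang < angle_max & cor_ > corr_min
  diag(sim) <- FALSE
  attr(sim, "angle") <- ang
  attr(sim, "corr") <- cor_
  sim
}

#' Long-format pairwise pose measures
#'
#' @param sim A matrix from \code{\link{similarity_matrix}}.
#' @return Data frame with columns \code{pose_i}, \code{pose_j},
#'   \code{angle_deg}, \code{min_axis_corr}, \code{similar} (upper
#'   triangle only).
#' @export
pairwise_pose_measures <- function(sim) {
  ids <- rownames(sim)
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  data.frame(pose_i = ids[idx[, 1]], pose_j = ids[idx[, 2]],
             angle_deg = attr(sim, "angle")[idx],
             min_axis_corr = attr(sim, "corr")[idx],
             similar = sim[idx])
}

#' Cluster poses from a binary similarity matrix
#'
#' Enumerates maximal cliques of at least \code{min_group} pairwise-similar
#' poses, then merges cliques sharing any pose until the clusters are
#' disjoint. Poses in no clique of sufficient size remain unclustered.
#'
#' @param sim Symmetric logical similarity matrix with pose ids as
#'   dimnames.
#' @param min_group Minimum clique size (default 4).
#' @return Object of class \code{pose_clusters}: list with \code{clusters}
#'   (list of sorted pose-id vectors), \code{unclustered} (sorted pose-id
#'   vector) and \code{representatives} (\code{NULL} until
#'   \code{\link{pick_representatives}} is used).
#' @export
find_clusters <- function(sim, min_group = 4) {
  if (is.null(rownames(sim))) {
    ids <- sprintf("pose%02d", seq_len(nrow(sim)))
    dimnames(sim) <- list(ids, ids)
  }
  ids <- rownames(sim)
  if (!isTRUE(all.equal(unname(sim), unname(t(sim)))))
    stop_nodkey("similarity matrix must be symmetric")
  if (length(ids) == 0L)
    return(structure(list(clusters = list(), unclustered = character(0),
                          representatives = NULL), class = "pose_clusters"))
  g <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g, min = min_group)
  cliques <- lapply(cliques, function(cl) sort(ids[as.integer(cl)]))
  clusters <- merge_overlapping(cliques)
  clustered <- unlist(clusters)
  structure(list(clusters = clusters,
                 unclustered = sort(setdiff(ids, clustered)),
                 representatives = NULL),
            class = "pose_clusters")
}

# Merge sets sharing any element until a fixed point; returns disjoint,
# sorted sets ordered by first member.
merge_overlapping <- function(sets) {
  sets <- lapply(sets, unique)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(sets)) {
      j <- i + 1L
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, character(1), 1L))]
}

#' @export
print.pose_clusters <- function(x, ...) {
  cat("Pose clustering:", length(x$clusters), "cluster(s),",
      length(x$unclustered), "unclustered pose(s)\n")
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d (%d): %s\n", i, length(x$clusters[[i]]),
                paste(x$clusters[[i]], collapse = ", ")))
    if (!is.null(x$representatives))
      cat("    representative:", x$representatives[i], "\n")
  }
  invisible(x)
}

#' Randomly pick a representative pose from a cluster
#'
#' Uniform over cluster members, reproducible under \code{seed}.
#'
#' @param cluster Character vector of pose ids.
#' @param seed Integer seed.
#' @return A single pose id.
#' @export
pick_representative <- function(cluster, seed = 1) {
  if (length(cluster) == 0L) stop_nodkey("empty cluster")
  with_seed(seed, cluster[sample.int(length(cluster), 1L)])
}

#' Pick representatives for every cluster in a clustering
#'
#' @param clusters A \code{\link{find_clusters}} result.
#' @param seed Integer master seed; each cluster draws from its own
#'   sub-stream.
#' @return The \code{pose_clusters} object with \code{representatives}
#'   filled in.
#' @export
pick_representatives <- function(clusters, seed = 1) {
  stopifnot(inherits(clusters, "pose_clusters"))
  clusters$representatives <- vapply(
    seq_along(clusters$clusters),
    function(i) pick_representative(clusters$clusters[[i]],
                                    derive_seed(seed, i)),
    character(1))
  clusters
}

#' Write clustering results as TSV tables
#'
#' Writes \code{pose_measures.tsv}, \code{clusters.tsv} and (when
#' representatives were picked) \code{representatives.tsv} into \code{dir}.
#'
#' @param sim Similarity matrix from \code{\link{similarity_matrix}}.
#' @param clusters A \code{\link{find_clusters}} result.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_cluster_report <- function(sim, clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "pose_measures.tsv")
  utils::write.table(pairwise_pose_measures(sim), paths[1],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assign_df <- data.frame(
    pose_id = c(unlist(clusters$clusters), clusters$unclustered),
    cluster = c(rep(seq_along(clusters$clusters),
                    lengths(clusters$clusters)),
                rep(NA_integer_, length(clusters$unclustered))))
  p2 <- file.path(dir, "clusters.tsv")
  utils::write.table(assign_df, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p2)
  if (!is.null(clusters$representatives)) {
    p3 <- file.path(dir, "representatives.tsv")
    utils::write.table(
      data.frame(cluster = seq_along(clusters$representatives),
                 pose_id = clusters$representatives),
      p3, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
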