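# Heterodimer docking poses: two labelled 3D point sets per pose.
#
# The reference subunit (LykX) anchors the common frame; the mobile subunit
# (Sym10) carries the between-pose variation used for clustering. Atom
# ordering must be identical across poses of the same system because the
# similarity measure correlates coordinates atom-by-atom.

#' Construct a single dimer docking pose
#'
#' @param pose_id Unique identifier.
#' @param ref Numeric matrix (n x 3), reference-subunit coordinates in
#'   Angstroms (LykX).
#' @param mob Numeric matrix (m x 3), mobile-subunit coordinates (Sym10).
#' @param allele Optional allele/group label.
#' @return Object of class \code{dimer_pose}.
#' @export
dimer_pose <- function(pose_id, ref, mob, allele = NA_character_) {
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  stopifnot(ncol(ref) == 3L, ncol(mob) == 3L)
  if (nrow(ref) < 3L)
    stop_nodkey("pose ", pose_id, ": reference subunit needs >= 3 atoms")
  structure(list(pose_id = as.character(pose_id), allele = allele,
                 ref = unname(ref), mob = unname(mob)),
            class = "dimer_pose")
}

#' Bundle poses into a pose set
#'
#' @param poses List of \code{\link{dimer_pose}} objects with distinct ids.
#' @return Object of class \code{dimer_poses} (a named list of poses).
#' @export
dimer_poses <- function(poses) {
  stopifnot(all(vapply(poses, inherits, logical(1), "dimer_pose")))
  ids <- vapply(poses, `[[`, character(1), "pose_id")
  if (anyDuplicated(ids))
    stop_nodkey("duplicated pose id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(poses) <- ids
  structure(poses, class = "dimer_poses")
}

#' @export
print.dimer_poses <- function(x, ...) {
  cat("Dimer pose set:", length(x), "poses;",
      nrow(x[[1L]]$ref), "ref atoms,", nrow(x[[1L]]$mob), "mobile atoms\n")
  if (!is.null(attr(x, "superposed_on")))
    cat("Superposed on reference pose:", attr(x, "superposed_on"), "\n")
  invisible(x)
}

# Random proper rotation (det +1) via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Unit directions with pairwise angles above min_sep_deg (rejection sampling).
separated_directions <- function(n, min_sep_deg, max_iter = 20000L) {
  dirs <- matrix(numeric(0), 0, 3)
  cmin <- cos(min_sep_deg * pi / 180)
  it <- 0L
  while (nrow(dirs) < n) {
    it <- it + 1L
    if (it > max_iter)
      stop_nodkey("cannot place ", n, " directions separated by >",
                  min_sep_deg, " degrees")
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    if (nrow(dirs) == 0L || all(dirs %*% v < cmin))
      dirs <- rbind(dirs, v)
  }
  dirs
}

#' Simulate rigid-body dimer pose families with planted clusters
#'
#' Every pose shares one reference-subunit point cloud (placed in a random
#' per-pose global frame, so superposition is exercised). Mobile subunits of
#' a cluster share a rigid placement and differ only by isotropic Gaussian
#' atom noise; placements of distinct clusters (and singletons) point in
#' directions separated by more than 45 degrees plus a 10 degree margin from
#' the reference centroid, guaranteeing separability under the default
#' angle threshold.
#'
#' @param n_clusters Planted cluster count.
#' @param poses_per_cluster Poses per planted cluster.
#' @param n_singletons Additional unclustered poses.
#' @param atoms_per_subunit Atoms per subunit (>= 3).
#' @param noise_sd Per-atom isotropic Gaussian noise, Angstroms.
#' @param seed Master seed (deterministic sub-streams).
#' @param separation_deg Minimum pairwise placement angle (default 55 = 45
#'   threshold + 10 margin).
#' @return List with \code{poses} (a \code{\link{dimer_poses}} set) and
#'   \code{truth}: data frame of \code{pose_id}, \code{cluster} (integer;
#'   \code{NA} for singletons).
#' @export
simulate_dimer_poses <- function(n_clusters = 3,
                                 poses_per_cluster = 10,
                                 n_singletons = 0,
                                 atoms_per_subunit = 30,
                                 noise_sd = 0,
                                 seed = 1,
                                 separation_deg = 55) {
  if (atoms_per_subunit < 3)
    stop_nodkey("atoms_per_subunit must be >= 3")
  n_place <- n_clusters + n_singletons
  if (n_place == 0L) stop_nodkey("nothing to simulate")

  shape_seed <- derive_seed(seed, 0L)
  place_seed <- derive_seed(seed, 1L)
  noise_seed <- derive_seed(seed, 2L)
  frame_seed <- derive_seed(seed, 3L)

  base <- with_seed(shape_seed, list(
    ref = matrix(stats::rnorm(atoms_per_subunit * 3, sd = 5), ncol = 3),
    mob = matrix(stats::rnorm(atoms_per_subunit * 3, sd = 5), ncol = 3)))
  base$ref <- sweep(base$ref, 2, centroid(base$ref))
  base$mob <- sweep(base$mob, 2, centroid(base$mob))

  placements <- with_seed(place_seed, {
    dirs <- separated_directions(n_place, separation_deg)
    lapply(seq_len(n_place), function(k)
      list(rot = random_rotation(), shift = 30 * dirs[k, ]))
  })

  labels <- c(rep(seq_len(n_clusters), each = poses_per_cluster),
              rep(NA_integer_, n_singletons))
  n_pose <- length(labels)
  place_of <- c(rep(seq_len(n_clusters), each = poses_per_cluster),
                if (n_singletons) n_clusters + seq_len(n_singletons))

  noise <- with_seed(noise_seed, lapply(seq_len(n_pose), function(i)
    if (noise_sd > 0)
      matrix(stats::rnorm(atoms_per_subunit * 3, sd = noise_sd), ncol = 3)
    else matrix(0, atoms_per_subunit, 3)))
  frames <- with_seed(frame_seed, lapply(seq_len(n_pose), function(i)
    list(rot = random_rotation(), shift = stats::runif(3, -20, 20))))

  poses <- lapply(seq_len(n_pose), function(i) {
    pl <- placements[[place_of[i]]]
    mob <- base$mob %*% t(pl$rot) +
      matrix(pl$shift, atoms_per_subunit, 3, byrow = TRUE) + noise[[i]]
    fr <- frames[[i]]
    sh <- matrix(fr$shift, atoms_per_subunit, 3, byrow = TRUE)
    dimer_pose(sprintf("P%02d", i),
               ref = base$ref %*% t(fr$rot) + sh,
               mob = mob %*% t(fr$rot) + sh)
  })
  list(poses = dimer_poses(poses),
       truth = data.frame(pose_id = sprintf("P%02d", seq_len(n_pose)),
                          cluster = labels))
}

#' Write a pose set as per-pose PDB files
#'
#' Each pose becomes \code{<pose_id>.pdb}; the reference subunit is written
#' as CA pseudo-atoms on chain A, the mobile subunit on chain B.
#'
#' @param poses A \code{\link{dimer_poses}} set.
#' @param dir Output directory (created if absent).
#' @param ref_chain,mob_chain Chain identifiers to use.
#' @return Invisibly, the files written.
#' @export
write_poses <- function(poses, dir, ref_chain = "A", mob_chain = "B") {
  stopifnot(inherits(poses, "dimer_poses"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(poses, function(p) {
    n1 <- nrow(p$ref); n2 <- nrow(p$mob)
    xyz <- as.numeric(t(rbind(p$ref, p$mob)))
    path <- file.path(dir, paste0(p$pose_id, ".pdb"))
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = rep("ATOM", n1 + n2),
                     resno = c(seq_len(n1), seq_len(n2)),
                     resid = rep("ALA", n1 + n2),
                     eleno = seq_len(n1 + n2),
                     elety = rep("CA", n1 + n2),
                     chain = c(rep(ref_chain, n1), rep(mob_chain, n2)))
    path
  }, character(1))
  invisible(paths)
}

#' Read a directory of dimer-pose PDB files
#'
#' @param dir Directory of \code{.pdb} files, one pose each; the file stem
#'   is the pose id.
#' @param ref_chain,mob_chain Chains holding the reference and mobile
#'   subunits.
#' @return A \code{\link{dimer_poses}} set.
#' @export
read_poses <- function(dir, ref_chain = "A", mob_chain = "B") {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(files)) stop_nodkey("no .pdb files in ", dir)
  poses <- lapply(files, function(f) {
    pdb <- bio3d::read.pdb(f, verbose = FALSE)
    at <- pdb$atom
    take <- function(ch) as.matrix(at[at$chain == ch, c("x", "y", "z")])
    ref <- take(ref_chain); mob <- take(mob_chain)
    if (!nrow(ref) || !nrow(mob))
      stop_nodkey(basename(f), ": missing chain ",
                  if (!nrow(ref)) ref_chain else mob_chain)
    dimer_pose(sub("\\.pdb$", "", basename(f)), ref = ref, mob = mob)
  })
  dimer_poses(poses)
}
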