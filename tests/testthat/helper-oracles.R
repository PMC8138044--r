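# Independent brute-force oracles used to cross-check the implementation.

# Maximal cliques by plain recursive Bron-Kerbosch (no pivoting), on a
# logical adjacency matrix; returns cliques as sorted id vectors.
bk_max_cliques <- function(adj, min_size = 1L) {
  n <- nrow(adj)
  ids <- rownames(adj)
  out <- list()
  recurse <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      if (length(r) >= min_size) out[[length(out) + 1L]] <<- sort(ids[r])
      return(invisible())
    }
    for (v in p) {
      nb <- which(adj[v, ])
      recurse(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  recurse(integer(0), seq_len(n), integer(0))
  out
}

# Transitive merge of overlapping sets via an explicit union-find.
uf_merge_sets <- function(sets) {
  if (!length(sets)) return(list())
  elems <- sort(unique(unlist(sets)))
  parent <- stats::setNames(seq_along(elems), elems)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (s in sets) {
    r <- find(match(s[1L], elems))
    for (e in s[-1L]) {
      r2 <- find(match(e, elems))
      if (r2 != r) parent[r2] <- r
    }
  }
  roots <- vapply(seq_along(elems), find, numeric(1))
  unname(lapply(split(elems, roots), sort))
}

# Full clique-and-merge clustering oracle on a similarity matrix.
oracle_clusters <- function(sim, min_group = 4L) {
  cliques <- bk_max_cliques(sim, min_size = min_group)
  clusters <- uf_merge_sets(cliques)
  clusters[order(vapply(clusters, `[`, character(1), 1L))]
}

# Canonical form of a clustering for set comparison.
canon_clusters <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, character(1), 1L))]
}

# Random symmetric logical similarity matrix with given edge probability.
random_sim_matrix <- function(n, p) {
  ids <- sprintf("p%02d", seq_len(n))
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  up <- upper.tri(m)
  m[up] <- stats::runif(sum(up)) < p
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Random proper rigid transform, applied as x %*% t(rot) + shift.
random_rigid_transform <- function(spread = 50) {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = stats::runif(3, -spread, spread))
}

transform_points <- function(m, tr) {
  m %*% t(tr$rot) + matrix(tr$shift, nrow(m), 3, byrow = TRUE)
}

transform_complex <- function(cx, tr) {
  p <- as.matrix(cx$protein[c("x", "y", "z")])
  l <- as.matrix(cx$ligand[c("x", "y", "z")])
  cx$protein[c("x", "y", "z")] <- transform_points(p, tr)
  cx$ligand[c("x", "y", "z")] <- transform_points(l, tr)
  cx
}

# Tiny alignment builder for hand-made cases.
make_aln <- function(seqs, groups = rep("g1", length(seqs)),
                     ids = paste0("s", seq_along(seqs))) {
  allele_alignment(seqs, ids = ids, groups = groups)
}

# Brute-force mean pairwise Hamming distance (double loop).
brute_mpd <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[i], "")[[1]]
    b <- strsplit(seqs[j], "")[[1]]
    tot <- tot + sum(a != b)
  }
  tot / (n * (n - 1) / 2)
}
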