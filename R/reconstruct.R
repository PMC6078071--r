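## Desk-scale tree reconstruction: Poisson-corrected pairwise distances,
## neighbor joining with a deterministic tie-break, and nonparametric
## bootstrap support. This stage stands in for the ML/Bayesian inference
## used on real data; the classifier consumes externally inferred newick
## files through exactly the same interface.

#' Proportion of mismatched residues between two aligned rows
#'
#' Pairwise deletion: columns where either row has a gap are ignored.
#'
#' @param msa named character vector of aligned sequences.
#' @param i,j row ids.
#' @return list with `p` (mismatch proportion) and `n` (compared
#'   columns).
#' @export
p_distance <- function(msa, i, j) {
  m <- msa_matrix(msa[c(i, j)])
  a <- m[1L, ]; b <- m[2L, ]
  ok <- a != "-" & b != "-"
  n <- sum(ok)
  if (n == 0L) stop2("no comparable (gap-free) columns between '",
                     i, "' and '", j, "'")
  list(p = sum(a[ok] != b[ok]) / n, n = n)
}

#' Poisson correction of an amino-acid p-distance
#'
#' `d = -(19/20) log(1 - 20 p / 19)`: the exact inverse of the
#' simulator's expected mismatch curve under the 20-state equal-rate
#' model. Saturated proportions (`p >= 19/20`) have no finite inverse
#' and come back as NA flagged in the `"saturated"` attribute.
#'
#' @param p mismatch proportion(s) in [0, 19/20).
#' @return corrected distance(s), NA where saturated.
#' @export
poisson_correct <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  sat <- !is.na(p) & p >= 19 / 20
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & !sat
  d[ok] <- -(19 / 20) * log(1 - 20 * p[ok] / 19)
  attr(d, "saturated") <- sat
  d
}

## mismatch / comparable counts for all pairs in one pass; the workhorse
## behind distance_matrix() and the bootstrap resampler
pair_mismatch_matrix <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m); L <- ncol(m)
  ids <- rownames(m)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  mis <- matrix(0, np, L)
  cmp <- matrix(0, np, L)
  gap <- m == "-"
  for (k in seq_len(np)) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    ok <- !gap[a, ] & !gap[b, ]
    cmp[k, ] <- ok
    mis[k, ] <- ok & (m[a, ] != m[b, ])
  }
  list(ids = ids, pairs = pairs, mis = mis, cmp = cmp)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param msa named character vector of aligned sequences.
#' @return a `dist_matrix`: list with `ids`, `d` (symmetric corrected
#'   distances, NA where saturated) and `saturated` (logical matrix).
#' @export
distance_matrix <- function(msa) {
  pm <- pair_mismatch_matrix(msa)
  n <- length(pm$ids)
  nm <- rowSums(pm$mis); nc <- rowSums(pm$cmp)
  if (any(nc == 0))
    stop2("pair(s) with no comparable columns")
  p <- nm / nc
  dcor <- poisson_correct(p)
  d <- matrix(0, n, n, dimnames = list(pm$ids, pm$ids))
  sat <- matrix(FALSE, n, n, dimnames = list(pm$ids, pm$ids))
  for (k in seq_len(nrow(pm$pairs))) {
    a <- pm$pairs[k, 1]; b <- pm$pairs[k, 2]
    d[a, b] <- d[b, a] <- dcor[k]
    sat[a, b] <- sat[b, a] <- attr(dcor, "saturated")[k]
  }
  structure(list(ids = pm$ids, d = d, saturated = sat),
            class = "dist_matrix")
}

#' Export a distance matrix in PHYLIP square format
#'
#' @param dm a `dist_matrix` or plain symmetric matrix with dimnames.
#' @param file output path (or connection).
#' @export
write_phylip_dist <- function(dm, file) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else dm
  ids <- rownames(d)
  lines <- c(format(nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(formatC(ids[i], width = 10, flag = "-"),
                     paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, file)
}

fmt_bl <- function(x) sprintf("%.12g", x)

## Neighbor joining over labelled clusters. Tracks, for every join, the
## tip-membership of the new cluster: clusters of size 2..n-2 are exactly
## the internal edges (bipartitions) of the resulting unrooted tree.
## Tie-break: among Q-minimal pairs, the lexicographically smallest
## sorted id pair. Negative branch-length estimates are clamped to 0.
nj_core <- function(d, ids) {
  n <- length(ids)
  sub <- stats::setNames(ids, ids)              # newick fragments
  members <- stats::setNames(lapply(ids, identity), ids)
  splits <- list()
  ntot <- n
  clamp <- function(x) max(x, 0)
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ix) {
      pr <- sort(ids[ix]); paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_id <- paste0("#", length(splits) + 1L)
    new_sub <- paste0("(", sub[[ids[i]]], ":", fmt_bl(li), ",",
                      sub[[ids[j]]], ":", fmt_bl(lj), ")")
    new_members <- c(members[[ids[i]]], members[[ids[j]]])
    if (length(new_members) >= 2L && length(new_members) <= ntot - 2L)
      splits[[length(splits) + 1L]] <- sort(new_members)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    ids <- c(ids[keep], new_id)
    dimnames(d) <- list(ids, ids)
    sub[[new_id]] <- new_sub
    members[[new_id]] <- new_members
    n <- n - 1L
  }
  l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- paste0("(", sub[[ids[1]]], ":", fmt_bl(l1), ",",
                sub[[ids[2]]], ":", fmt_bl(l2), ",",
                sub[[ids[3]]], ":", fmt_bl(l3), ");")
  list(newick = nwk, splits = splits)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (Q-criterion joins, Studier-Keppler distance updates),
#' deterministic via a lexicographic tie-break on the joined id pair.
#'
#' @param dm a `dist_matrix` or symmetric numeric matrix with dimnames.
#' @return an unrooted `gene_tree` (supports unset).
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else dm
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (nrow(d) < 3L) stop2("neighbor joining needs >= 3 taxa")
  if (anyNA(d)) stop2("saturated (NA) entries in distance matrix")
  res <- nj_core(d, rownames(d))
  parse_newick(res$newick)
}

split_key <- function(tips) paste(sort(tips), collapse = "\r")

## canonical bipartition keys of a tree: each side reported as the one
## NOT containing the alphabetically first tip
tree_split_keys <- function(splits, all_tips) {
  ref <- sort(all_tips)[1L]
  vapply(splits, function(s) {
    if (ref %in% s) split_key(setdiff(all_tips, s)) else split_key(s)
  }, "")
}

## non-trivial bipartitions of a phylo as canonical keys, aligned with
## the internal nodes that subtend them
phylo_split_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- desc_sets(phy)
  root <- ntip + 1L
  nodes <- setdiff((ntip + 1L):(ntip + phy$Nnode), root)
  splits <- lapply(nodes, function(v) phy$tip.label[sets[[v]]])
  ok <- lengths(splits) >= 2L & lengths(splits) <= ntip - 2L
  nodes <- nodes[ok]; splits <- splits[ok]
  list(nodes = nodes, keys = tree_split_keys(splits, phy$tip.label),
       splits = splits)
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' The point tree is NJ on the full alignment; each of `B` replicates
#' resamples alignment columns with replacement and re-estimates the
#' tree, and the percentage of replicates containing each internal-edge
#' bipartition is written into the MLBP slot (the BPP slot stays absent:
#' NJ bootstrap proportions are not posterior probabilities). Replicates
#' with saturated distances are skipped and counted.
#'
#' @param msa named character vector of aligned sequences.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed; resampling is deterministic in it.
#' @return a `gene_tree` whose internal nodes carry bootstrap
#'   percentages in `mlbp`; attribute `"skipped"` counts dropped
#'   replicates.
#' @export
bootstrap_support <- function(msa, B = 100L, seed = 1L) {
  stopifnot(is_count(B, 1))
  pm <- pair_mismatch_matrix(msa)
  n <- length(pm$ids)
  if (n < 3L) stop2("bootstrap needs >= 3 taxa")
  L <- ncol(pm$mis)

  dist_from_weights <- function(w) {
    nm <- as.vector(pm$mis %*% w)
    nc <- as.vector(pm$cmp %*% w)
    if (any(nc == 0)) return(NULL)
    p <- nm / nc
    if (any(p >= 19 / 20)) return(NULL)
    dcor <- -(19 / 20) * log(1 - 20 * p / 19)
    d <- matrix(0, n, n, dimnames = list(pm$ids, pm$ids))
    d[pm$pairs] <- dcor
    d[pm$pairs[, c(2, 1), drop = FALSE]] <- dcor
    d
  }

  d0 <- dist_from_weights(rep(1, L))
  if (is.null(d0)) stop2("saturated distances on the full alignment")
  point <- nj_core(d0, pm$ids)
  tree <- parse_newick(point$newick)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  info <- phylo_split_keys(phy)

  counts <- stats::setNames(rep(0, length(info$keys)), info$keys)
  used <- 0L; skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      db <- dist_from_weights(w)
      if (is.null(db)) { skipped <- skipped + 1L; next }
      rep_keys <- tree_split_keys(nj_core(db, pm$ids)$splits, pm$ids)
      hit <- info$keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
      used <- used + 1L
    }
  })
  if (skipped > 0.1 * B)
    warning(skipped, " of ", B, " bootstrap replicates skipped ",
            "(saturated distances)", call. = FALSE)
  if (used == 0L) stop2("all bootstrap replicates saturated")
  mlbp <- rep(NA_real_, phy$Nnode)
  key_of_node <- stats::setNames(rep(NA_character_, phy$Nnode),
                                 seq_len(phy$Nnode))
  sets <- desc_sets(phy)
  for (v in info$nodes) {
    s <- phy$tip.label[sets[[v]]]
    if (length(s) >= 2L && length(s) <= ntip - 2L) {
      key <- tree_split_keys(list(s), phy$tip.label)
      mlbp[v - ntip] <- 100 * counts[[key]] / used
    }
  }
  out <- gene_tree(phy, mlbp = mlbp, bpp = rep(NA_real_, phy$Nnode))
  attr(out, "skipped") <- skipped
  out
}

#' Reconstruct a gene tree from an alignment
#'
#' Convenience wrapper: Poisson distances, NJ, optional bootstrap.
#'
#' @param msa named character vector of aligned sequences.
#' @param bootstrap replicate count; 0 for the point tree only.
#' @param seed integer seed for the resampling.
#' @return a `gene_tree`.
#' @export
reconstruct_tree <- function(msa, bootstrap = 100L, seed = 1L) {
  if (bootstrap >= 1L) bootstrap_support(msa, B = bootstrap, seed = seed)
  else neighbor_joining(distance_matrix(msa))
}
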