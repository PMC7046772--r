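#' Principal-network decomposition of a connectivity matrix
#'
#' Decomposes a symmetric weighted connectivity matrix into principal
#' networks (PNs) by eigendecomposition. The loadings of a PN are the
#' entries of the corresponding unit-norm eigenvector; their magnitude
#' measures each node's influence on the PN and their sign the sense of its
#' connectivity relative to the other members. Components are ranked by
#' eigenvalue in descending signed order, so PN1 is the most strongly
#' internally connected subnetwork. A node is a member of a PN when the
#' absolute value of its loading is at least `tau` (inclusive).
#'
#' Each eigenvector's sign is fixed so that its largest-magnitude loading is
#' positive (ties broken by first index), which makes loadings reproducible
#' across platforms and eigensolvers; membership is invariant under this
#' global sign flip. Components with a negative eigenvalue are computed but
#' flagged (`negative_eigenvalue`), as are components whose eigenvalue is
#' within `1e-10 * ||W||` of a neighbouring one (`unstable`), where the
#' eigenbasis is not numerically well defined.
#'
#' @param weights Symmetric connectivity matrix (group-mean matrix in the
#'   standard workflow).
#' @param tau Loading threshold in (0, 1); default 0.1.
#' @param n_components Number of leading components to return (default 2:
#'   PN1 and PN2).
#' @return List of class `pnms_pn_list`; each element is a `pnms_pn` list
#'   with `rank`, `eigenvalue`, `loadings` (named, unit-norm), `tau`,
#'   `members` (labels in node order), `member_signs`, `partial_matrix`
#'   (the rank-one term `lambda * v v'` with zero diagonal, restricted to
#'   members), and the flags described above.
#' @export
pn_decompose <- function(weights, tau = 0.1, n_components = 2) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("weights must be a square matrix")
  if (max(abs(weights - t(weights))) > 1e-8 * max(abs(weights), 1))
    stop("weights must be symmetric")
  if (!(tau > 0 && tau < 1)) stop("tau must lie in (0, 1)")
  n <- nrow(weights)
  if (n_components < 1 || n_components > n)
    stop("n_components must lie in [1, ", n, "]")
  eig <- eigen((weights + t(weights)) / 2, symmetric = TRUE)
  gap_tol <- 1e-10 * norm(weights, "2")
  gaps <- abs(diff(eig$values))
  pns <- lapply(seq_len(n_components), function(k) {
    v <- eig$vectors[, k]
    # sign fix: largest-|loading| entry positive, ties -> first index
    imax <- which(abs(v) == max(abs(v)))[1]
    if (v[imax] < 0) v <- -v
    names(v) <- rownames(weights)
    members <- names(v)[abs(v) >= tau]
    pm <- eig$values[k] * tcrossprod(v)
    dimnames(pm) <- list(names(v), names(v))
    diag(pm) <- 0
    unstable <- (k > 1 && gaps[k - 1] < gap_tol) ||
      (k < n && gaps[k] < gap_tol)
    structure(list(rank = k, eigenvalue = eig$values[k], loadings = v,
                   tau = tau, members = members,
                   member_signs = sign(v[members]),
                   partial_matrix = pm[members, members, drop = FALSE],
                   negative_eigenvalue = eig$values[k] < 0,
                   unstable = unstable,
                   mixed_sign = length(unique(sign(v[members]))) > 1),
              class = "pnms_pn")
  })
  structure(pns, class = "pnms_pn_list", tau = tau,
            all_eigenvalues = eig$values)
}

#' @export
print.pnms_pn <- function(x, ...) {
  cat(sprintf("PN%d: eigenvalue %.6g, %d members (|loading| >= %g)\n",
              x$rank, x$eigenvalue, length(x$members), x$tau))
  cat("  ", paste(x$members, collapse = ", "), "\n")
  if (x$negative_eigenvalue) cat("  flag: negative eigenvalue\n")
  if (x$unstable) cat("  flag: near-degenerate eigenvalue\n")
  if (x$mixed_sign) cat("  flag: mixed-sign member loadings\n")
  invisible(x)
}

#' @export
print.pnms_pn_list <- function(x, ...) {
  for (pn in x) print(pn)
  invisible(x)
}

#' Reconstruct a matrix from its principal-network components
#'
#' Sums the rank-one spectral terms `lambda_k v_k v_k'` of the given
#' components and restores the zero diagonal. With the full set of `n`
#' components this reproduces the input matrix (off-diagonal) exactly up to
#' numerical precision; with a partial set it is the documented truncated
#' approximation, whose error is non-increasing in the number of components
#' retained.
#'
#' @param weights The matrix that was decomposed (used for dimension and
#'   labels).
#' @param pns A `pnms_pn_list` from [pn_decompose()].
#' @return Reconstructed symmetric matrix with zero diagonal.
#' @export
pn_reconstruct <- function(weights, pns) {
  acc <- matrix(0, nrow(weights), ncol(weights),
                dimnames = dimnames(weights))
  for (pn in pns) {
    v <- pn$loadings
    acc <- acc + pn$eigenvalue * tcrossprod(v)
  }
  diag(acc) <- 0
  acc
}

#' Compare PN membership across groups
#'
#' For each group and PN rank, reports the set-theoretic differences of the
#' member sets against a reference group's decomposition (nodes lost =
#' present in the reference but not the group; gained = the converse).
#' Decompositions must share the node table and threshold. Ranks flagged as
#' numerically unstable in either decomposition are refused.
#'
#' @param pns_by_group Named list of `pnms_pn_list` objects, one per group.
#' @param reference Name of the reference group (default `"HC"`).
#' @return Data frame with columns `group`, `rank`, `lost`, `gained`
#'   (comma-separated labels, empty string when none).
#' @export
pn_membership_comparison <- function(pns_by_group, reference = "HC") {
  if (!reference %in% names(pns_by_group))
    stop("reference group '", reference, "' not in pns_by_group")
  ref <- pns_by_group[[reference]]
  taus <- unique(vapply(pns_by_group, function(p) attr(p, "tau"), 0))
  if (length(taus) > 1)
    stop("decompositions use different loading thresholds")
  nodesets <- lapply(pns_by_group, function(p) names(p[[1]]$loadings))
  if (!all(vapply(nodesets, identical, TRUE, y = nodesets[[1]])))
    stop("decompositions use different node tables")
  out <- lapply(setdiff(names(pns_by_group), reference), function(g) {
    pl <- pns_by_group[[g]]
    do.call(rbind, lapply(seq_len(min(length(pl), length(ref))), function(k) {
      if (pl[[k]]$unstable || ref[[k]]$unstable)
        stop("rank ", k, " flagged unstable; refusing membership comparison")
      data.frame(group = g, rank = k,
                 lost = paste(setdiff(ref[[k]]$members, pl[[k]]$members),
                              collapse = ","),
                 gained = paste(setdiff(pl[[k]]$members, ref[[k]]$members),
                                collapse = ","))
    }))
  })
  do.call(rbind, out)
}

#' Hemispheric composition of a PN's edges
#'
#' Sums the member-member edge weight of a PN on the group-mean matrix and
#' splits it into inter-hemispheric and intra-hemispheric fractions. Edges
#' with a midline endpoint are counted as intra-hemispheric (they cross no
#' hemispheric boundary), so the two fractions always sum to 1. Homotopic
#' pairs (left and right instances of the same region, both members) are
#' counted.
#'
#' @param weights Group-mean connectivity matrix.
#' @param pn A `pnms_pn` component.
#' @param node_table Node table annotating hemispheres.
#' @return List with `total_weight`, `inter_fraction`, `intra_fraction`,
#'   `homotopic_pairs`.
#' @export
edge_composition <- function(weights, pn, node_table) {
  members <- pn$members
  idx <- match(members, node_table$region_label)
  if (anyNA(idx))
    stop("member(s) not in node table: ",
         paste(members[is.na(idx)], collapse = ", "))
  hemi <- node_table$hemisphere[idx]
  sub <- weights[members, members, drop = FALSE]
  n <- length(members)
  inter <- 0; intra <- 0; homotopic <- 0
  base <- homotopic_base(members)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      w <- sub[i, j]
      crossing <- hemi[i] != hemi[j] &&
        all(c(hemi[i], hemi[j]) %in% c("left", "right"))
      if (crossing) inter <- inter + w else intra <- intra + w
      if (crossing && base[i] == base[j] && w > 0)
        homotopic <- homotopic + 1
    }
  }
  total <- inter + intra
  list(total_weight = total,
       inter_fraction = if (total > 0) inter / total else NA_real_,
       intra_fraction = if (total > 0) intra / total else NA_real_,
       homotopic_pairs = homotopic)
}
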