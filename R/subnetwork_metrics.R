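#' Extract an induced subnetwork
#'
#' Restricts a subject's full connectivity matrix to a node set, keeping the
#' original edge weights (not the rank-one partial-matrix entries). The
#' result is itself a valid connectivity matrix: symmetric, nonnegative,
#' zero diagonal.
#'
#' @param weights Full connectivity matrix with region-label dimnames.
#' @param node_set Character vector of member region labels, length >= 2.
#' @return The induced submatrix, rows/columns in `node_set` order.
#' @export
extract_subnetwork <- function(weights, node_set) {
  if (length(node_set) < 2) stop("node_set must contain at least 2 nodes")
  unknown <- setdiff(node_set, rownames(weights))
  if (length(unknown))
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  weights[node_set, node_set, drop = FALSE]
}

#' Per-subject nodal strengths within a reference subnetwork
#'
#' Uses a principal network defined on the healthy-control group-mean matrix
#' as a fixed basis: for every subject (all groups), the subject's full
#' matrix is restricted to the reference member set and the nodal strength
#' of each member is computed within that induced submatrix. The subnetwork
#' strength of a node can never exceed its full-matrix strength; the
#' difference is exactly the weight connecting it to non-members.
#'
#' @param cohort A `pnms_cohort`.
#' @param reference_pn A `pnms_pn` computed on the HC group-mean matrix
#'   (any fixed member set is accepted; the HC reference is the standard
#'   workflow), or a character vector of member labels.
#' @param pn_rank Rank recorded in the output (taken from `reference_pn`
#'   when available).
#' @return Long data frame: `subject_id`, `group`, `pn_rank`,
#'   `region_label`, `strength`.
#' @export
subnetwork_nodal_strength <- function(cohort, reference_pn,
                                      pn_rank = NULL) {
  if (inherits(reference_pn, "pnms_pn")) {
    members <- reference_pn$members
    if (is.null(pn_rank)) pn_rank <- reference_pn$rank
  } else {
    members <- reference_pn
    if (is.null(pn_rank)) pn_rank <- NA_integer_
  }
  res <- lapply(seq_along(cohort$matrices), function(i) {
    sub <- extract_subnetwork(cohort$matrices[[i]], members)
    data.frame(subject_id = cohort$manifest$subject_id[i],
               group = as.character(cohort$manifest$group[i]),
               pn_rank = pn_rank,
               region_label = members,
               strength = unname(nodal_strength(sub)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Wide layout of subnetwork strengths for one region
#'
#' Convenience accessor: the per-subject strength of one region within one
#' reference subnetwork, aligned with the cohort manifest order.
#'
#' @param sub_strengths Long data frame from [subnetwork_nodal_strength()].
#' @param region Region label.
#' @return Numeric vector, one entry per subject in manifest order.
#' @export
subnetwork_strength_vector <- function(sub_strengths, region) {
  rows <- sub_strengths[sub_strengths$region_label == region, ]
  if (nrow(rows) == 0) stop("region '", region, "' not in subnetwork")
  stats::setNames(rows$strength, rows$subject_id)
}
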