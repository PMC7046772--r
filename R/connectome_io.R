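#' Read a node table
#'
#' A node table defines the canonical node order for every connectivity
#' matrix in a run. It is a TSV file with header
#' `region_label, hemisphere, lobe, node_class`. Region labels must be
#' unique; the file order is the canonical order (no sorting is applied, so
#' outputs are reproducible across platforms).
#'
#' @param path Path to a tab-separated node table.
#' @return A `data.frame` with columns `region_label`, `hemisphere`
#'   (`left`/`right`/`midline`), `lobe` and `node_class`
#'   (`cortical`/`subcortical`).
#' @seealso [default_node_table()] for the packaged 115-region table.
#' @export
read_node_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_node_table(df)
}

#' Write a node table
#' @param node_table A validated node table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(node_table, path) {
  node_table <- validate_node_table(node_table)
  utils::write.table(node_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged 115-region node table
#'
#' A symmetric parcellation of 115 cortical and subcortical regions (57
#' left/right pairs plus the brainstem), following Desikan-Killiany-Tourville
#' style naming. The 18 canonical high-strength regions (bilateral
#' precentral, superior frontal, middle frontal and postcentral gyri,
#' superior parietal lobule, precuneus, middle temporal gyrus, thalamus and
#' putamen) are included under the exact labels used by the strength
#' calibration table ([hub_strength_reference()]).
#'
#' @return A node table `data.frame` with 115 rows.
#' @export
default_node_table <- function() {
  path <- system.file("extdata", "nodes_115.tsv", package = "pnms",
                      mustWork = TRUE)
  read_node_table(path)
}

validate_node_table <- function(df) {
  required <- c("region_label", "hemisphere", "lobe", "node_class")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("node table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, required]
  if (anyDuplicated(df$region_label))
    stop("node table has duplicated region labels: ",
         paste(unique(df$region_label[duplicated(df$region_label)]),
               collapse = ", "))
  bad_hemi <- setdiff(unique(df$hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi))
    stop("unknown hemisphere value(s): ", paste(bad_hemi, collapse = ", "))
  bad_cls <- setdiff(unique(df$node_class), c("cortical", "subcortical"))
  if (length(bad_cls))
    stop("unknown node_class value(s): ", paste(bad_cls, collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Base region name shared by a homotopic pair
#'
#' Strips the `Left `/`Right ` hemisphere prefix so the left and right
#' instances of the same region map to the same base name. Midline regions
#' are returned unchanged.
#'
#' @param labels Character vector of region labels.
#' @return Character vector of base names.
#' @export
homotopic_base <- function(labels) {
  sub("^(Left|Right) ", "", labels)
}

#' Validate a connectivity matrix
#'
#' Checks that a weighted adjacency matrix is square, nonnegative,
#' symmetric to within `asym_tol` (relative to its largest entry) and has a
#' zero diagonal. Small asymmetries are repaired as `(W + t(W)) / 2`; a
#' nonzero diagonal is forced to zero with a warning. If `node_table` is
#' given, dimension and label order must match it exactly.
#'
#' @param weights Square numeric matrix (dimnames optional, but checked
#'   against `node_table` when both are present).
#' @param node_table Optional node table giving the canonical order.
#' @param asym_tol Relative asymmetry tolerance, `max|W - t(W)| / max(W)`.
#' @return The validated (symmetrized, zero-diagonal) matrix with region
#'   labels as dimnames when available.
#' @export
validate_connectome <- function(weights, node_table = NULL, asym_tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix")
  if (nrow(weights) != ncol(weights))
    stop("connectivity matrix must be square, got ",
         nrow(weights), "x", ncol(weights))
  if (!is.null(node_table)) {
    if (nrow(weights) != nrow(node_table))
      stop("matrix dimension (", nrow(weights),
           ") does not match node table length (", nrow(node_table), ")")
    if (!is.null(rownames(weights))) {
      mism <- which(rownames(weights) != node_table$region_label)
      if (length(mism))
        stop("matrix labels do not match node table order; first mismatch ",
             "at position ", mism[1], ": '", rownames(weights)[mism[1]],
             "' vs '", node_table$region_label[mism[1]], "'")
    }
    dimnames(weights) <- list(node_table$region_label,
                              node_table$region_label)
  }
  if (anyNA(weights)) stop("connectivity matrix contains missing values")
  if (any(weights < 0))
    stop("connectivity matrix contains negative weights (min ",
         format(min(weights)), ")")
  wmax <- max(weights)
  asym <- max(abs(weights - t(weights)))
  if (wmax > 0 && asym / wmax > asym_tol)
    stop("matrix asymmetry ", format(asym / wmax),
         " exceeds tolerance ", format(asym_tol))
  if (asym > 0) weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal forced to zero")
    diag(weights) <- 0
  }
  weights
}

#' Read a connectivity matrix from dense labelled TSV
#'
#' The canonical on-disk format is a dense tab-separated matrix with region
#' labels as the first row and first column, in node-table order, `.` as the
#' decimal separator and UTF-8 encoding.
#'
#' @inheritParams validate_connectome
#' @param path Path to the TSV file.
#' @return Validated connectivity matrix with an attribute `subject_id`
#'   (the file name without extension) when none is recorded in the file.
#' @export
read_connectome_matrix <- function(path, node_table = NULL, asym_tol = 1e-8) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in matrix file ", path)
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m))) {
    mism <- which(rownames(m) != colnames(m))[1]
    stop("row/column labels disagree in ", path, "; first mismatch: '",
         rownames(m)[mism], "' vs '", colnames(m)[mism], "'")
  }
  m <- validate_connectome(m, node_table = node_table, asym_tol = asym_tol)
  attr(m, "subject_id") <- sub("\\.[^.]*$", "", basename(path))
  m
}

#' Write a connectivity matrix as dense labelled TSV
#' @param weights Connectivity matrix with region-label dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectome_matrix <- function(weights, path) {
  if (is.null(rownames(weights)))
    stop("matrix must carry region labels as dimnames")
  df <- data.frame(region_label = rownames(weights),
                   weights, check.names = FALSE)
  # full precision so that write -> read round-trips bit-exactly
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

manifest_columns <- c("subject_id", "group", "age", "sex", "disease_duration",
                      "lesion_load", "tiv", "dgm_volume", "edss", "sdmt")
cohort_groups <- c("HC", "RRMS", "PPMS", "SPMS")

#' Read a cohort manifest
#'
#' The manifest is a CSV file with header
#' `subject_id,group,age,sex,disease_duration,lesion_load,tiv,dgm_volume,edss,sdmt`.
#' Missing clinical scores and the disease covariates that do not apply to
#' healthy controls are encoded as empty fields and preserved as `NA`
#' (never imputed here).
#'
#' @param path Path to the CSV manifest.
#' @return A `data.frame` with typed columns; `group` is a factor with
#'   levels `HC`, `RRMS`, `PPMS`, `SPMS`.
#' @export
read_cohort_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"),
                        colClasses = c(subject_id = "character",
                                       group = "character",
                                       sex = "character"))
  validate_manifest(df)
}

#' Write a cohort manifest
#' @param manifest A validated manifest `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

validate_manifest <- function(df) {
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, manifest_columns]
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  bad_grp <- setdiff(unique(as.character(df$group)), cohort_groups)
  if (length(bad_grp))
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "))
  df$group <- factor(as.character(df$group), levels = cohort_groups)
  bad_sex <- setdiff(unique(stats::na.omit(as.character(df$sex))), c("M", "F"))
  if (length(bad_sex))
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  for (col in c("age", "disease_duration", "lesion_load", "tiv",
                "dgm_volume", "edss", "sdmt"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$edss < 0 | df$edss > 10, na.rm = TRUE))
    stop("EDSS outside [0, 10] for subject(s): ",
         paste(df$subject_id[which(df$edss < 0 | df$edss > 10)],
               collapse = ", "))
  if (any(df$sdmt < 0, na.rm = TRUE))
    stop("negative SDMT score in manifest")
  rownames(df) <- NULL
  df
}

#' Assemble a cohort
#'
#' A cohort bundles the node table, the subject manifest and one validated
#' connectivity matrix per subject, all sharing the node-table order.
#'
#' @param node_table Node table (canonical node order).
#' @param manifest Subject manifest (see [read_cohort_manifest()]).
#' @param matrices Named list of connectivity matrices; names must be
#'   exactly the manifest `subject_id`s.
#' @return An object of class `pnms_cohort`.
#' @export
cohort <- function(node_table, manifest, matrices) {
  node_table <- validate_node_table(node_table)
  manifest <- validate_manifest(manifest)
  if (!setequal(names(matrices), manifest$subject_id))
    stop("matrix names and manifest subject_ids do not match")
  matrices <- matrices[manifest$subject_id]
  matrices <- lapply(matrices, validate_connectome, node_table = node_table)
  structure(list(node_table = node_table, manifest = manifest,
                 matrices = matrices),
            class = "pnms_cohort")
}

#' @export
print.pnms_cohort <- function(x, ...) {
  cat("pnms cohort:", nrow(x$manifest), "subjects,",
      nrow(x$node_table), "regions\n")
  print(table(x$manifest$group))
  invisible(x)
}

#' Subjects belonging to a group
#' @param cohort A `pnms_cohort`.
#' @param group One of `HC`, `RRMS`, `PPMS`, `SPMS`, or `MS` for all three
#'   disease groups pooled.
#' @return Character vector of subject ids.
#' @export
group_subjects <- function(cohort, group) {
  grp <- as.character(cohort$manifest$group)
  keep <- if (identical(group, "MS")) grp != "HC" else grp == group
  cohort$manifest$subject_id[keep]
}

#' Write a cohort to a directory
#'
#' Writes `manifest.csv`, `node_table.tsv` and one `<subject_id>.tsv` dense
#' matrix per subject under `dir/matrices/`.
#'
#' @param cohort A `pnms_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  write_node_table(cohort$node_table, file.path(dir, "node_table.tsv"))
  write_cohort_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  for (sid in names(cohort$matrices))
    write_connectome_matrix(cohort$matrices[[sid]],
                            file.path(dir, "matrices", paste0(sid, ".tsv")))
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @inheritParams validate_connectome
#' @return A `pnms_cohort`.
#' @export
read_cohort <- function(dir, asym_tol = 1e-8) {
  node_table <- read_node_table(file.path(dir, "node_table.tsv"))
  manifest <- read_cohort_manifest(file.path(dir, "manifest.csv"))
  mats <- lapply(manifest$subject_id, function(sid)
    read_connectome_matrix(file.path(dir, "matrices", paste0(sid, ".tsv")),
                           node_table = node_table, asym_tol = asym_tol))
  names(mats) <- manifest$subject_id
  cohort(node_table, manifest, mats)
}
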