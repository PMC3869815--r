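# Tabular I/O. All tables are tab-separated, UTF-8, '.' decimal, no
# quoting, full double precision, so that written artifacts are
# byte-stable across runs.

write_tsv <- function(df, path, row_names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = row_names,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a thickness dataset to TSV files
#'
#' Writes three files under `dir`: `<prefix>_thickness.tsv` (subjects x
#' regions, first column `subject_id`, header of region names),
#' `<prefix>_covariates.tsv` (`subject_id`, `age`, `group`) and
#' `<prefix>_atlas.tsv` (`region_id`, `name`, `hemisphere`, `lobe`).
#'
#' @param data a [thickness_dataset()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the three file paths.
#' @seealso [load_thickness_table()] for the inverse.
#' @export
write_thickness_dataset <- function(data, dir, prefix = "cohort") {
  stopifnot(inherits(data, "thickness_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_thickness.tsv", "_covariates.tsv",
                                           "_atlas.tsv")))
  thick <- data.frame(subject_id = data$subject_id, data$thickness,
                      check.names = FALSE)
  write_tsv(thick, paths[1])
  write_tsv(data.frame(subject_id = data$subject_id, age = data$age,
                       group = data$group), paths[2])
  write_tsv(as.data.frame(data$atlas), paths[3])
  invisible(paths)
}

#' Load a thickness dataset from TSV files
#'
#' Reads and cross-validates the three tables written by
#' [write_thickness_dataset()]: every atlas region must appear as a
#' thickness column (matched by name, atlas order imposed), every subject
#' must have covariates (matched by `subject_id`), all thickness cells
#' must be numeric.
#'
#' @param path thickness TSV (subjects x regions, `subject_id` column).
#' @param covariates_path covariates TSV (`subject_id`, `age`, `group`).
#' @param atlas_path atlas TSV (`region_id`, `name`, `hemisphere`, `lobe`).
#' @return a [thickness_dataset()].
#' @export
load_thickness_table <- function(path, covariates_path, atlas_path) {
  for (f in c(path, covariates_path, atlas_path))
    if (!file.exists(f)) stop_covnet("file not found: ", f)
  atlas <- validate_atlas(read.delim(atlas_path, check.names = FALSE,
                                     stringsAsFactors = FALSE))
  thick_tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cov <- read.delim(covariates_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(thick_tab))
    stop_covnet("thickness table needs a subject_id column")
  if (!all(c("subject_id", "age", "group") %in% names(cov)))
    stop_covnet("covariates table needs subject_id, age, group")
  missing_regions <- setdiff(atlas$name, names(thick_tab))
  if (length(missing_regions))
    stop_covnet("thickness table is missing atlas region(s): ",
                paste(missing_regions, collapse = ", "))
  if (anyDuplicated(thick_tab$subject_id))
    stop_covnet("duplicate subject_id in thickness table: ",
                paste(unique(thick_tab$subject_id[duplicated(thick_tab$subject_id)]),
                      collapse = ", "))
  unknown <- setdiff(cov$subject_id, thick_tab$subject_id)
  if (length(unknown))
    stop_covnet("covariates reference unknown subject id(s): ",
                paste(unknown, collapse = ", "))
  missing_cov <- setdiff(thick_tab$subject_id, cov$subject_id)
  if (length(missing_cov))
    stop_covnet("no covariates for subject id(s): ",
                paste(missing_cov, collapse = ", "))
  m <- as.matrix(thick_tab[, atlas$name, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop_covnet("non-numeric or missing thickness values")
  cov <- cov[match(thick_tab$subject_id, cov$subject_id), ]
  thickness_dataset(m, cov$age, cov$group, atlas,
                    subject_id = thick_tab$subject_id)
}

#' Write a correlation matrix (square TSV)
#'
#' @param cmat a [correlation_matrix()].
#' @param path output TSV path.
#' @export
write_correlation_matrix <- function(cmat, path) {
  stopifnot(inherits(cmat, "correlation_matrix"))
  write_tsv(as.data.frame(cmat$r), path, row_names = TRUE)
}

#' Write an edge comparison table (edge-list TSV)
#'
#' @param edges an `edge_comparison` from [compare_edges()].
#' @param path output TSV path.
#' @export
write_edge_comparison <- function(edges, path) {
  write_tsv(as.data.frame(edges), path)
}

#' Write a binary network (square 0/1 TSV and edge list)
#'
#' @param net a [binary_network()].
#' @param path square-matrix TSV path; the edge list goes to
#'   `<path basename>_edges.tsv` next to it.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "binary_network"))
  write_tsv(as.data.frame(net$adjacency), path, row_names = TRUE)
  ut <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  edge_path <- sub("\\.tsv$", "_edges.tsv", path)
  write_tsv(data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L), edge_path)
  invisible(c(path, edge_path))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
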