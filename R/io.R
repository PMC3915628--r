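# Format plumbing: printed reference tables, NIfTI volumes, subject tables.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "compareMRI")
  if (path == "") stop("missing packaged data file: ", file)
  path
}

#' Published cohort-table categorical counts
#'
#' The 2x2 contingency tables printed in the study's cohort table (gender,
#' handedness, medication use) and scanner-split paragraphs, together with
#' the chi-square value printed for each.
#'
#' @return data frame with columns `row`, `description`, `a`, `b`, `c`, `d`,
#'   `printed_chi2`.
#' @export
table1_counts <- function() {
  utils::read.csv(extdata("table1_counts.csv"), stringsAsFactors = FALSE)
}

#' Published age summaries of the two patient groups
#'
#' @return data frame with columns `group`, `mean`, `sd`, `n`.
#' @export
table1_age <- function() {
  utils::read.csv(extdata("table1_age.csv"), stringsAsFactors = FALSE)
}

#' Published diagnostic-performance table
#'
#' The printed AUC, accuracy, feature count, sensitivity, specificity, PPV
#' and NPV of the three pairwise comparisons, plus the reconstruction
#' tolerance each row needs (one printed specificity cell is truncated
#' rather than rounded) and the number of decimals its accuracy is printed
#' with.
#'
#' @return data frame, one row per pairwise comparison.
#' @export
table2_printed <- function() {
  utils::read.csv(extdata("table2_printed.csv"), stringsAsFactors = FALSE)
}

#' Write a density map as NIfTI-1
#'
#' @param map a `density_map` (or 3D array).
#' @param file output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel size in mm when `map` is a bare array.
#' @return the file path, invisibly.
#' @export
write_density_map <- function(map, file, voxel_size = c(1, 1, 1)) {
  vs <- if (inherits(map, "density_map")) map$voxel_size else voxel_size
  img <- RNifti::asNifti(map_data(map))
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a density map from NIfTI-1
#'
#' @param file path to a NIfTI volume.
#' @param compartment compartment label to attach.
#' @return a `density_map` with the voxel size taken from the header.
#' @export
read_density_map <- function(file, compartment = "GM") {
  img <- RNifti::readNifti(file)
  if (length(dim(img)) != 3) stop("expected a 3D volume: ", file)
  density_map(array(as.numeric(img), dim(img)), compartment,
              RNifti::pixdim(img)[1:3])
}

#' Write a subject table as CSV
#'
#' @param subjects data frame with columns id, group, age, gender,
#'   handedness, scanner.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_subject_table <- function(subjects, file) {
  utils::write.csv(subjects, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a subject table from CSV
#'
#' @param file path to a CSV with columns id, group, age, gender,
#'   handedness, scanner.
#' @return data frame of subject records.
#' @export
read_subject_table <- function(file) {
  subjects <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "gender", "handedness", "scanner")
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0)
    stop("subject table misses columns: ", paste(miss, collapse = ", "))
  if (any(subjects$age < 18 | subjects$age > 50))
    stop("ages must lie within the 18-50 inclusion window")
  subjects
}
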