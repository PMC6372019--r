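# File-format interfaces: PNG + JSON sidecar for sections, NIfTI for
# orientation fields and label volumes, TSV for matrices / geometry /
# profiles, CSV per subject for cohorts.

#' Write / read a synthetic section as PNG plus JSON sidecar
#'
#' The image is stored as 8-bit grayscale PNG; boundary curves, the label
#' map (run-length encoded by rows) and the ground-truth curves go into a
#' JSON sidecar next to it.
#'
#' @param section A `cyto_section`.
#' @param path PNG output path; the sidecar is `path` with `.json` appended.
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path) {
  stopifnot(inherits(section, "cyto_section"))
  png::writePNG(section$image, path)
  rle_lab <- rle(as.integer(section$label_map))
  sidecar <- list(
    shape = dim(section$label_map),
    label_rle = list(lengths = rle_lab$lengths, values = rle_lab$values),
    pial_curve = section$pial_curve,
    wm_curve = section$wm_curve,
    truth_profiles = as.data.frame(section$truth_profiles),
    geometry = section$geometry,
    polarity = section$polarity,
    noise_sd = section$noise_sd
  )
  writeLines(jsonlite::toJSON(sidecar, digits = 10, auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_section
#' @export
read_section <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  sc <- jsonlite::fromJSON(paste0(path, ".json"))
  label_map <- matrix(as.integer(rep(sc$label_rle$values,
                                     sc$label_rle$lengths)),
                      sc$shape[1], sc$shape[2])
  truth <- as.matrix(sc$truth_profiles)
  colnames(truth) <- sub("^X", "", colnames(truth))
  structure(
    list(image = img, label_map = label_map,
         pial_curve = as_tibble(sc$pial_curve),
         wm_curve = as_tibble(sc$wm_curve),
         truth_profiles = truth, geometry = sc$geometry,
         polarity = sc$polarity, noise_sd = sc$noise_sd),
    class = "cyto_section"
  )
}

#' Write / read an orientation field as NIfTI volumes
#'
#' Stores four volumes next to `prefix`: `<prefix>_dirs.nii.gz` (4-D),
#' `<prefix>_fa.nii.gz`, `<prefix>_labels.nii.gz`, `<prefix>_mask.nii.gz`.
#'
#' @param field A `cyto_field`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_orientation_field <- function(field, prefix) {
  stopifnot(inherits(field, "cyto_field"))
  RNifti::writeNifti(RNifti::asNifti(field$dirs), paste0(prefix, "_dirs.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(field$fa), paste0(prefix, "_fa.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(field$labels * 1.0),
                     paste0(prefix, "_labels.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(field$mask * 1.0),
                     paste0(prefix, "_mask.nii.gz"))
  invisible(prefix)
}

#' @rdname write_orientation_field
#' @export
read_orientation_field <- function(prefix) {
  arr <- function(suffix) {
    a <- RNifti::readNifti(paste0(prefix, suffix))
    array(as.numeric(a), dim(a))
  }
  dirs <- arr("_dirs.nii.gz")
  structure(
    list(dirs = dirs,
         fa = arr("_fa.nii.gz"),
         labels = array(as.integer(round(arr("_labels.nii.gz"))),
                        dim(dirs)[1:3]),
         mask = array(arr("_mask.nii.gz") > 0.5, dim(dirs)[1:3]),
         grid_shape = dim(dirs)[1:3]),
    class = "cyto_field"
  )
}

#' Write / read a region-by-region matrix as TSV
#'
#' Region ids form the header row and the first column.
#'
#' @param m Matrix with region-id dimnames.
#' @param path Output path.
#' @return `path`, invisibly (writer); the matrix (reader).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  m
}

#' Write / read region geometry as TSV
#'
#' Columns `region`, `x`, `y`, `z`, `volume`, `area`, `hemisphere`.
#'
#' @param geometry Geometry tibble.
#' @param path Output path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_geometry_tsv <- function(geometry, path) {
  write.table(geometry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry_tsv
#' @export
read_geometry_tsv <- function(path) {
  as_tibble(read.delim(path))
}

#' Write a cohort as one CSV matrix per subject
#'
#' Files are named `<prefix>_sub<k>.csv` with a region-id header row and
#' column.
#'
#' @param cohort List of subject matrices.
#' @param prefix Output path prefix.
#' @return Written paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, prefix) {
  paths <- vapply(seq_along(cohort), function(k) {
    p <- sprintf("%s_sub%03d.csv", prefix, k)
    ids <- rownames(cohort[[k]])
    if (is.null(ids)) ids <- as.character(seq_len(nrow(cohort[[k]])))
    df <- data.frame(region = ids, cohort[[k]], check.names = FALSE)
    write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(prefix) {
  paths <- sort(Sys.glob(sprintf("%s_sub*.csv", prefix)))
  lapply(paths, function(p) {
    df <- read.delim(p, sep = ",", check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$region
    m
  })
}

#' Write profiles as TSV (one row per profile, 1,000 value columns)
#'
#' @param profiles Profile tibble with list-column `values`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  vals <- do.call(rbind, profiles$values)
  colnames(vals) <- paste0("v", seq_len(ncol(vals)))
  df <- data.frame(pair_id = profiles$pair_id, region = profiles$region, vals)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
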