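## File formats.
##
## Projection sets travel as a single versioned RDS container (bit-exact
## array round trips) with companion plain-text exporters (CSV spectra and
## directions, YAML protocol) for interchange with other tools.  Volumes are
## written as NIfTI with mm spacing in the header.

PROJECTION_SCHEMA_VERSION <- "1.0"

#' Write/read a projection-set container
#'
#' Single-file container holding spectra, field axis, directions, protocol,
#' optional zero-gradient spectrum and timestamp, with a schema version.
#' Arrays round-trip bit-exactly. Reading a file without the expected schema
#' fields or version raises an explicit error.
#'
#' @param s a [projection_set].
#' @param path file path (conventionally `.eprproj.rds`).
#' @return `read_projection_set` returns the [projection_set];
#'   `write_projection_set` returns `path` invisibly.
#' @export
write_projection_set <- function(s, path) {
  stopifnot(inherits(s, "projection_set"))
  obj <- unclass(s)
  obj$schema <- "eprredox/projection_set"
  obj$schema_version <- PROJECTION_SCHEMA_VERSION
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' @rdname write_projection_set
#' @export
read_projection_set <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$schema, "eprredox/projection_set")) {
    stop("not an eprredox projection-set container (schema mismatch)")
  }
  if (!identical(obj$schema_version, PROJECTION_SCHEMA_VERSION)) {
    stop("projection-set schema version ", obj$schema_version,
         " not supported (expected ", PROJECTION_SCHEMA_VERSION, ")")
  }
  need <- c("spectra", "directions", "field_axis", "protocol")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("malformed container: missing ", paste(miss, collapse = ", "))
  projection_set(obj$spectra, obj$directions, obj$field_axis, obj$protocol,
                 obj$zero_gradient_spectrum, obj$timestamp)
}

#' Export the spectra of a projection set as CSV
#'
#' First column is the field axis (mT); remaining columns are one spectrum
#' per direction (`dir_1`, `dir_2`, ...).
#'
#' @param s a [projection_set].
#' @param path CSV path.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "projection_set"))
  df <- data.frame(field_mT = s$field_axis, t(s$spectra))
  names(df)[-1] <- paste0("dir_", seq_len(nrow(s$spectra)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write/read a volume image as NIfTI
#'
#' The voxel spacing (mm) is carried in the NIfTI header; the centred-FOV
#' origin convention is restored on read.
#'
#' @param v a [volume_image].
#' @param path file path (`.nii` or `.nii.gz`).
#' @export
write_volume_nifti <- function(v, path) {
  stopifnot(inherits(v, "volume_image"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  d <- dim(img)
  volume_image(array(as.numeric(img), d), fov = spacing * d)
}

#' Write/read a scan protocol or reconstruction config as YAML
#'
#' @param x a [scan_protocol] or [recon_config] (any plain list works).
#' @param path YAML path.
#' @export
write_config_yaml <- function(x, path) {
  yaml::write_yaml(c(unclass(x), list(.class = class(x)[1])), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "scan_protocol")) {
    do.call(scan_protocol, obj)
  } else if (identical(cls, "recon_config")) {
    obj$matrix <- unlist(obj$matrix); obj$fov <- unlist(obj$fov)
    do.call(recon_config, obj[setdiff(names(obj), "preset")])
  } else {
    obj
  }
}
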