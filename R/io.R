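# Plain-text readers and writers.
#
# Curve files are tab-separated with a '#key: value' metadata header, the
# dialect every generator writes and every analysis reader accepts. Ion
# frames use standard multi-frame XYZ (Angstrom); scalar grids are written
# in OpenDX format.

#' Write a two-column (or wider) curve file with a metadata header
#'
#' @param data Data frame of numeric columns.
#' @param path Output path.
#' @param metadata Named list written as `#key: value` header lines.
#' @export
write_curve_tsv <- function(data, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("#%s: %s", k, format(metadata[[k]], digits = 15)), con)
  writeLines(paste(names(data), collapse = "\t"), con)
  utils::write.table(data, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a curve file written by [write_curve_tsv()]
#'
#' Also accepts generic two-column ASCII without a header.
#'
#' @param path Input path.
#' @return List with `data` (data frame) and `metadata` (named list; numeric
#'   values are converted).
#' @export
read_curve_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  metadata <- list()
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^#([^:]+):\\s*(.*)$", lines[h]))[[1]]
    if (length(m) == 3L) {
      v <- suppressWarnings(as.numeric(m[3]))
      metadata[[trimws(m[2])]] <- if (is.na(v)) m[3] else v
    }
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  data <- utils::read.table(text = body, header = TRUE, sep = "\t")
  list(data = data, metadata = metadata)
}

#' Write an ion trajectory as multi-frame XYZ
#'
#' Standard XYZ: an atom-count line, a comment line, then `element x y z`
#' rows in Angstrom, repeated per frame.
#'
#' @param traj An `ion_trajectory`.
#' @param path Output path.
#' @param element Element symbol for the ions (default `"Na"`).
#' @export
write_xyz <- function(traj, path, element = "Na") {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("frame %d", f), con)
    if (nrow(fr) > 0L)
      writeLines(sprintf("%s %.4f %.4f %.4f", element,
                         fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path Input path.
#' @param box_dimensions Box edges in Angstrom (length-3); taken as the
#'   coordinate-wise maximum when `NULL`.
#' @param ion_charge Ion charge in e attached to the result.
#' @return An `ion_trajectory`.
#' @export
read_xyz <- function(path, box_dimensions = NULL, ion_charge = 1) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort("malformed XYZ: expected atom count", "smelt_io_error")
    rows <- if (n > 0L) lines[(i + 2L):(i + 1L + n)] else character(0)
    coords <- if (n > 0L) {
      parts <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    } else matrix(numeric(0), 0, 3)
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + n
  }
  if (is.null(box_dimensions)) {
    allc <- do.call(rbind, frames)
    box_dimensions <- if (nrow(allc)) apply(allc, 2, max) else c(1, 1, 1)
  }
  structure(list(frames = frames, box_dimensions = box_dimensions,
                 ion_charge = ion_charge, n_frames = length(frames),
                 metadata = list(source = path)),
            class = "ion_trajectory")
}

#' Write a scalar grid in OpenDX format
#'
#' Works for both `density_grid` (molarity) and `potential_field` (kT/e)
#' objects; `NA` voxels are written as 0.
#'
#' @param grid A `density_grid` or `potential_field`.
#' @param path Output path.
#' @export
write_opendx <- function(grid, path) {
  vals <- grid$values
  dims <- dim(vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("origin %.6g %.6g %.6g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$voxel_edge),
    sprintf("delta 0 %.6g 0", grid$voxel_edge),
    sprintf("delta 0 0 %.6g", grid$voxel_edge),
    sprintf("object 2 class gridconnections counts %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(dims))), con)
  # DX order: z fastest
  v <- as.vector(aperm(vals, c(3, 2, 1)))
  v[!is.finite(v)] <- 0
  writeLines(vapply(split(v, ceiling(seq_along(v) / 3)),
                    function(g) paste(format(g, digits = 7), collapse = " "),
                    character(1)), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Write an I-z curve in the curve dialect
#' @param curve An `iz_curve`.
#' @param path Output path.
#' @export
write_iz_curve <- function(curve, path) {
  write_curve_tsv(
    data.frame(z_nm = curve$z, current_nA = curve$current), path,
    metadata = list(sample_potential_V = curve$sample_potential,
                    probe_potential_V = curve$probe_potential,
                    bias_V = curve$bias, gate_V = curve$gate))
}

#' Read an I-z curve from the curve dialect
#' @param path Input path.
#' @return An `iz_curve`.
#' @export
read_iz_curve <- function(path) {
  x <- read_curve_tsv(path)
  us <- x$metadata$sample_potential_V %||% NA_real_
  up <- x$metadata$probe_potential_V %||% NA_real_
  new_iz_curve(x$data[[1]], x$data[[2]], us, up, metadata = x$metadata)
}
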