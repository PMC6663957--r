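#' Interfile-style header I/O
#'
#' Projection data are stored as a raw little-endian 32-bit float array in
#' sinogram/view/tangential order (tangential fastest) next to a text
#' header (`.hs`); images (`.hv`/`.v`) use z/y/x order (x fastest).  The
#' header is a `key := value` map carrying the full scanner
#' parameterization plus a run-time `geometry` keyword with value
#' `"cylindrical"` or `"blocks-on-cylindrical"`.
#'
#' @param path Header file path.
#' @return `read_interfile_header`: named character vector of keys (in file
#'   order).
#' @name interfile
NULL

fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' @rdname interfile
#' @export
read_interfile_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  has <- grepl(":=", lines, fixed = TRUE)
  if (!all(has)) stop("malformed header line: ", lines[!has][1])
  key <- trimws(sub("\\s*:=.*$", "", lines))
  val <- trimws(sub("^.*?:=\\s*", "", lines))
  key <- sub("^!", "", key)
  keep <- !(key %in% c("INTERFILE", "END OF INTERFILE"))
  stats::setNames(val[keep], key[keep])
}

write_interfile_header <- function(keys, path) {
  lines <- c("!INTERFILE :=",
             paste(names(keys), ":=", unname(keys)),
             "!END OF INTERFILE :=")
  writeLines(lines, path)
}

spec_to_keys <- function(spec) {
  c(
    "scanner name" = spec$name,
    "inner radius (mm)" = fmt_num(spec$inner_radius),
    "number of polygon sides" = as.character(spec$n_sides),
    "number of blocks transaxial" = as.character(spec$n_blocks_transaxial),
    "number of blocks axial" = as.character(spec$n_blocks_axial),
    "number of crystals per block transaxial" =
      as.character(spec$n_crystals_per_block_transaxial),
    "number of crystals per block axial" =
      as.character(spec$n_crystals_per_block_axial),
    "crystal size transaxial (mm)" = fmt_num(spec$crystal_size[1]),
    "crystal size axial (mm)" = fmt_num(spec$crystal_size[2]),
    "crystal size depth (mm)" = fmt_num(spec$crystal_size[3]),
    "crystal gap transaxial (mm)" = fmt_num(spec$crystal_gap_transaxial),
    "crystal gap axial (mm)" = fmt_num(spec$crystal_gap_axial),
    "block gap transaxial (mm)" = fmt_num(spec$block_gap_transaxial),
    "block gap axial (mm)" = fmt_num(spec$block_gap_axial),
    "average depth of interaction (mm)" = fmt_num(spec$average_doi)
  )
}

block_required_keys <- c(
  "crystal gap transaxial (mm)", "crystal gap axial (mm)",
  "block gap transaxial (mm)", "block gap axial (mm)",
  "number of polygon sides"
)

keys_to_spec <- function(keys) {
  need <- c("scanner name", "inner radius (mm)", "number of polygon sides",
            "number of blocks transaxial", "number of blocks axial",
            "number of crystals per block transaxial",
            "number of crystals per block axial",
            "crystal size transaxial (mm)", "crystal size axial (mm)",
            "crystal size depth (mm)")
  miss <- setdiff(need, names(keys))
  if (length(miss)) {
    stop("header missing scanner keys: ", paste(miss, collapse = ", "))
  }
  num <- function(k, default = NULL) {
    if (k %in% names(keys)) as.numeric(keys[[k]]) else default
  }
  scanner_spec(
    name = keys[["scanner name"]],
    inner_radius = num("inner radius (mm)"),
    n_sides = num("number of polygon sides"),
    n_blocks_transaxial = num("number of blocks transaxial"),
    n_blocks_axial = num("number of blocks axial"),
    n_crystals_per_block_transaxial =
      num("number of crystals per block transaxial"),
    n_crystals_per_block_axial = num("number of crystals per block axial"),
    crystal_size = c(num("crystal size transaxial (mm)"),
                     num("crystal size axial (mm)"),
                     num("crystal size depth (mm)")),
    crystal_gap_transaxial = num("crystal gap transaxial (mm)", 0),
    crystal_gap_axial = num("crystal gap axial (mm)", 0),
    block_gap_transaxial = num("block gap transaxial (mm)", 0),
    block_gap_axial = num("block gap axial (mm)", 0),
    average_doi = num("average depth of interaction (mm)")
  )
}

check_geometry_keyword <- function(keys) {
  if (!"geometry" %in% names(keys)) {
    stop("header missing the 'geometry' keyword")
  }
  g <- keys[["geometry"]]
  if (!g %in% c("cylindrical", "blocks-on-cylindrical")) {
    stop("invalid geometry keyword: ", g)
  }
  if (g == "blocks-on-cylindrical") {
    miss <- setdiff(block_required_keys, names(keys))
    if (length(miss)) {
      stop("blocks-on-cylindrical header missing keys: ",
           paste(miss, collapse = ", "))
    }
  }
  g
}

#' Write projection data as interfile header + binary payload
#'
#' @param pd A `proj_data` (or `normalization_sinogram` /
#'   `attenuation_sinogram`, whose kind is recorded in the header).
#' @param base Output path without extension; writes `base.hs` and
#'   `base.s`.
#' @param kind Data kind recorded in the header.
#' @return `base.hs`, invisibly.
#' @export
write_proj_data <- function(pd, base,
                            kind = c("emission", "normalization",
                                     "attenuation")) {
  kind <- match.arg(kind)
  if (inherits(pd, "normalization_sinogram")) {
    pd <- structure(list(info = pd$info,
                         counts = pd$factors), class = "proj_data")
    kind <- "normalization"
  } else if (inherits(pd, "attenuation_sinogram")) {
    pd <- structure(list(info = pd$info,
                         counts = pd$factors), class = "proj_data")
    kind <- "attenuation"
  }
  info <- pd$info
  datafile <- paste0(basename(base), ".s")
  keys <- c(
    "name of data file" = datafile,
    "type of data" = "PET",
    "data kind" = kind,
    "geometry" = info$mode,
    spec_to_keys(info$spec),
    "maximum ring difference" = as.character(info$max_ring_difference),
    "number of sinograms" = as.character(num_sinograms(info)),
    "number of views" = as.character(info$num_views),
    "number of tangential positions" = as.character(info$num_tangential),
    "number format" = "float",
    "number of bytes per pixel" = "4",
    "imagedata byte order" = "LITTLEENDIAN"
  )
  write_interfile_header(keys, paste0(base, ".hs"))
  con <- file(paste0(base, ".s"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(pd$counts), con, size = 4, endian = "little")
  invisible(paste0(base, ".hs"))
}

#' Read projection data from an interfile header
#'
#' Rebuilds the scanner spec and `proj_data_info` from the header (the
#' `geometry` keyword selects the detector model at run time) and reads the
#' float32 payload, validating its size against the header dimensions.
#'
#' @param path Path to the `.hs` header.
#' @param geometry Optional override of the header's geometry keyword.
#' @return A `proj_data` with attribute `data_kind`.
#' @export
read_proj_data <- function(path, geometry = NULL) {
  keys <- read_interfile_header(path)
  g <- if (is.null(geometry)) check_geometry_keyword(keys) else geometry
  spec <- keys_to_spec(keys)
  info <- proj_data_info(
    spec, mode = g,
    max_ring_difference = as.integer(keys[["maximum ring difference"]]),
    num_tangential = as.integer(keys[["number of tangential positions"]])
  )
  ns <- as.integer(keys[["number of sinograms"]])
  nv <- as.integer(keys[["number of views"]])
  if (ns != num_sinograms(info) || nv != info$num_views) {
    stop("header sinogram dimensions inconsistent with scanner parameters")
  }
  datafile <- file.path(dirname(path), keys[["name of data file"]])
  if (!file.exists(datafile)) stop("data file not found: ", datafile)
  n <- ns * nv * as.integer(keys[["number of tangential positions"]])
  sz <- file.info(datafile)$size
  if (sz != 4 * n) {
    stop(sprintf("payload size mismatch: %d bytes, expected %d", sz, 4 * n))
  }
  con <- file(datafile, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  pd <- proj_data(info)
  pd$counts[] <- v
  attr(pd, "data_kind") <- keys[["data kind"]]
  pd
}

#' Write / read a voxel image as interfile header + binary payload
#'
#' @param img A [voxel_image()].
#' @param base Output path without extension; writes `base.hv`, `base.v`.
#' @return `write_image`: `base.hv` invisibly; `read_image`: a
#'   [voxel_image()].
#' @export
write_image <- function(img, base) {
  d <- dim(img$values)
  keys <- c(
    "name of data file" = paste0(basename(base), ".v"),
    "type of data" = "image",
    "matrix size [1]" = as.character(d[1]),
    "matrix size [2]" = as.character(d[2]),
    "matrix size [3]" = as.character(d[3]),
    "scaling factor (mm/pixel) [1]" = fmt_num(img$voxel_size[1]),
    "scaling factor (mm/pixel) [2]" = fmt_num(img$voxel_size[2]),
    "scaling factor (mm/pixel) [3]" = fmt_num(img$voxel_size[3]),
    "origin (mm) [1]" = fmt_num(img$origin[1]),
    "origin (mm) [2]" = fmt_num(img$origin[2]),
    "origin (mm) [3]" = fmt_num(img$origin[3]),
    "number format" = "float",
    "number of bytes per pixel" = "4",
    "imagedata byte order" = "LITTLEENDIAN"
  )
  write_interfile_header(keys, paste0(base, ".hv"))
  con <- file(paste0(base, ".v"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(img$values), con, size = 4, endian = "little")
  invisible(paste0(base, ".hv"))
}

#' @rdname write_image
#' @param path Path to the `.hv` header.
#' @export
read_image <- function(path) {
  keys <- read_interfile_header(path)
  d <- as.integer(c(keys[["matrix size [1]"]], keys[["matrix size [2]"]],
                    keys[["matrix size [3]"]]))
  vs <- as.numeric(c(keys[["scaling factor (mm/pixel) [1]"]],
                     keys[["scaling factor (mm/pixel) [2]"]],
                     keys[["scaling factor (mm/pixel) [3]"]]))
  org <- as.numeric(c(keys[["origin (mm) [1]"]], keys[["origin (mm) [2]"]],
                      keys[["origin (mm) [3]"]]))
  if (any(is.na(org))) org <- c(0, 0, 0)
  datafile <- file.path(dirname(path), keys[["name of data file"]])
  if (!file.exists(datafile)) stop("data file not found: ", datafile)
  n <- prod(d)
  if (file.info(datafile)$size != 4 * n) {
    stop("payload size mismatch for image data")
  }
  con <- file(datafile, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  voxel_image(array(v, dim = d), vs, origin = org)
}
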