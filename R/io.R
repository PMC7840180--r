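#' Read a 3D volume from TIFF, NIfTI or NRRD
#'
#' Multi-page TIFF stacks are interpreted page = z (the anterior-posterior
#' slice axis). TIFF carries no z spacing, so `spacing_override` is required
#' for TIFF unless the caller accepts the (1, 1, 1) placeholder refusal.
#' NIfTI spacing comes from `pixdim`, NRRD spacing from
#' `space directions`/`spacings`.
#'
#' @param path file path (`.tif`/`.tiff`, `.nii`/`.nii.gz`, `.nrrd`).
#' @param spacing_override optional `(sx, sy, sz)` um overriding/filling the
#'   header spacing.
#' @param axes axis-role tags to attach (the on-disk order of e.g. an atlas
#'   file is conventions-dependent, so the caller may re-tag).
#' @param label if `TRUE` return a [LabelVolume()] (integer labels).
#' @return a [Volume()] or [LabelVolume()].
#' @export
read_volume <- function(path, spacing_override = NULL,
                        axes = c("LR", "DV", "AP"), label = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- guess_format(path)
  got <- switch(fmt,
    tiff = read_tiff_stack(path),
    nifti = read_nifti_volume(path),
    nrrd = read_nrrd(path),
    stop("unrecognised volume format: ", path)
  )
  spacing <- got$spacing
  if (!is.null(spacing_override)) spacing <- as.numeric(spacing_override)
  if (is.null(spacing))
    stop("no voxel spacing in header of ", path,
         " and no spacing_override given")
  if (missing(axes) && !is.null(got$axes)) axes <- got$axes
  if (label) {
    lab <- round(got$data)
    LabelVolume(lab, spacing = spacing, axes = axes)
  } else {
    Volume(got$data, spacing = spacing, axes = axes)
  }
}

#' Write a volume to TIFF, NIfTI or NRRD
#'
#' Format is chosen from the file extension. Label volumes are written as
#' unsigned integers; integer-valued data round-trips bit-exactly.
#'
#' @param vol a [Volume()] or [LabelVolume()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  arr <- vol_array(vol)
  fmt <- guess_format(path)
  is_label <- inherits(vol, "LabelVolume")
  res <- try(switch(fmt,
    tiff = write_tiff_stack(arr, path),
    nifti = write_nifti_volume(arr, vol$spacing, path, is_label),
    nrrd = write_nrrd(arr, vol$spacing, path, is_label, axes = vol$axes),
    stop("unrecognised volume format: ", path)
  ), silent = TRUE)
  if (inherits(res, "try-error"))
    stop("failed writing ", path, ": ", attr(res, "condition")$message)
  invisible(path)
}

guess_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.(tif|tiff)$", p)) return("tiff")
  if (grepl("\\.(nii|nii\\.gz)$", p)) return("nifti")
  if (grepl("\\.nrrd$", p)) return("nrrd")
  "unknown"
}

# ---- TIFF ------------------------------------------------------------------

read_tiff_stack <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF ", path, ": ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  # readTIFF returns row-major matrices (rows = image y); store as (x, y, z)
  arr <- array(0, dim = c(d2[2], d2[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  list(data = arr, spacing = NULL)
}

write_tiff_stack <- function(arr, path) {
  intish <- all(arr == round(arr)) && min(arr) >= 0 && max(arr) <= 65535
  pages <- lapply(seq_len(dim(arr)[3]), function(k) {
    m <- t(arr[, , k])
    if (intish) m / 65535 else m
  })
  if (intish) {
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

# ---- NIfTI -----------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI ", path, ": ",
                                           conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- array(arr, dim = dim(arr)[1:3])
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- as.numeric(sp)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- NULL
  list(data = arr, spacing = sp)
}

write_nifti_volume <- function(arr, spacing, path, is_label) {
  if (is_label) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path,
                     datatype = if (is_label) "int32" else "double")
  invisible(path)
}

# ---- NRRD ------------------------------------------------------------------
# Minimal NRRD0004 support: 3D scalar fields, raw or gzip encoding,
# little-endian, the types the Allen CCF distributions use.

nrrd_types <- c(
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
  "uint8_t" = "uint8",
  "short" = "int16", "signed short" = "int16", "int16" = "int16",
  "ushort" = "uint16", "unsigned short" = "uint16", "uint16" = "uint16",
  "int" = "int32", "signed int" = "int32", "int32" = "int32",
  "uint" = "uint32", "unsigned int" = "uint32", "uint32" = "uint32",
  "float" = "float", "double" = "double"
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- read_header_line(con)
    if (is.null(line) || !nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) < 2) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  type <- nrrd_types[[tolower(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]])
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD supported: ", path)
  n <- prod(sizes)
  enc <- tolower(fields[["encoding"]])
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  endian <- if (!is.null(fields[["endian"]]) &&
                grepl("big", fields[["endian"]])) "big" else "little"
  vals <- decode_scalars(payload, type, n, endian)
  spacing <- nrrd_spacing(fields)
  axes <- NULL
  if (!is.null(fields[["birdreg axes"]])) {
    ax <- strsplit(trimws(fields[["birdreg axes"]]), "\\s+")[[1]]
    if (setequal(ax, c("LR", "DV", "AP"))) axes <- ax
  }
  list(data = array(vals, dim = sizes), spacing = spacing, axes = axes)
}

read_header_line <- function(con) {
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) return(if (length(chars)) rawToChar(chars) else NULL)
    if (b == as.raw(10L)) break
    if (b != as.raw(13L)) chars <- c(chars, b)
  }
  rawToChar(chars)
}

decode_scalars <- function(payload, type, n, endian) {
  switch(type,
    uint8 = as.numeric(readBin(payload, "integer", n, size = 1,
                               signed = FALSE)),
    int16 = as.numeric(readBin(payload, "integer", n, size = 2,
                               signed = TRUE, endian = endian)),
    uint16 = as.numeric(readBin(payload, "integer", n, size = 2,
                                signed = FALSE, endian = endian)),
    int32 = as.numeric(readBin(payload, "integer", n, size = 4,
                               endian = endian)),
    uint32 = {
      v <- readBin(payload, "integer", n, size = 4, endian = endian)
      v <- as.numeric(v)
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    float = as.numeric(readBin(payload, "double", n, size = 4,
                               endian = endian)),
    double = readBin(payload, "double", n, size = 8, endian = endian)
  )
}

nrrd_spacing <- function(fields) {
  sd <- fields[["space directions"]]
  if (!is.null(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    if (length(vecs) == 3L) {
      sp <- vapply(vecs, function(v) {
        nums <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
        sqrt(sum(nums^2))
      }, numeric(1))
      return(unname(sp))
    }
  }
  sp <- fields[["spacings"]]
  if (!is.null(sp)) return(as.numeric(strsplit(sp, "\\s+")[[1]]))
  NULL
}

write_nrrd <- function(arr, spacing, path, is_label, axes = NULL) {
  type <- if (is_label || all(arr == round(arr))) "int32" else "double"
  hdr <- c(
    "NRRD0004",
    "# birdreg volume",
    paste0("type: ", if (type == "int32") "int32" else "double"),
    "dimension: 3",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("spacings: ", paste(format(spacing, digits = 15),
                               collapse = " ")),
    "encoding: raw",
    "endian: little",
    if (!is.null(axes)) paste0("birdreg axes:=", paste(axes, collapse = " ")),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (type == "int32") {
    writeBin(as.integer(round(as.vector(arr))), con, size = 4,
             endian = "little")
  } else {
    writeBin(as.double(as.vector(arr)), con, size = 8, endian = "little")
  }
  invisible(path)
}

# ---- tables ----------------------------------------------------------------

#' Read a POI table from CSV
#'
#' Expected columns: `name, x, y, z, space` with coordinates in um.
#'
#' @param path CSV path.
#' @return a [POISet()]; empty table gives an empty set.
#' @export
read_poi_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("POI CSV must have columns name,x,y,z[,space]: ", path)
  if (nrow(df) == 0)
    return(POISet(character(0), matrix(numeric(0), ncol = 3), "sample"))
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v))) stop("non-numeric coordinate in column ", col,
                            " of ", path)
    df[[col]] <- v
  }
  space <- if ("space" %in% names(df)) unique(df$space) else "sample"
  if (length(space) != 1)
    stop("POI table mixes coordinate spaces: ", paste(space, collapse = ", "))
  POISet(df$name, as.matrix(df[, c("x", "y", "z")]), space)
}

#' Write a POI table to CSV
#' @param pois a [POISet()].
#' @param path destination CSV path.
#' @export
write_poi_table <- function(pois, path) {
  utils::write.csv(as.data.frame(pois), path, row.names = FALSE)
  invisible(path)
}

#' Read a landmark-plane correspondence table from CSV
#'
#' Expected columns `a` (reference-atlas plane index, 100 um plates) and `b`
#' (raw-stack plane index); optionally `k`. Rows are the K+1 matched coronal
#' planes bounding K sub-stacks.
#'
#' @param path CSV path.
#' @return a [landmark_table()].
#' @export
read_landmark_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("a", "b") %in% names(df)))
    stop("landmark CSV must have columns a,b: ", path)
  landmark_table(df$a, df$b)
}
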