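#' Read an atomic model (or ensemble) from PDB
#'
#' Parses the mandatory CRYST1 record (the cell drives all reciprocal
#' geometry) and the ATOM/HETATM records, converting orthogonal coordinates
#' to fractional via the standard orthogonalization convention (a along x,
#' b in the xy plane). Multi-model files (MODEL/ENDMDL) yield an
#' [ensemble()].
#'
#' @param path PDB file path.
#' @param wrap Wrap single-model coordinates into `[0, 1)` (default `TRUE`;
#'   ensembles are never wrapped).
#' @return An [atomic_model()], or an [ensemble()] for multi-model files.
#' @export
read_pdb_model <- function(path, wrap = TRUE) {
  lines <- readLines(path)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) {
    stop("PDB file has no CRYST1 record; the unit cell is required",
         call. = FALSE)
  }
  num <- function(str, from, to) as.numeric(substr(str, from, to))
  sg <- trimws(substr(cl[1], 56, 66))
  lat <- lattice(num(cl[1], 7, 15), num(cl[1], 16, 24), num(cl[1], 25, 33),
                 num(cl[1], 34, 40), num(cl[1], 41, 47), num(cl[1], 48, 54),
                 laue_group = if (grepl("^P *41?$", sg) && sg != "P 1")
                   "P4/m" else "P1")
  parse_atoms <- function(ls) {
    at <- ls[grepl("^(ATOM  |HETATM)", ls)]
    if (length(at) == 0) stop("no ATOM/HETATM records", call. = FALSE)
    el <- trimws(substr(at, 77, 78))
    name <- trimws(substr(at, 13, 16))
    el[el == ""] <- substr(name[el == ""], 1, 1)
    occ <- suppressWarnings(as.numeric(substr(at, 55, 60)))
    occ[is.na(occ)] <- 1
    list(el = el, occ = occ,
         xyz = cbind(num(at, 31, 38), num(at, 39, 46), num(at, 47, 54)))
  }
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) <= 1) {
    a <- parse_atoms(lines)
    fr <- orth_to_frac(lat, a$xyz)
    return(atomic_model(
      tibble::tibble(element = a$el, x = fr[, 1], y = fr[, 2], z = fr[, 3],
                     occ = a$occ), lat, wrap = wrap))
  }
  ends <- grep("^ENDMDL", lines)
  snaps <- purrr::map2(model_starts, ends, function(s, e)
    parse_atoms(lines[s:e]))
  a1 <- snaps[[1]]
  fr1 <- orth_to_frac(lat, a1$xyz)
  model <- atomic_model(
    tibble::tibble(element = a1$el, x = fr1[, 1], y = fr1[, 2],
                   z = fr1[, 3], occ = a1$occ), lat, wrap = FALSE)
  coords <- array(NA_real_, c(nrow(model), 3, length(snaps)))
  for (i in seq_along(snaps)) {
    if (nrow(snaps[[i]]$xyz) != nrow(model)) {
      stop("model ", i, " has a different atom count", call. = FALSE)
    }
    coords[, , i] <- orth_to_frac(lat, snaps[[i]]$xyz)
  }
  ensemble(model, coords)
}

#' Write an atomic model or ensemble to PDB
#'
#' Emits CRYST1 (with the stated space-group label) and ATOM records in the
#' standard fixed-width layout; ensembles become MODEL/ENDMDL blocks.
#'
#' @param x An [atomic_model()] or [ensemble()].
#' @param path Output path.
#' @param space_group CRYST1 space-group label (default `"P 1"`).
#' @return `path`, invisibly.
#' @export
write_pdb_model <- function(x, path, space_group = "P 1") {
  model <- if (inherits(x, "ensemble")) x$model else x
  stopifnot(inherits(model, "atomic_model"))
  lat <- model_lattice(model)
  hdr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                 lat$a, lat$b, lat$c, lat$alpha, lat$beta, lat$gamma,
                 space_group, 1L)
  atom_block <- function(xyz) {
    sprintf("ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(model)),
            substr(model$element, 1, 4), "MOL", "A", 1L,
            xyz[, 1], xyz[, 2], xyz[, 3], model$occ, 0,
            model$element)
  }
  if (inherits(x, "ensemble")) {
    blocks <- purrr::map(seq_len(n_snapshots(x)), function(i) {
      xyz <- frac_to_orth(lat, snapshot_coords(x, i))
      c(sprintf("MODEL     %4d", i), atom_block(xyz), "ENDMDL")
    })
    writeLines(c(hdr, unlist(blocks), "END"), path)
  } else {
    xyz <- frac_to_orth(lat, coord_matrix(model))
    writeLines(c(hdr, atom_block(xyz), "END"), path)
  }
  invisible(path)
}

#' h k l I text exchange format
#'
#' One whitespace-separated record per measured point: physical Miller
#' indices (half-integers printed exactly, e.g. `0.5`) and the intensity.
#' [read_hkl()] inverts [write_hkl()] bit-exactly on the values.
#'
#' @param map A [diffuse_map()] or `bragg_set`.
#' @param path File path.
#' @return `path` invisibly (write); a [diffuse_map()] (read).
#' @export
write_hkl <- function(map, path) {
  map <- as_diffuse_map(map)
  meas <- map_measured(map)
  lines <- sprintf("%s %s %s %s",
                   format(map$h[meas], trim = TRUE, digits = 15),
                   format(map$k[meas], trim = TRUE, digits = 15),
                   format(map$l[meas], trim = TRUE, digits = 15),
                   format(map$intensity[meas], trim = TRUE, digits = 17))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hkl
#' @param lat The [lattice()] the indices refer to.
#' @param sampling Integer per-axis sampling factors of the file's lattice.
#' @export
read_hkl <- function(path, lat, sampling = c(1L, 1L, 1L)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    grid <- new_reciprocal_grid(
      tibble::tibble(ih = integer(), ik = integer(), il = integer(),
                     h = numeric(), k = numeric(), l = numeric(),
                     s = numeric()), lat, sampling, NA_real_)
    return(diffuse_map(grid, numeric(0), provenance = "observed"))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) != 4)
  if (length(bad) > 0) {
    stop("malformed h k l I record at line ", bad[1], call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE)
  if (anyNA(m)) {
    stop("non-numeric h k l I record at line ",
         which(apply(is.na(m), 1, any))[1], call. = FALSE)
  }
  sampling <- as.integer(sampling)
  idx <- sweep(m[, 1:3, drop = FALSE], 2, sampling, "*")
  if (any(abs(idx - round(idx)) > 1e-6)) {
    stop("indices are not multiples of 1/sampling at line ",
         which(apply(abs(idx - round(idx)) > 1e-6, 1, any))[1],
         call. = FALSE)
  }
  idx <- round(idx)
  grid <- new_reciprocal_grid(
    tibble::tibble(ih = as.integer(idx[, 1]), ik = as.integer(idx[, 2]),
                   il = as.integer(idx[, 3]),
                   h = m[, 1], k = m[, 2], l = m[, 3],
                   s = s_modulus(lat, m[, 1], m[, 2], m[, 3])),
    lat, sampling, NA_real_)
  diffuse_map(grid, m[, 4], provenance = "observed")
}

#' Voxel-grid container (text)
#'
#' A self-describing text format for intensity maps: a `# key: value`
#' header (cell, Laue group, sampling, d_min, provenance, mask convention)
#' followed by one `ih ik il intensity measured` record per point in fixed
#' l-fastest traversal order. `read_grid(write_grid(x))` reproduces the map
#' bit-exactly.
#'
#' @param map A [diffuse_map()].
#' @param path File path.
#' @return `path` invisibly (write); a [diffuse_map()] (read).
#' @export
write_grid <- function(map, path) {
  map <- as_diffuse_map(map)
  lat <- attr(map, "lattice")
  ord <- order(map$ih, map$ik, map$il)   # l fastest within fixed h,k
  hdr <- c(
    sprintf("# cell: %.17g %.17g %.17g %.17g %.17g %.17g",
            lat$a, lat$b, lat$c, lat$alpha, lat$beta, lat$gamma),
    sprintf("# laue: %s", lat$laue_group),
    sprintf("# sampling: %d %d %d", attr(map, "sampling")[1],
            attr(map, "sampling")[2], attr(map, "sampling")[3]),
    sprintf("# d_min: %.17g", attr(map, "d_min") %||% NA_real_),
    sprintf("# provenance: %s", map_provenance(map) %||% "unknown"),
    "# mask: 1 = measured, 0 = unmeasured")
  body <- sprintf("%d %d %d %.17g %d", map$ih[ord], map$ik[ord],
                  map$il[ord], map$intensity[ord],
                  as.integer(map_measured(map)[ord]))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) stop("grid file missing header key ", key,
                              call. = FALSE)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  cell <- as.numeric(strsplit(get("cell"), " +")[[1]])
  sampling <- as.integer(strsplit(get("sampling"), " +")[[1]])
  d_min <- suppressWarnings(as.numeric(get("d_min")))
  lat <- lattice(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                 laue_group = get("laue"), multiplicity = sampling)
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), " +"))),
              ncol = 5, byrow = TRUE)
  h <- m[, 1] / sampling[1]; k <- m[, 2] / sampling[2]
  l <- m[, 3] / sampling[3]
  grid <- new_reciprocal_grid(
    tibble::tibble(ih = as.integer(m[, 1]), ik = as.integer(m[, 2]),
                   il = as.integer(m[, 3]), h = h, k = k, l = l,
                   s = s_modulus(lat, h, k, l)),
    lat, sampling, d_min)
  diffuse_map(grid, m[, 4], measured = m[, 5] == 1,
              provenance = get("provenance"))
}

#' Detector geometry and orientation as plain-text key=value config
#'
#' The setting matrix is written as nine whitespace-separated numbers,
#' row-major, in Angstrom^-1 per fractional index.
#'
#' @param geom A [detector_geometry()].
#' @param setting An [orientation_setting()] (optional on write).
#' @param path File path.
#' @return `path` invisibly (write); a list `geometry`, `setting` (read).
#' @export
write_geometry <- function(geom, path, setting = NULL) {
  ln <- c(
    sprintf("distance_mm=%.17g", geom$distance),
    sprintf("pixel_mm=%.17g", geom$pixel),
    sprintf("center_px=%.17g %.17g", geom$center[1], geom$center[2]),
    sprintf("wavelength_A=%.17g", geom$wavelength),
    sprintf("dims=%d %d", geom$dims[1], geom$dims[2]),
    sprintf("polarization=%.17g", geom$polarization),
    sprintf("polarization_azimuth_deg=%.17g", geom$polarization_azimuth),
    sprintf("saturation_adu=%.17g", geom$saturation))
  if (!is.null(setting)) {
    ln <- c(ln,
            sprintf("setting_matrix=%s",
                    paste(format(t(setting$A), digits = 17),
                          collapse = " ")),
            sprintf("phi_deg=%.17g", setting$phi),
            sprintf("axis=%s", paste(format(setting$axis, digits = 17),
                                     collapse = " ")))
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  g <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("geometry config missing key ", key, call. = FALSE)
    as.numeric(strsplit(trimws(vals[i]), " +")[[1]])
  }
  geom <- detector_geometry(g("distance_mm"), g("pixel_mm"),
                            g("center_px"), g("wavelength_A"),
                            dims = g("dims"),
                            polarization = g("polarization"),
                            polarization_azimuth =
                              g("polarization_azimuth_deg"),
                            saturation = g("saturation_adu"))
  setting <- NULL
  if ("setting_matrix" %in% keys) {
    setting <- orientation_setting(
      A = matrix(g("setting_matrix"), 3, 3, byrow = TRUE),
      phi = g("phi_deg"), axis = g("axis"))
  }
  list(geometry = geom, setting = setting)
}

#' 16-bit grayscale TIFF image exchange
#'
#' Counts are clipped to `[0, 65535]` and rounded on write; the mask can be
#' written as a companion image. Requires the `tiff` package.
#'
#' @param img A [detector_image()].
#' @param path TIFF path.
#' @param mask_path Optional companion mask TIFF (255 = masked).
#' @return `path` invisibly (write); a [detector_image()] (read).
#' @export
write_image_tiff <- function(img, path, mask_path = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF output", call. = FALSE)
  }
  v <- round(pmin(pmax(img$counts, 0), 65535))
  tiff::writeTIFF(t(v) / 65535, path, bits.per.sample = 16L)
  if (!is.null(mask_path)) {
    tiff::writeTIFF(t(img$mask * 1), mask_path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' @rdname write_image_tiff
#' @param geom,setting Geometry (and optional orientation) to attach.
#' @export
read_image_tiff <- function(path, geom, setting = NULL, mask_path = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF input", call. = FALSE)
  }
  v <- t(tiff::readTIFF(path)) * 65535
  mask <- if (!is.null(mask_path)) t(tiff::readTIFF(mask_path)) > 0 else NULL
  detector_image(round(v), geom, setting, mask)
}

#' Raw binary image with sidecar text header
#'
#' Unsigned 16-bit little-endian pixels, column-major; the sidecar
#' (`<path>.hdr`) records the dimensions.
#'
#' @inheritParams write_image_tiff
#' @export
write_image_raw <- function(img, path) {
  v <- as.integer(round(pmin(pmax(img$counts, 0), 65535)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 2, endian = "little")
  writeLines(c(sprintf("dims=%d %d", nrow(img$counts), ncol(img$counts)),
               "dtype=uint16le", "order=column-major"),
             paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_image_raw
#' @param geom,setting Geometry (and optional orientation) to attach.
#' @export
read_image_raw <- function(path, geom, setting = NULL) {
  hdr <- readLines(paste0(path, ".hdr"))
  d <- as.integer(strsplit(sub("^dims=", "",
                               grep("^dims=", hdr, value = TRUE)),
                           " +")[[1]])
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = prod(d), size = 2, signed = FALSE,
               endian = "little")
  detector_image(matrix(v, d[1], d[2]), geom, setting)
}

#' Write a Patterson map in CCP4/MRC format
#'
#' Minimal mode-2 (32-bit float) MRC writer: map values on the full box
#' grid, cell set to the Patterson box, axes in x-fastest order.
#'
#' @param pmap A `patterson_map` from [patterson_fft()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(pmap, path) {
  d <- dim(pmap$values)
  box <- pmap$box
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(d)                     # NX NY NZ
  wi(2L)                    # MODE 2 = float32
  wi(c(0L, 0L, 0L))         # NXSTART..
  wi(d)                     # MX MY MZ
  wf(c(box$a, box$b, box$c, box$alpha, box$beta, box$gamma))
  wi(c(1L, 2L, 3L))         # MAPC MAPR MAPS
  wf(c(min(pmap$values), max(pmap$values), mean(pmap$values)))
  wi(c(1L, 0L))             # ISPG, NSYMBT
  wi(rep(0L, 25))           # EXTRA
  wf(c(0, 0, 0))            # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(pmap$values))
  wi(0L)                    # NLABL
  writeBin(raw(800), con)   # labels
  wf(as.vector(pmap$values))
  invisible(path)
}
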