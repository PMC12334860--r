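#' Write a voxel grid as NRRD
#'
#' Minimal NRRD 4 writer for 3-D scalar volumes: `double` (densities,
#' doses) or `uint8` (binary masks), raw little-endian encoding, spacing
#' and origin carried in `space directions` / `space origin`.
#'
#' @param grid a [voxel_grid()], or a logical array plus `geometry` for
#'   masks.
#' @param path output path (`.nrrd`).
#' @param type `"double"` or `"uint8"`.
#' @param geometry when `grid` is a bare array: list with `spacing`,
#'   `origin`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(grid, path, type = c("double", "uint8"),
                       geometry = NULL) {
  type <- match.arg(type)
  if (inherits(grid, "voxel_grid")) {
    vals <- grid$values; spacing <- grid$spacing; origin <- grid$origin
  } else {
    if (is.null(geometry))
      clrt_abort("geometry required for bare arrays", "clrt_invalid_argument")
    vals <- grid; spacing <- geometry$spacing; origin <- geometry$origin
  }
  dims <- dim(vals)
  header <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    sprintf("type: %s", if (type == "uint8") "unsigned char" else "double"),
    "dimension: 3",
    "space dimension: 3",
    sprintf("sizes: %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            origin[1], origin[2], origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (type == "uint8") {
    writeBin(as.raw(as.integer(vals != 0)), con)
  } else {
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
  }
  invisible(path)
}

parse_nrrd_triplets <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(t)
    as.numeric(strsplit(gsub("[()]", "", t), ",")[[1]]))
}

#' Read an NRRD volume
#'
#' Supports the subset this package writes (3-D, raw or ascii encoding,
#' little-endian, scalar types) plus gzip-encoded raw data.
#'
#' @param path `.nrrd` file.
#' @return A [voxel_grid()]; mask volumes come back as 0/1 doubles.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD"))
    clrt_abort(sprintf("%s is not an NRRD file", path), "clrt_io_error")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(":=?", line))
    pos <- regexpr(":=?", line)
    key <- trimws(substr(line, 1, pos - 1))
    val <- trimws(substr(line, pos + attr(pos, "match.length"), nchar(line)))
    fields[[tolower(key)]] <- val
  }
  dims <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(dims) != 3)
    clrt_abort("only 3-D NRRD volumes are supported", "clrt_io_error")
  n <- prod(dims)
  type <- fields$type
  enc <- fields$encoding %||% "raw"
  read_payload <- function(con) {
    if (type %in% c("unsigned char", "uchar", "uint8", "uint8_t")) {
      as.numeric(readBin(con, "raw", n = n))
    } else if (type %in% c("double", "float")) {
      sz <- if (type == "float") 4L else 8L
      readBin(con, "double", n = n, size = sz, endian = "little")
    } else {
      clrt_abort(sprintf("unsupported NRRD type '%s'", type), "clrt_io_error")
    }
  }
  vals <- if (enc == "raw") {
    read_payload(con)
  } else if (enc %in% c("gzip", "gz")) {
    raw_rest <- readBin(con, "raw", n = file.size(path))
    bc <- rawConnection(memDecompress(raw_rest, type = "gzip"))
    on.exit(close(bc), add = TRUE)
    read_payload(bc)
  } else if (enc %in% c("ascii", "text", "txt")) {
    scan(con, what = double(), n = n, quiet = TRUE)
  } else {
    clrt_abort(sprintf("unsupported NRRD encoding '%s'", enc), "clrt_io_error")
  }
  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space directions`)) {
    tri <- parse_nrrd_triplets(fields$`space directions`)
    spacing <- vapply(seq_len(3), function(a) tri[[a]][a], 0)
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  if (!is.null(fields$`space origin`))
    origin <- parse_nrrd_triplets(fields$`space origin`)[[1]]
  voxel_grid(array(vals, dims), spacing, origin)
}

#' Read a raster volume (NRRD or NIfTI)
#'
#' NRRD goes through the package reader; `.nii`/`.nii.gz` through RNifti,
#' taking spacing from the pixel dimensions and origin from the xform
#' translation.
#'
#' @param path file path.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    xf <- RNifti::xform(img)
    voxel_grid(array(as.numeric(img), dim(img)[1:3]),
               spacing = abs(pd[1:3]), origin = as.numeric(xf[1:3, 4]))
  } else {
    clrt_abort(sprintf("unsupported volume format: %s", path), "clrt_io_error")
  }
}

#' Write a structure set as NRRD masks
#'
#' One `uint8` NRRD per structure, named `<label>.nrrd`.
#'
#' @param structures a [structure_set()].
#' @param grid the reference [voxel_grid()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_structures <- function(structures, grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(structures$masks))
    write_nrrd(structures$masks[[lab]], file.path(dir, paste0(lab, ".nrrd")),
               type = "uint8",
               geometry = list(spacing = grid$spacing, origin = grid$origin))
  invisible(dir)
}

#' Read a directory of structure masks
#'
#' @param dir directory of `<label>.nrrd` / `<label>.nii[.gz]` masks.
#' @param grid the reference [voxel_grid()].
#' @return A [structure_set()].
#' @export
read_structures <- function(dir, grid) {
  files <- list.files(dir, pattern = "\\.(nrrd|nii|nii\\.gz)$",
                      full.names = TRUE)
  if (length(files) == 0)
    clrt_abort(sprintf("no mask volumes found in %s", dir), "clrt_io_error")
  masks <- list()
  for (f in files) {
    lab <- sub("\\.(nrrd|nii|nii\\.gz)$", "", basename(f))
    masks[[lab]] <- array(read_volume(f)$values != 0, grid$dims)
  }
  structure_set(masks, grid)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a plan as structured text
#'
#' Versioned, fully precision-preserving text format: prescription,
#' fractions, one beam per line (target, direction, weight), the objective
#' trace, and any constraint violations. [read_plan()] round-trips it.
#'
#' @param plan a `clrt_plan` from [optimize_weights()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  lines <- c(
    "# clrt plan v1",
    sprintf("prescription_gy: %s", fmt_num(plan$prescription)),
    sprintf("fractions: %d", plan$fractions),
    sprintf("iterations: %d", plan$iterations),
    sprintf("converged: %s", if (plan$converged) "true" else "false"),
    sprintf("n_beams: %d", length(plan$weights)),
    "beams: tx ty tz dx dy dz weight",
    vapply(seq_along(plan$beams), function(j) {
      b <- plan$beams[[j]]
      paste(c(fmt_num(b$target), fmt_num(b$direction),
              fmt_num(plan$weights[j])), collapse = " ")
    }, ""),
    sprintf("trace: %s", paste(fmt_num(plan$trace), collapse = " ")),
    sprintf("constraint_violation: %s",
            paste(fmt_num(plan$constraint_violation), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a plan written by [write_plan()]
#'
#' @param path plan file.
#' @return A list with `beams`, `weights`, `trace`, `prescription`,
#'   `fractions`, `iterations`, `converged`, `constraint_violation`
#'   (class `clrt_plan`; no dose grid — recompute via [accumulate_dose()]).
#' @export
read_plan <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "# clrt plan v1"))
    clrt_abort(sprintf("%s is not a clrt plan file", path), "clrt_io_error")
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)[1]
    sub(paste0("^", key, ": "), "", ln)
  }
  n_beams <- as.integer(get_field("n_beams"))
  beam_start <- grep("^beams:", lines) + 1
  beams <- vector("list", n_beams)
  weights <- numeric(n_beams)
  for (j in seq_len(n_beams)) {
    v <- as.numeric(strsplit(lines[beam_start + j - 1], " ")[[1]])
    beams[[j]] <- beam(v[1:3], v[4:6], v[7])
    weights[j] <- v[7]
  }
  cv <- get_field("constraint_violation")
  structure(list(
    beams = beams, weights = weights,
    trace = as.numeric(strsplit(get_field("trace"), " ")[[1]]),
    prescription = as.numeric(get_field("prescription_gy")),
    fractions = as.integer(get_field("fractions")),
    iterations = as.integer(get_field("iterations")),
    converged = identical(get_field("converged"), "true"),
    constraint_violation = if (is.na(cv) || cv == "") numeric(0) else
      as.numeric(strsplit(cv, " ")[[1]])
  ), class = "clrt_plan")
}

#' Export DVH curves as CSV
#'
#' @param dvhs a `dvh_curve` or list of them.
#' @param path output `.csv` (columns `structure`, `dose_gy`,
#'   `volume_fraction`).
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  if (inherits(dvhs, "dvh_curve")) dvhs <- list(dvhs)
  tab <- do.call(rbind, lapply(dvhs, as.data.frame))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a plan-indices report as structured text
#'
#' @param indices a [plan_indices()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indices_report <- function(indices, path) {
  keys <- c("CI", "TCI", "CN", "GI", "V100", "V100PTV", "VPTV",
            "R100eff", "R50eff")
  writeLines(c("# clrt indices v1",
               sprintf("%s: %s", keys,
                       vapply(keys, function(k) fmt_num(indices[[k]]), ""))),
             path)
  invisible(path)
}
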