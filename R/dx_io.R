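#' Read an OpenDX regular-grid scalar map
#'
#' Parses the ASCII OpenDX dialect used for volumetric free-energy maps
#' (`object 1 class gridpositions`, orthogonal deltas, scalar data with the
#' z index varying fastest). Values equal to the masked-voxel sentinel
#' (see [write_volumetric()]) are restored as masked voxels.
#'
#' @param path path to a `.dx` file.
#' @param sentinel value that marks masked voxels, kJ/mol; `NULL` disables
#'   sentinel detection. Default 999.
#' @return A [scalar_field()].
#' @export
read_volumetric <- function(path, sentinel = 999) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  find1 <- function(pat, what) {
    i <- grep(pat, lines)
    if (!length(i)) stop("malformed OpenDX file (", path, "): missing ", what)
    i[1L]
  }
  ig <- find1("^object\\s+1\\s+class\\s+gridpositions\\s+counts", "gridpositions header")
  shape <- parse_nums(lines[ig], "counts line", n_tail = 3L)
  if (any(shape != round(shape)) || any(shape < 1))
    stop("malformed OpenDX file (", path, "): bad counts line: ", lines[ig])
  shape <- as.integer(shape)
  io <- find1("^origin\\b", "origin")
  origin <- parse_nums(lines[io], "origin line", n_tail = 3L)
  id <- grep("^delta\\b", lines)
  if (length(id) != 3L)
    stop("malformed OpenDX file (", path, "): expected 3 delta lines, found ",
         length(id))
  deltas <- t(vapply(lines[id], parse_nums, numeric(3), what = "delta line",
                     n_tail = 3L, USE.NAMES = FALSE))
  if (any(abs(deltas[lower.tri(deltas) | upper.tri(deltas)]) > 1e-12))
    stop("non-regular grid in ", path, ": off-diagonal delta components ",
         "(only axis-aligned orthogonal grids are supported)")
  spacing <- diag(deltas)
  ia <- find1("^object\\s+3\\s+class\\s+array.*data\\s+follows", "data array header")
  items <- parse_nums(lines[ia], "items count", pick = "items")
  n <- prod(shape)
  if (items != n)
    stop("malformed OpenDX file (", path, "): items ", items,
         " does not match counts product ", n, " at line: ", lines[ia])
  body <- lines[-seq_len(ia)]
  body <- body[!grepl("^(object|attribute|component|end)\\b", body) &
                 nzchar(trimws(body))]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  if (anyNA(vals))
    stop("malformed OpenDX file (", path, "): non-numeric token in data array")
  if (length(vals) != n)
    stop("malformed OpenDX file (", path, "): data array has ", length(vals),
         " values, expected ", n, " (file truncated?)")
  ## OpenDX order: z fastest, x slowest -> permute into R's x-fastest layout
  arr <- aperm(array(vals, dim = rev(shape)), c(3L, 2L, 1L))
  mask <- NULL
  if (!is.null(sentinel)) {
    mask <- arr == sentinel
    if (any(mask)) arr[mask] <- 0
  }
  scalar_field(grid_spec(origin, spacing, shape), arr, mask)
}

parse_nums <- function(line, what, n_tail = NULL, pick = NULL) {
  toks <- strsplit(trimws(line), "\\s+")[[1L]]
  if (!is.null(pick)) {
    i <- match(pick, toks)
    if (is.na(i) || i == length(toks))
      stop("malformed OpenDX ", what, ": ", line)
    v <- suppressWarnings(as.numeric(toks[i + 1L]))
    if (is.na(v)) stop("malformed OpenDX ", what, ": ", line)
    return(v)
  }
  v <- suppressWarnings(as.numeric(toks))
  v <- v[!is.na(v)]
  if (length(v) < n_tail) stop("malformed OpenDX ", what, ": ", line)
  utils::tail(v, n_tail)
}

#' Write a scalar field as an OpenDX map
#'
#' Emits the ASCII `gridpositions` dialect (3 values per line, z fastest)
#' readable by [read_volumetric()] and by standard molecular viewers.
#' Masked voxels are written as a sentinel value chosen far above any
#' energy cutoff so they can never re-enter the state space on re-read.
#'
#' @param field a [scalar_field()].
#' @param path output path.
#' @param sentinel value written for masked voxels, kJ/mol (default 999);
#'   `NULL` disables masking support, in which case non-finite or masked
#'   voxels are an error.
#' @return `path`, invisibly.
#' @export
write_volumetric <- function(field, path, sentinel = 999) {
  stopifnot(inherits(field, "scalar_field"))
  g <- field$grid
  vals <- field$values
  if (is.null(sentinel)) {
    if (any(field$mask) || any(!is.finite(vals)))
      stop("field has masked or non-finite voxels and sentinel writing is disabled")
  } else {
    vals[field$mask | !is.finite(vals)] <- sentinel
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$shape[1], g$shape[2], g$shape[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing[1]),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing[2]),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$shape[1], g$shape[2], g$shape[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n_voxels(g))
  ), con)
  flat <- as.vector(aperm(vals, c(3L, 2L, 1L)))  # z fastest on disk
  n <- length(flat)
  pad <- (3L - n %% 3L) %% 3L
  m <- matrix(c(sprintf("%.6g", flat), rep("", pad)), nrow = 3L)
  rows <- trimws(apply(m, 2L, paste, collapse = " "))
  writeLines(rows, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "energy (kJ/mol)" class field'), con)
  invisible(path)
}
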