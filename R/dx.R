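## OpenDX scalar-grid interchange for potential maps.
##
## The format is the regular-grid dialect written by APBS and read by most
## visualization tools: a gridpositions object (counts, origin, three delta
## rows), a gridconnections object, and a rank-0 data array with values in
## z-fastest node order.  Only uniform axis-aligned spacings are supported.

#' Read an OpenDX scalar grid
#'
#' @param path DX file path.
#' @param units unit label to attach to the returned map.
#' @return a `potential_map`.
#' @export
read_dx <- function(path, units = "kT/e") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  grab <- function(pattern) {
    hit <- grep(pattern, lines)
    if (!length(hit)) stop("malformed DX header: missing '", pattern, "'")
    hit[1]
  }
  cnt_line <- lines[grab("gridpositions")]
  counts <- as.integer(tail(strsplit(trimws(cnt_line), "\\s+")[[1]], 3))
  if (anyNA(counts) || length(counts) != 3) stop("malformed DX counts line")
  origin <- as.numeric(strsplit(trimws(lines[grab("^\\s*origin")]), "\\s+")[[1]][-1])
  if (length(origin) != 3 || anyNA(origin)) stop("malformed DX origin line")
  delta_idx <- grep("^\\s*delta", lines)
  if (length(delta_idx) != 3) stop("malformed DX header: expected 3 delta rows")
  deltas <- t(vapply(lines[delta_idx], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][-1])
  }, numeric(3)))
  diag_d <- diag(deltas)
  if (any(abs(deltas - diag(diag_d)) > 1e-9)) {
    stop("only axis-aligned DX grids are supported")
  }
  if (max(abs(diag_d - diag_d[1])) > 1e-9) stop("only uniform DX spacings are supported")
  data_at <- grab("data follows")
  nvals <- prod(counts)
  vals <- scan(text = paste(lines[(data_at + 1):length(lines)], collapse = "\n"),
               what = numeric(), n = nvals, quiet = TRUE)
  if (length(vals) != nvals) {
    stop("DX data block holds ", length(vals), " values, expected ", nvals)
  }
  ## DX order: z fastest, x slowest -> fill an (nz, ny, nx) array then permute
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  potential_map(origin, diag_d[1], arr, units)
}

#' Write a potential map as OpenDX
#'
#' @param map a `potential_map`.
#' @param path destination file.
#' @param digits significant digits for the data values.
#' @return `path`, invisibly.
#' @export
write_dx <- function(map, path, digits = 6) {
  stopifnot(inherits(map, "potential_map"))
  n <- map$dims
  h <- map$spacing
  vals <- as.numeric(aperm(map$values, c(3, 2, 1)))  # z fastest
  rows <- split(vals, ceiling(seq_along(vals) / 3))
  header <- c(
    sprintf("# OpenDX scalar grid (%s)", map$units),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", map$origin[1], map$origin[2], map$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", h),
    sprintf("delta 0.000000 %.6f 0.000000", h),
    sprintf("delta 0.000000 0.000000 %.6f", h),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(n))
  )
  body <- vapply(rows, function(v) {
    paste(formatC(v, digits = digits, format = "g"), collapse = " ")
  }, character(1))
  writeLines(c(header, body,
               'attribute "dep" string "positions"',
               'object "regular positions regular connections" class field'),
             path)
  invisible(path)
}
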