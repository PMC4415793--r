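#' @title ESRI ASCII grid input/output
#'
#' @description Plain-text single-band raster format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values, top row first.  Used
#' here as the on-disk raster format for climatologies, masks and risk
#' layers.
#'
#' @name ascii_grid
NULL

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @return a list with `data` (numeric matrix, `NA` for nodata) and
#'   `geometry` (`xll`, `yll`, `cellsize`, `nodata`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has wrong cell count")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(data = m,
       geometry = list(xll = hdr$xllcorner, yll = hdr$yllcorner,
                       cellsize = hdr$cellsize, nodata = nodata))
}

#' Write an ESRI ASCII grid
#'
#' @param data numeric matrix (`NA` written as the nodata value).
#' @param path output `.asc` path.
#' @param geometry list with `xll`, `yll`, `cellsize` and optionally
#'   `nodata` (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(data, path, geometry = list()) {
  xll <- geometry$xll %||% 0
  yll <- geometry$yll %||% 0
  cs <- geometry$cellsize %||% 1
  nodata <- geometry$nodata %||% -9999
  m <- data
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(data)), paste("nrows", nrow(data)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cs, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Write a risk grid as one ASCII grid per layer
#'
#' @param grid a [risk_grid()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix; files are `<prefix><layer>.asc`.
#' @return character vector of written paths, invisibly.
#' @export
write_risk_grid <- function(grid, dir, prefix = "") {
  stopifnot(inherits(grid, "risk_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(grid$layers), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".asc"))
    write_ascii_grid(grid$layers[[nm]], p, grid$geometry)
    p
  }, character(1))
  invisible(paths)
}

#' Read a monthly climatology raster stack
#'
#' Expects 24 ASCII grids in one directory: `tmin_01.asc` ... `tmin_12.asc`
#' and `tmax_01.asc` ... `tmax_12.asc`, all on the same geometry.
#'
#' @param dir directory containing the grids.
#' @return a `climate_stack`: list with `tmin` and `tmax` arrays
#'   (`nrows x ncols x 12`) and `geometry`.
#' @export
read_climate_stack <- function(dir) {
  get <- function(var, m) {
    p <- file.path(dir, sprintf("%s_%02d.asc", var, m))
    if (!file.exists(p)) stop("missing climatology grid: ", p)
    read_ascii_grid(p)
  }
  first <- get("tmin", 1)
  nr <- nrow(first$data); nc <- ncol(first$data)
  tmin <- array(NA_real_, c(nr, nc, 12))
  tmax <- array(NA_real_, c(nr, nc, 12))
  for (m in 1:12) {
    a <- get("tmin", m); b <- get("tmax", m)
    if (!all(dim(a$data) == c(nr, nc)) || !all(dim(b$data) == c(nr, nc)))
      stop("climatology grids have inconsistent dimensions")
    tmin[, , m] <- a$data
    tmax[, , m] <- b$data
  }
  climate_stack(tmin, tmax, first$geometry)
}

#' Construct a climate stack
#'
#' @param tmin,tmax `nrows x ncols x 12` arrays of monthly minimum and
#'   maximum temperature, degrees C.
#' @param geometry grid geometry (`xll`, `yll`, `cellsize`).
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(tmin, tmax, geometry = list()) {
  stopifnot(length(dim(tmin)) == 3L, dim(tmin)[3] == 12L,
            all(dim(tmin) == dim(tmax)))
  bad <- !is.na(tmin) & !is.na(tmax) & tmin > tmax
  if (any(bad)) stop("tmin exceeds tmax in ", sum(bad), " cells")
  geometry$nrows <- dim(tmin)[1]
  geometry$ncols <- dim(tmin)[2]
  if (is.null(geometry$xll)) geometry$xll <- 0
  if (is.null(geometry$yll)) geometry$yll <- 0
  if (is.null(geometry$cellsize)) geometry$cellsize <- 1
  structure(list(tmin = tmin, tmax = tmax, geometry = geometry),
            class = "climate_stack")
}

#' Write a climate stack as 24 ASCII grids
#'
#' @param stack a `climate_stack`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_climate_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "climate_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in 1:12) {
    write_ascii_grid(stack$tmin[, , m],
                     file.path(dir, sprintf("tmin_%02d.asc", m)),
                     stack$geometry)
    write_ascii_grid(stack$tmax[, , m],
                     file.path(dir, sprintf("tmax_%02d.asc", m)),
                     stack$geometry)
  }
  invisible(dir)
}
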