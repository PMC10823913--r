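#' Read an ESRI ASCII grid
#'
#' Parses the 6-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) and the whitespace-separated matrix
#' body. Rows run north to south, as in the format.
#'
#' @param path Path to a `.asc` file.
#' @param require_cellsize Optional cell size (m) that the file must declare
#'   (use 25 for cell-ID rasters); mismatch is an error.
#' @return List of class `asc_grid`: `data` (matrix, `NA` for NODATA),
#'   `xllcorner`, `yllcorner`, `cellsize`, `nodata`.
#' @export
read_asc <- function(path, require_cellsize = NULL) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  body_start <- 1L
  for (i in seq_len(min(6L, length(lines)))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      body_start <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("malformed .asc header, missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(require_cellsize) && hdr$cellsize != require_cellsize) {
    stop("expected cellsize ", require_cellsize, " m but file declares ",
         hdr$cellsize, call. = FALSE)
  }
  vals <- scan(text = lines[body_start:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  structure(list(data = m, xllcorner = hdr$xllcorner,
                 yllcorner = hdr$yllcorner, cellsize = hdr$cellsize,
                 nodata = if (is.null(hdr$nodata_value)) -9999
                          else hdr$nodata_value),
            class = "asc_grid")
}

#' Write an ESRI ASCII grid
#'
#' @param grid An `asc_grid` (see [read_asc()]) or a plain matrix.
#' @param path Output path.
#' @param xllcorner,yllcorner,cellsize,nodata Header values used when `grid`
#'   is a plain matrix.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, xllcorner = 0, yllcorner = 0,
                      cellsize = 25, nodata = -9999) {
  if (inherits(grid, "asc_grid")) {
    m <- grid$data; xllcorner <- grid$xllcorner; yllcorner <- grid$yllcorner
    cellsize <- grid$cellsize; nodata <- grid$nodata
  } else {
    m <- grid
  }
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Cell-ID raster of a landscape
#'
#' Assigns `cellID25` values in row-major order from the north-west corner,
#' the convention used throughout the package.
#'
#' @param nrows,ncols Landscape size in cells.
#' @return Integer matrix of cell IDs.
#' @export
cellid_raster <- function(nrows, ncols) {
  matrix(seq_len(nrows * ncols), nrows, ncols, byrow = TRUE)
}

#' Write a generated tree table
#'
#' Writes the published dataset schema: CSV with columns `cellID25`, `sp`,
#' `n`, `dbh`, `h`. Rows identical in (`cellID25`, `sp`, `dbh`, `h`) are
#' merged with summed counts; rows are ordered by (`cellID25`, `sp`, `dbh`)
#' so output is deterministic. Every `n` must be an integer >= 1.
#'
#' @param trees Data frame with those five columns.
#' @param path Output path.
#' @return The merged, ordered data frame, invisibly.
#' @export
write_tree_table <- function(trees, path) {
  need <- c("cellID25", "sp", "n", "dbh", "h")
  miss <- setdiff(need, names(trees))
  if (length(miss)) stop("tree table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(trees) && (any(trees$n < 1) || any(trees$n != round(trees$n)))) {
    stop("internal error: tree counts must be integers >= 1", call. = FALSE)
  }
  if (nrow(trees)) {
    key <- paste(trees$cellID25, trees$sp, trees$dbh, trees$h, sep = "\r")
    n <- tapply(trees$n, key, sum)
    first <- !duplicated(key)
    out <- trees[first, need, drop = FALSE]
    out$n <- as.integer(n[paste(out$cellID25, out$sp, out$dbh, out$h,
                                sep = "\r")])
    out <- out[order(out$cellID25, out$sp, out$dbh), , drop = FALSE]
  } else {
    out <- trees[, need, drop = FALSE]
  }
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read a generated tree table
#'
#' @param path CSV path in the [write_tree_table()] schema.
#' @return Data frame `cellID25`, `sp`, `n`, `dbh`, `h`.
#' @export
read_tree_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cellID25", "sp", "n", "dbh", "h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tree table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Serialize fitted ALS models to JSON
#'
#' Writes a human-readable description of a stratified model set (form,
#' selected metrics, coefficients, Box-Cox lambda, residual variance)
#' sufficient to reproduce its predictions after reading back, up to the
#' decimal round-trip of the coefficients (relative error below 1e-12).
#'
#' @param set A `stratified_models` object.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(set, path) {
  ser1 <- function(m) {
    if (is.null(m)) return(NULL)
    list(form = m$form, metrics = as.list(m$metrics),
         coef = as.list(m$coef), lambda = m$lambda, v = m$v,
         n_obs = m$n_obs, adj_r2 = m$adj_r2, search = m$search)
  }
  obj <- list(variable = set$variable,
              models = lapply(set$models, ser1),
              pooled = ser1(set$pooled),
              pooled_strata = as.list(set$pooled_strata),
              fallback = ser1(set$fallback),
              min_plots = set$min_plots,
              settings = set$settings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a serialized stratified model set
#'
#' @param path `.json` path written by [write_model_set()].
#' @return A `stratified_models` object.
#' @export
read_model_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de1 <- function(m) {
    if (is.null(m)) return(NULL)
    structure(list(
      form = m$form,
      metrics = as.character(unlist(m$metrics)),
      coef = stats::setNames(as.numeric(unlist(m$coef)),
                             names(unlist(m$coef))),
      lambda = if (is.null(m$lambda)) NA_real_ else as.numeric(m$lambda),
      v = if (is.null(m$v)) NA_real_ else as.numeric(m$v),
      n_obs = m$n_obs, adj_r2 = if (is.null(m$adj_r2)) NA_real_
                                else as.numeric(m$adj_r2),
      search = m$search
    ), class = "als_model")
  }
  structure(list(
    variable = obj$variable,
    models = lapply(obj$models, de1),
    pooled = de1(obj$pooled),
    pooled_strata = as.character(unlist(obj$pooled_strata)),
    fallback = de1(obj$fallback),
    min_plots = obj$min_plots,
    settings = lapply(obj$settings, function(x)
      if (is.list(x)) unlist(x) else x)
  ), class = "stratified_models")
}
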