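# Text serialisation of the package's gridded containers. Rasters and daily
# cubes travel as long-form CSV with a '#' comment header carrying the grid,
# units and kind, so a file is self-describing and round-trips at full
# double precision.

grid_header <- function(grid) {
  sprintf("# grid: %.17g %.17g %.17g %.17g %d %d",
          grid$origin_lon, grid$origin_lat,
          grid$cell_size_lon, grid$cell_size_lat,
          grid$n_cols, grid$n_rows)
}

parse_grid_header <- function(lines) {
  gl <- grep("^# grid: ", lines, value = TRUE)
  if (length(gl) != 1) stop("file lacks a single '# grid:' header")
  p <- as.numeric(strsplit(sub("^# grid: ", "", gl), " ")[[1]])
  grid_spec(p[1], p[2], p[3], p[4], p[5], p[6])
}

header_value <- function(lines, key) {
  gl <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
  if (length(gl) == 0) return(NULL)
  sub(paste0("^# ", key, ": "), "", gl[1])
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read and write raster fields as self-describing CSV
#'
#' Long-form CSV (`col,row,value`, 0-based indices) with a comment header
#' carrying the grid definition, units and kind. Missing cells are omitted
#' on write and missing after read; numeric values round-trip exactly.
#'
#' @param field A [raster_field()].
#' @param path File path.
#' @return `read_raster_csv()` returns a [raster_field()];
#'   `write_raster_csv()` returns `path` invisibly.
#' @export
write_raster_csv <- function(field, path) {
  stopifnot(is_raster_field(field))
  df <- tidy.raster_field(field) |> dplyr::filter(!is.na(.data$value))
  val <- if (field$kind == "categorical") df$value else fmt_num(df$value)
  hdr <- c("# ozoneyield raster v1",
           grid_header(field$grid),
           sprintf("# units: %s", field$units),
           sprintf("# kind: %s", field$kind))
  if (field$kind == "categorical") {
    hdr <- c(hdr, sprintf("# levels: %s", paste(field$levels, collapse = "|")))
  }
  writeLines(c(hdr, "col,row,value",
               sprintf("%d,%d,%s", df$col, df$row, val)), path)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  lines <- readLines(path)
  grid <- parse_grid_header(lines)
  kind <- header_value(lines, "kind") %||% "continuous"
  units <- header_value(lines, "units") %||% ""
  levels <- header_value(lines, "levels")
  if (!is.null(levels)) levels <- strsplit(levels, "|", fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = body, colClasses = c(
    col = "integer", row = "integer",
    value = if (kind == "categorical") "character" else "numeric"
  ))
  raster_from_table(grid, df, units = units, kind = kind, levels = levels)
}

#' Read and write daily dose cubes as self-describing CSV
#'
#' Long-form CSV (`date,col,row,value`) with the same comment-header scheme
#' as [write_raster_csv()]. Only daily-mode cubes are persisted; hourly
#' cubes are an in-memory convenience.
#'
#' @param cube A daily-mode [flux_cube()].
#' @param path File path.
#' @return `read_cube_csv()` returns a [flux_cube()].
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(is_flux_cube(cube))
  if (cube$mode != "daily") stop("only daily-mode cubes are serialised")
  df <- tidy.flux_cube(cube) |> dplyr::filter(!is.na(.data$value))
  writeLines(c("# ozoneyield cube v1",
               grid_header(cube$grid),
               "# mode: daily",
               "date,col,row,value",
               sprintf("%s,%d,%d,%s", format(df$date), df$col, df$row,
                       fmt_num(df$value))), path)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  lines <- readLines(path)
  grid <- parse_grid_header(lines)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = body, colClasses = c(
    date = "Date", col = "integer", row = "integer", value = "numeric"
  ))
  dates <- sort(unique(df$date))
  vals <- array(NA_real_, c(length(dates), grid$n_rows, grid$n_cols))
  ti <- match(df$date, dates)
  vals[cbind(ti, df$row + 1L, df$col + 1L)] <- df$value
  flux_cube(grid, dates, vals, mode = "daily")
}

#' Write a tibble as CSV with a provenance comment header
#'
#' @param tbl Data frame.
#' @param path File path.
#' @param comments Character vector of header lines (written as `# ...`).
#' @return `path`, invisibly. `read_table_csv()` returns a tibble.
#' @export
write_table_csv <- function(tbl, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste("#", comments), con)
  utils::write.csv(tbl, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
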