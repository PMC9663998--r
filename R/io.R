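#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack Integer array `width x height x n` of counts (0..65535),
#'   as produced by [render_frames()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  n <- dim(stack)[3]
  imgs <- lapply(seq_len(n), function(i) t(stack[, , i]) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file.
#' @return Integer array `width x height x n` of counts (0..65535).
#' @export
read_tiff_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  W <- ncol(imgs[[1]]); H <- nrow(imgs[[1]])
  out <- array(0L, dim = c(W, H, length(imgs)))
  for (i in seq_along(imgs))
    out[, , i] <- as.integer(round(t(imgs[[i]]) * 65535))
  out
}

#' Write / read a track as CSV
#'
#' The CSV schema is `frame,t,x_mm,y_mm,length_mm,valid` plus any extra
#' columns present; `fps` is stored in a header comment.
#'
#' @param track Track tibble with attribute `fps`.
#' @param path CSV file.
#' @return `path` (write) or the track tibble (read).
#' @export
write_track_csv <- function(track, path) {
  fps <- attr(track, "fps")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%s", format(fps, digits = 15)), con)
  df <- as.data.frame(track)
  names(df)[names(df) == "x"] <- "x_mm"
  names(df)[names(df) == "y"] <- "y_mm"
  names(df)[names(df) == "length"] <- "length_mm"
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  first <- readLines(path, n = 1)
  fps <- NULL
  skip <- 0
  if (grepl("^# fps=", first)) {
    fps <- as.numeric(sub("^# fps=", "", first))
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip)
  names(df)[names(df) == "x_mm"] <- "x"
  names(df)[names(df) == "y_mm"] <- "y"
  names(df)[names(df) == "length_mm"] <- "length"
  out <- tibble::as_tibble(df)
  attr(out, "fps") <- fps
  out
}

#' Write a run report as JSON
#'
#' @param report Named list (nested lists / tibbles allowed).
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
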