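#' Write a track table to CSV
#'
#' Long-format CSV with header `t,id,x,y` plus any extra columns
#' (`heading`, `omega`, ...). Numeric values are written with 17
#' significant digits so a write/read round trip reproduces the doubles
#' exactly.
#'
#' @param tracks a track table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(c("t", "id", "x", "y") %in% names(tracks)))
  first <- c("t", "id", "x", "y")
  tracks <- tracks[, c(first, setdiff(names(tracks), first))]
  cols <- lapply(tracks, function(col) {
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col
  })
  lines <- c(paste(names(tracks), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a track table from CSV
#'
#' Reads the `t,id,x,y[,...]` dialect, canonically sorts by (id, t),
#' validates that each fish sits on a uniform frame grid, and reports
#' malformed rows with their line numbers. Missing frames are allowed
#' (the series is segmented downstream) and logged; frame times off the
#' common grid are an error.
#'
#' @param path CSV file path.
#' @param fps expected frame rate; inferred from the time grid when
#'   `NULL`.
#' @return a track table `data.frame` with attribute `fps`.
#' @export
read_tracks <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("t", "id", "x", "y")
  if (!all(need %in% names(raw)))
    stop("track file must have columns t,id,x,y (found: ",
         paste(names(raw), collapse = ","), ")")
  extra <- setdiff(names(raw), c(need, "heading", "omega"))
  if (length(extra))
    warning("unknown columns preserved: ", paste(extra, collapse = ", "))
  for (col in names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop("malformed values in column '", col, "' at file line(s) ",
           paste(utils::head(bad + 1, 5), collapse = ", "))
    raw[[col]] <- v
  }
  raw <- raw[order(raw$id, raw$t), ]
  rownames(raw) <- NULL
  if (is.null(fps)) {
    dts <- diff(sort(unique(raw$t)))
    dts <- dts[dts > 0]
    fps <- 1 / stats::median(dts)
  }
  n_gaps <- 0
  for (fid in unique(raw$id)) {
    tt <- raw$t[raw$id == fid]
    fr <- tt * fps
    off <- abs(fr - round(fr))
    if (any(off > 1e-6))
      stop("fish ", fid, ": frame times off the 1/", round(fps),
           " s grid at t = ",
           paste(utils::head(tt[off > 1e-6], 5), collapse = ", "))
    if (anyDuplicated(round(fr)))
      stop("fish ", fid, ": duplicated frames")
    n_gaps <- n_gaps + sum(diff(round(fr)) != 1)
  }
  if (n_gaps > 0)
    message(n_gaps, " frame gap(s) in ", basename(path),
            "; series will be segmented")
  attr(raw, "fps") <- fps
  raw
}
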