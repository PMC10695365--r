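#' @include AllClasses.R
NULL

#' Construct a TrajectorySet
#'
#' @param x,y numeric frames x animals matrices of coordinates in cm
#' @param time_s numeric vector of frame timestamps in seconds, strictly
#'   increasing
#' @param valid logical frames x animals matrix; defaults to non-NA positions
#' @param animal_ids character labels for the animals; defaults to the column
#'   names of \code{x}
#' @param arena numeric (width, height) of the arena in cm
#' @param frame_rate sampling rate in Hz
#' @param day integer day index of the session
#' @param familiar optional named character vector mapping each animal id to
#'   its familiar partner's id
#' @return a \linkS4class{TrajectorySet}
#' @export
TrajectorySet <- function(x, y, time_s, valid = NULL, animal_ids = colnames(x),
                          arena, frame_rate, day = 1L, familiar = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(ncol(x)))
  if (is.null(valid)) valid <- !is.na(x) & !is.na(y)
  valid <- as.matrix(valid)
  storage.mode(valid) <- "logical"
  dimnames(x) <- dimnames(y) <- dimnames(valid) <-
    list(NULL, animal_ids)
  cd <- DataFrame(animal_id = animal_ids, row.names = animal_ids)
  cd$familiar_partner <- if (is.null(familiar)) NA_character_ else
    unname(familiar[animal_ids])
  se <- SummarizedExperiment(
    assays = list(x = x, y = y, valid = valid),
    rowData = DataFrame(time_s = as.numeric(time_s)),
    colData = cd)
  metadata(se) <- list(arena = as.numeric(arena),
                       frame_rate = as.numeric(frame_rate),
                       day = as.integer(day))
  methods::new("TrajectorySet", se)
}

#' @describeIn TrajectorySet x coordinates (frames x animals, cm)
#' @param ts a TrajectorySet
#' @export
coordsX <- function(ts) assay(ts, "x")

#' @describeIn TrajectorySet y coordinates (frames x animals, cm)
#' @export
coordsY <- function(ts) assay(ts, "y")

#' @describeIn TrajectorySet validity mask (frames x animals, logical)
#' @export
validMask <- function(ts) assay(ts, "valid")

#' @describeIn TrajectorySet frame timestamps in seconds
#' @export
frameTimes <- function(ts) rowData(ts)$time_s

#' @describeIn TrajectorySet animal identifiers
#' @export
animalIds <- function(ts) colData(ts)$animal_id

#' @describeIn TrajectorySet arena (width, height) in cm
#' @export
arenaDims <- function(ts) metadata(ts)$arena

#' @describeIn TrajectorySet sampling rate in Hz
#' @export
frameRate <- function(ts) metadata(ts)$frame_rate

#' @describeIn TrajectorySet number of frames
#' @export
nFrames <- function(ts) nrow(ts)

#' @describeIn TrajectorySet number of animals
#' @export
nAnimals <- function(ts) ncol(ts)

setMethod("show", "TrajectorySet", function(object) {
  md <- metadata(object)
  cat(sprintf(
    "TrajectorySet: %d frames x %d animals (day %d)\n",
    nrow(object), ncol(object), md$day))
  cat(sprintf("  arena %.0f x %.0f cm, %.3g Hz, %.0f s\n",
              md$arena[1], md$arena[2], md$frame_rate,
              if (nrow(object) > 1)
                rowData(object)$time_s[nrow(object)] else 0))
  cat(sprintf("  animals: %s\n", paste(animalIds(object), collapse = ", ")))
  cat(sprintf("  valid animal-frames: %.1f%%\n",
              100 * mean(assay(object, "valid"))))
})

#' Flatten a TrajectorySet to a long table
#'
#' One row per animal-frame with columns \code{frame}, \code{time_s},
#' \code{animal_id}, \code{x_cm}, \code{y_cm}, \code{valid}.
#'
#' @param ts a \linkS4class{TrajectorySet}
#' @return a data.frame
#' @export
asLongTable <- function(ts) {
  ids <- animalIds(ts)
  nf <- nrow(ts)
  x <- coordsX(ts); y <- coordsY(ts); v <- validMask(ts)
  data.frame(
    frame = rep(seq_len(nf), times = length(ids)),
    time_s = rep(frameTimes(ts), times = length(ids)),
    animal_id = rep(ids, each = nf),
    x_cm = as.vector(x), y_cm = as.vector(y),
    valid = as.vector(v), stringsAsFactors = FALSE)
}

#' Rebuild a TrajectorySet from a long table
#'
#' Inverse of [asLongTable()].
#'
#' @param df a data.frame in the long layout written by [asLongTable()]
#' @param arena numeric (width, height) in cm
#' @param frame_rate sampling rate in Hz
#' @param day day index
#' @return a \linkS4class{TrajectorySet}
#' @export
fromLongTable <- function(df, arena, frame_rate, day = 1L) {
  ids <- unique(df$animal_id)
  frames <- sort(unique(df$frame))
  nf <- length(frames)
  x <- y <- matrix(NA_real_, nf, length(ids), dimnames = list(NULL, ids))
  v <- matrix(FALSE, nf, length(ids), dimnames = list(NULL, ids))
  tt <- numeric(nf)
  fidx <- match(df$frame, frames)
  aidx <- match(df$animal_id, ids)
  x[cbind(fidx, aidx)] <- df$x_cm
  y[cbind(fidx, aidx)] <- df$y_cm
  v[cbind(fidx, aidx)] <- df$valid
  tt[fidx] <- df$time_s
  TrajectorySet(x, y, tt, valid = v, animal_ids = ids, arena = arena,
                frame_rate = frame_rate, day = day)
}

#' Write / read trajectory CSV files
#'
#' `writeLongCSV()` and `readLongCSV()` use the plain long layout of
#' [asLongTable()]. `writeDLC()` and `readDLC()` use the three-header-row
#' dialect of pose-tracking output tables (scorer / bodyparts / coords), with
#' one "bodypart" per animal and a likelihood column encoding validity.
#'
#' @param ts a \linkS4class{TrajectorySet}
#' @param path file path
#' @param scorer scorer label written into the DLC header
#' @return `readLongCSV()` and `readDLC()` return a TrajectorySet; the writers
#'   return `path` invisibly.
#' @name trajectory-io
NULL

#' @rdname trajectory-io
#' @export
writeLongCSV <- function(ts, path) {
  data.table::fwrite(asLongTable(ts), path)
  invisible(path)
}

#' @rdname trajectory-io
#' @param arena,frame_rate,day session metadata (not stored in the long CSV)
#' @export
readLongCSV <- function(path, arena, frame_rate, day = 1L) {
  df <- as.data.frame(data.table::fread(path))
  df$valid <- as.logical(df$valid)
  fromLongTable(df, arena = arena, frame_rate = frame_rate, day = day)
}

#' @rdname trajectory-io
#' @export
writeDLC <- function(ts, path, scorer = "grouptrax") {
  ids <- animalIds(ts)
  x <- coordsX(ts); y <- coordsY(ts); v <- validMask(ts)
  cols <- c("coords", rep(ids, each = 3))
  h1 <- c("scorer", rep(scorer, 3 * length(ids)))
  h2 <- cols
  h2[1] <- "bodyparts"
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(ids)))
  body <- matrix(NA_real_, nrow(ts), 3 * length(ids))
  for (j in seq_along(ids)) {
    body[, 3 * j - 2] <- x[, j]
    body[, 3 * j - 1] <- y[, j]
    body[, 3 * j] <- as.numeric(v[, j])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(h1, collapse = ","), con)
  writeLines(paste(h2, collapse = ","), con)
  writeLines(paste(h3, collapse = ","), con)
  lines <- apply(cbind(seq_len(nrow(ts)) - 1L, body), 1L, function(r)
    paste(ifelse(is.na(r), "", format(r, trim = TRUE, scientific = FALSE)),
          collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname trajectory-io
#' @export
readDLC <- function(path, arena, frame_rate, day = 1L) {
  h <- readLines(path, n = 3L)
  h2 <- strsplit(h[2], ",", fixed = TRUE)[[1]]
  h3 <- strsplit(h[3], ",", fixed = TRUE)[[1]]
  body <- as.matrix(data.table::fread(path, skip = 3L, header = FALSE))
  ids <- unique(h2[-1])
  nf <- nrow(body)
  x <- y <- matrix(NA_real_, nf, length(ids), dimnames = list(NULL, ids))
  v <- matrix(FALSE, nf, length(ids), dimnames = list(NULL, ids))
  for (k in seq_along(h2)[-1]) {
    j <- match(h2[k], ids)
    col <- suppressWarnings(as.numeric(body[, k]))
    if (h3[k] == "x") x[, j] <- col
    if (h3[k] == "y") y[, j] <- col
    if (h3[k] == "likelihood") v[, j] <- !is.na(col) & col >= 0.5
  }
  tt <- (seq_len(nf) - 1) / frame_rate
  TrajectorySet(x, y, tt, valid = v & !is.na(x) & !is.na(y), animal_ids = ids,
                arena = arena, frame_rate = frame_rate, day = day)
}
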