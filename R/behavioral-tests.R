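#' @include track-repair.R
NULL

#' Rectangular zones and standard apparatus zone maps
#'
#' `zoneRect()` builds an axis-aligned rectangular zone (boundaries
#' inclusive). `zoneUnion()` combines zones. `openFieldZones()` tiles an
#' 80 x 80 cm arena into a 5 x 5 grid of 16 cm blocks with the central nine
#' blocks as the center zone and the central single block as the object zone.
#' `threeChamberZones()` splits the same arena into three equal-width
#' compartments. `epmZones()` lays out an elevated plus maze (two open and
#' two closed 50 x 10 cm arms around a 10 x 10 cm hub, centered at the
#' origin).
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds in cm
#' @return a zone object (list), or a named list of zones for the apparatus
#'   helpers
#' @name zones
NULL

#' @rdname zones
#' @export
zoneRect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(rects = list(c(xmin = xmin, xmax = xmax,
                                ymin = ymin, ymax = ymax))),
            class = "gtZone")
}

#' @rdname zones
#' @param ... zones to combine
#' @export
zoneUnion <- function(...) {
  zs <- list(...)
  structure(list(rects = do.call(c, lapply(zs, `[[`, "rects"))),
            class = "gtZone")
}

#' @rdname zones
#' @param side arena side length in cm
#' @export
openFieldZones <- function(side = 80) {
  b <- side / 5  # 16 cm blocks for the standard 80 cm arena
  list(center = zoneRect(b, 4 * b, b, 4 * b),
       object = zoneRect(2 * b, 3 * b, 2 * b, 3 * b),
       block_cm = b)
}

#' @rdname zones
#' @export
threeChamberZones <- function(side = 80) {
  w <- side / 3
  list(left = zoneRect(0, w, 0, side),
       center = zoneRect(w, 2 * w, 0, side),
       right = zoneRect(2 * w, side, 0, side))
}

#' @rdname zones
#' @param armLength,armWidth,hub elevated-plus-maze arm and hub dimensions, cm
#' @export
epmZones <- function(armLength = 50, armWidth = 10, hub = 10) {
  h <- hub / 2; w <- armWidth / 2
  open <- zoneUnion(zoneRect(-w, w, h, h + armLength),
                    zoneRect(-w, w, -h - armLength, -h))
  closed <- zoneUnion(zoneRect(h, h + armLength, -w, w),
                      zoneRect(-h - armLength, -h, -w, w))
  list(open = open, closed = closed, hub = zoneRect(-h, h, -h, h))
}

#' Test points against a zone
#'
#' @param x,y coordinates in cm
#' @param zone a zone from [zoneRect()] or the apparatus helpers
#' @return logical vector, TRUE where the point lies inside (boundaries
#'   inclusive)
#' @export
pointInZone <- function(x, y, zone) {
  stopifnot(inherits(zone, "gtZone"))
  inside <- rep(FALSE, length(x))
  for (r in zone$rects)
    inside <- inside | (x >= r["xmin"] & x <= r["xmax"] &
                          y >= r["ymin"] & y <= r["ymax"])
  inside & !is.na(x) & !is.na(y)
}

#' Total path length of a track
#'
#' Sum of Euclidean distances between consecutive valid positions.
#'
#' @param x,y coordinates in cm
#' @param valid validity mask; defaults to non-NA positions
#' @return distance in cm
#' @export
pathLength <- function(x, y, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(x) & !is.na(y)
  xv <- x[valid]; yv <- y[valid]
  if (length(xv) < 2L) stop("path length needs at least 2 valid frames")
  sum(sqrt(diff(xv)^2 + diff(yv)^2))
}

#' Count entries into a zone
#'
#' An entry is a transition from outside the zone to inside it between
#' consecutive valid frames; starting inside the zone does not count until
#' the animal exits and re-enters.
#'
#' @param x,y coordinates in cm
#' @param zone a zone object
#' @param valid validity mask
#' @return integer count
#' @export
zoneEntries <- function(x, y, zone, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(x) & !is.na(y)
  inz <- pointInZone(x[valid], y[valid], zone)
  if (length(inz) < 2L) return(0L)
  sum(inz[-1] & !inz[-length(inz)])
}

#' Normalize a value by recording duration
#'
#' Divides a session total (distance, entry count) by the recording duration,
#' for tests whose recording length varied between subjects.
#'
#' @param value session total
#' @param duration_s recording duration in seconds (> 0)
#' @return value per second
#' @export
perTimeNormalize <- function(value, duration_s) {
  if (any(duration_s <= 0)) stop("duration must be positive")
  value / duration_s
}

#' Habituation-corrected test value
#'
#' Test-phase value minus habituation-phase value, controlling for baseline
#' individual activity.
#'
#' @param test_value,habituation_value same index measured in the two phases
#' @return difference
#' @export
habituationDelta <- function(test_value, habituation_value) {
  if (any(is.na(test_value)) || any(is.na(habituation_value)))
    stop("both phases must be measured")
  test_value - habituation_value
}

#' Chamber preference ratio
#'
#' Entries into the animal compartment divided by total entries into both
#' stimulus compartments.
#'
#' @param entries_animal,entries_toy entry counts
#' @return fraction in \[0, 1\]; NA (with a warning) when no entries occurred
#' @export
chamberPreference <- function(entries_animal, entries_toy) {
  tot <- entries_animal + entries_toy
  if (any(tot == 0)) {
    warning("zero total compartment entries; preference undefined")
    return(ifelse(tot == 0, NA_real_, entries_animal / tot))
  }
  entries_animal / tot
}

#' Total durations per label of a glove-test event log
#'
#' Overlapping intervals with the same label are merged before summation, so
#' double-coded overlaps are not counted twice.
#'
#' @param event_log data.frame with columns \code{label}, \code{start_s},
#'   \code{end_s} (end strictly after start)
#' @param labels labels to report (zeros when absent)
#' @return named numeric of total durations in seconds
#' @export
gloveDurations <- function(event_log,
                           labels = c("approach", "avoid", "handling")) {
  out <- setNames(numeric(length(labels)), labels)
  if (nrow(event_log) == 0L) return(out)
  if (any(event_log$end_s <= event_log$start_s))
    stop("event intervals must have positive length")
  for (lb in unique(event_log$label)) {
    iv <- event_log[event_log$label == lb, , drop = FALSE]
    iv <- iv[order(iv$start_s), , drop = FALSE]
    tot <- 0; cs <- iv$start_s[1]; ce <- iv$end_s[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start_s[i] <= ce) ce <- max(ce, iv$end_s[i])
      else { tot <- tot + (ce - cs); cs <- iv$start_s[i]; ce <- iv$end_s[i] }
    }
    tot <- tot + (ce - cs)
    if (lb %in% labels) out[lb] <- tot
  }
  out
}

#' Assemble the 13-item battery table from per-trial data
#'
#' Computes the battery columns of [batteryItems()] for each subject from raw
#' trial material: open-field and elevated-plus-maze tracks, novel-object and
#' three-chamber habituation/test phase tracks, and a glove-test event log.
#' Open-field and three-chamber distance and entry counts are divided by the
#' recording duration; novel-object and three-chamber indices are
#' habituation-corrected differences; three-chamber entries enter as the
#' habituation-corrected preference ratio for the animal compartment. The
#' tracked point stands in for the head in the object-zone entry count.
#'
#' @param trials named list (one element per subject). Each subject is a list
#'   with elements \code{of}, \code{no_hab}, \code{no_test}, \code{tc_hab},
#'   \code{tc_test}, \code{epm} — each a list(track = data.frame(x, y),
#'   duration_s = seconds) — plus \code{glove} (event-log data.frame) and
#'   \code{tc_animal_side} ("left" or "right").
#' @return data.frame, one row per subject, columns [batteryItems()]
#' @export
scoreTestBattery <- function(trials) {
  ofz <- openFieldZones()
  tcz <- threeChamberZones()
  epz <- epmZones()
  rows <- lapply(names(trials), function(id) {
    tr <- trials[[id]]
    g <- gloveDurations(tr$glove)
    no_entry <- habituationDelta(
      zoneEntries(tr$no_test$track$x, tr$no_test$track$y, ofz$center),
      zoneEntries(tr$no_hab$track$x, tr$no_hab$track$y, ofz$center))
    no_dist <- habituationDelta(
      pathLength(tr$no_test$track$x, tr$no_test$track$y),
      pathLength(tr$no_hab$track$x, tr$no_hab$track$y))
    no_head <- habituationDelta(
      zoneEntries(tr$no_test$track$x, tr$no_test$track$y, ofz$object),
      zoneEntries(tr$no_hab$track$x, tr$no_hab$track$y, ofz$object))
    side <- match.arg(tr$tc_animal_side, c("left", "right"))
    a_zone <- tcz[[side]]
    t_zone <- tcz[[setdiff(c("left", "right"), side)]]
    tc_pref <- habituationDelta(
      chamberPreference(
        zoneEntries(tr$tc_test$track$x, tr$tc_test$track$y, a_zone),
        zoneEntries(tr$tc_test$track$x, tr$tc_test$track$y, t_zone)),
      chamberPreference(
        zoneEntries(tr$tc_hab$track$x, tr$tc_hab$track$y, a_zone),
        zoneEntries(tr$tc_hab$track$x, tr$tc_hab$track$y, t_zone)))
    tc_dist <- habituationDelta(
      perTimeNormalize(pathLength(tr$tc_test$track$x, tr$tc_test$track$y),
                       tr$tc_test$duration_s),
      perTimeNormalize(pathLength(tr$tc_hab$track$x, tr$tc_hab$track$y),
                       tr$tc_hab$duration_s))
    vals <- c(
      no_entry, no_dist, no_head,
      zoneEntries(tr$epm$track$x, tr$epm$track$y, epz$open),
      zoneEntries(tr$epm$track$x, tr$epm$track$y, epz$closed),
      pathLength(tr$epm$track$x, tr$epm$track$y),
      perTimeNormalize(pathLength(tr$of$track$x, tr$of$track$y),
                       tr$of$duration_s),
      perTimeNormalize(zoneEntries(tr$of$track$x, tr$of$track$y, ofz$center),
                       tr$of$duration_s),
      g["handling"], g["avoid"], g["approach"],
      tc_dist, tc_pref)
    setNames(vals, batteryItems())
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- names(trials)
  out
}
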