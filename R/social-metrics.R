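#' @include behavioral-tests.R
NULL

# Absorb runs shorter than minFrames into the surrounding state, working on
# the run-length encoding. Flipping the shortest offending run first merges
# it with both neighbours, so the procedure terminates.
debounceRuns <- function(z, minFrames) {
  if (minFrames <= 1 || length(z) < 2L) return(z)
  r <- rle(z)
  len <- r$lengths; val <- r$values
  while (length(len) > 1L) {
    short <- which(len < minFrames)
    if (!length(short)) break
    i <- short[which.min(len[short])]
    lo <- max(1L, i - 1L); hi <- min(length(len), i + 1L)
    newlen <- sum(len[lo:hi])
    newval <- if (i > 1L) val[i - 1L] else val[i + 1L]
    keep_pre <- seq_len(lo - 1L)
    keep_post <- if (hi < length(len)) (hi + 1L):length(len) else integer(0)
    len <- c(len[keep_pre], newlen, len[keep_post])
    val <- c(val[keep_pre], newval, val[keep_post])
  }
  inverse.rle(list(lengths = len, values = val))
}

#' Dyadic proximity series with bout debouncing
#'
#' A dyad is in proximity when the inter-individual distance is at or below
#' \code{thresholdCm}. Proximity and non-proximity bouts shorter than
#' \code{minBoutS} are absorbed into the surrounding state. Frames where
#' either animal is invalid are NA and excluded from both numerator and
#' denominator of any time computed from the series; dyad-days with less than
#' half their frames valid are flagged unusable.
#'
#' @param ts a \linkS4class{TrajectorySet}
#' @param thresholdCm proximity threshold in cm (default about one adult
#'   body length without the tail)
#' @param minBoutS debounce bout length in seconds
#' @return a \linkS4class{ProximitySeries}
#' @export
proximitySeries <- function(ts, thresholdCm = 20, minBoutS = 2) {
  stopifnot(thresholdCm > 0, minBoutS >= 0)
  ids <- animalIds(ts)
  dy <- combn(ids, 2)
  x <- coordsX(ts); y <- coordsY(ts); v <- validMask(ts)
  dt <- 1 / frameRate(ts)
  nf <- nrow(ts)
  minFrames <- minBoutS * frameRate(ts)
  ser <- matrix(NA, nf, ncol(dy))
  colnames(ser) <- paste(dy[1, ], dy[2, ], sep = "-")
  vf <- numeric(ncol(dy))
  for (k in seq_len(ncol(dy))) {
    a <- dy[1, k]; b <- dy[2, k]
    ok <- v[, a] & v[, b]
    d <- sqrt((x[, a] - x[, b])^2 + (y[, a] - y[, b])^2)
    s <- rep(NA, nf)
    s[ok] <- d[ok] <= thresholdCm
    if (any(ok)) s[ok] <- debounceRuns(s[ok], minFrames)
    ser[, k] <- s
    vf[k] <- mean(ok)
  }
  methods::new("ProximitySeries", series = ser, dyadA = dy[1, ],
               dyadB = dy[2, ], dt = dt,
               sessionDuration = nf * dt, validFraction = vf,
               usable = vf >= 0.5, thresholdCm = thresholdCm,
               minBoutS = minBoutS)
}

setMethod("show", "ProximitySeries", function(object) {
  cat(sprintf(
    "ProximitySeries: %d frames, %d dyads (threshold %.0f cm, debounce %.1f s)\n",
    nrow(object@series), ncol(object@series), object@thresholdCm,
    object@minBoutS))
  pt <- proximityTime(object)
  for (k in seq_along(pt))
    cat(sprintf("  %s: %.1f s%s\n", names(pt)[k], pt[k],
                if (object@usable[k]) "" else " [unusable]"))
})

#' Per-dyad proximity time, rescaled to the full session
#'
#' Proximity fraction over frames where both animals are valid, multiplied by
#' the nominal session duration. Unusable dyads (valid fraction below one
#' half) are NA.
#'
#' @param ps a \linkS4class{ProximitySeries}
#' @return named numeric, seconds per dyad
#' @export
proximityTime <- function(ps) {
  out <- colMeans(ps@series, na.rm = TRUE) * ps@sessionDuration
  out[!ps@usable] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

#' Detect approach and avoidance events with mover attribution
#'
#' Each proximity onset yields one approach and each offset one avoidance.
#' The mover is the dyad member with the greater path length over the
#' \code{windowS} seconds preceding an onset or following an offset; exact
#' ties keep the event but record the mover as NA (ambiguous), which excludes
#' it from per-subject counts.
#'
#' @param ps a debounced \linkS4class{ProximitySeries}
#' @param ts the \linkS4class{TrajectorySet} the series came from
#' @param windowS attribution window in seconds
#' @return data.frame: dyad_a, dyad_b, kind ("approach"/"avoidance"),
#'   time_s, frame, mover (NA when ambiguous)
#' @export
detectEvents <- function(ps, ts, windowS = 3) {
  x <- coordsX(ts); y <- coordsY(ts); v <- validMask(ts)
  tt <- frameTimes(ts)
  ev <- list()
  for (k in seq_len(ncol(ps@series))) {
    if (!ps@usable[k]) next
    s <- ps@series[, k]
    idx <- which(!is.na(s))
    if (length(idx) < 2L) next
    z <- s[idx]
    tr <- which(z[-1] != z[-length(z)]) + 1L
    for (i in tr) {
      f <- idx[i]
      kind <- if (z[i]) "approach" else "avoidance"
      if (kind == "approach")
        win <- which(tt > tt[f] - windowS & tt <= tt[f])
      else
        win <- which(tt >= tt[f] & tt < tt[f] + windowS)
      mover <- NA_character_
      a <- ps@dyadA[k]; b <- ps@dyadB[k]
      pl <- vapply(c(a, b), function(id) {
        ok <- v[win, id]
        if (sum(ok) < 2L) return(0)
        pathLength(x[win, id], y[win, id], valid = ok)
      }, 0)
      if (abs(pl[1] - pl[2]) > 1e-9) mover <- c(a, b)[which.max(pl)]
      ev[[length(ev) + 1L]] <- data.frame(
        dyad_a = a, dyad_b = b, kind = kind, time_s = tt[f], frame = f,
        mover = mover, stringsAsFactors = FALSE)
    }
  }
  if (!length(ev))
    return(data.frame(dyad_a = character(), dyad_b = character(),
                      kind = character(), time_s = numeric(),
                      frame = integer(), mover = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' Time a subject spends in proximity with no group member
#'
#' Computed over frames where all three of the subject's dyad series are
#' defined, rescaled to the nominal session duration. NA when any of the
#' subject's dyads is unusable.
#'
#' @param ps a \linkS4class{ProximitySeries}
#' @param subject animal id
#' @return seconds
#' @export
isolationTime <- function(ps, subject) {
  k <- which(ps@dyadA == subject | ps@dyadB == subject)
  if (!length(k)) stop("unknown subject: ", subject)
  if (any(!ps@usable[k])) return(NA_real_)
  sub <- ps@series[, k, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  if (!any(complete)) return(NA_real_)
  iso <- rowSums(sub[complete, , drop = FALSE]) == 0L
  mean(iso) * ps@sessionDuration
}

#' Per-subject social interaction indices for one session
#'
#' The nine indices: time in isolation; time in proximity with the familiar
#' partner and (mean over the two) unfamiliar partners; approach counts
#' (total, familiar, unfamiliar mean); avoidance counts (total, familiar,
#' unfamiliar mean). Totals satisfy
#' \code{total = familiar + 2 * unfamiliar_mean} exactly. Events with an
#' ambiguous mover are not attributed to any subject.
#'
#' @param ts a \linkS4class{TrajectorySet} whose colData carries
#'   \code{familiar_partner}
#' @param ps the matching \linkS4class{ProximitySeries}
#' @param events the matching event table from [detectEvents()]
#' @return data.frame, one row per subject
#' @export
socialIndices <- function(ts, ps, events) {
  ids <- animalIds(ts)
  fam <- setNames(colData(ts)$familiar_partner, ids)
  if (any(is.na(fam)))
    stop("familiar partner must be recorded for every subject")
  pt <- proximityTime(ps)
  day <- metadata(ts)$day
  rows <- lapply(ids, function(id) {
    partner_of <- function(k)
      ifelse(ps@dyadA[k] == id, ps@dyadB[k], ps@dyadA[k])
    k3 <- which(ps@dyadA == id | ps@dyadB == id)
    partners <- vapply(k3, partner_of, "")
    unf <- setdiff(partners, fam[id])
    prox_f <- pt[k3[partners == fam[id]]]
    prox_u <- mean(pt[k3[partners %in% unf]])
    cnt <- function(kind, ids_partner) {
      if (!nrow(events)) return(0L)
      sel <- events$kind == kind & !is.na(events$mover) &
        events$mover == id &
        (events$dyad_a == id | events$dyad_b == id)
      other <- ifelse(events$dyad_a == id, events$dyad_b, events$dyad_a)
      sum(sel & other %in% ids_partner)
    }
    app_f <- cnt("approach", fam[id])
    app_u <- cnt("approach", unf) / 2
    avd_f <- cnt("avoidance", fam[id])
    avd_u <- cnt("avoidance", unf) / 2
    data.frame(
      subject = id, day = day,
      isolation_s = isolationTime(ps, id),
      prox_familiar_s = unname(prox_f),
      prox_unfamiliar_s = prox_u,
      approaches_total = app_f + 2 * app_u,
      approaches_familiar = app_f,
      approaches_unfamiliar = app_u,
      avoidances_total = avd_f + 2 * avd_u,
      avoidances_familiar = avd_f,
      avoidances_unfamiliar = avd_u,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The nine social index column names
#' @return character(9)
#' @export
socialIndexNames <- function() c(
  "isolation_s", "prox_familiar_s", "prox_unfamiliar_s",
  "approaches_total", "approaches_familiar", "approaches_unfamiliar",
  "avoidances_total", "avoidances_familiar", "avoidances_unfamiliar")

#' Average daily social indices over a term
#'
#' Arithmetic mean of each index over the usable (non-excluded, non-missing)
#' days of a term, per subject. A subject-term with no usable day is dropped
#' with a warning.
#'
#' @param rows daily index rows from [socialIndices()], stacked over days
#' @param excludeDays integer days to exclude (e.g. days lost to camera
#'   malfunction)
#' @return data.frame of per-subject term means
#' @export
aggregateTerm <- function(rows, excludeDays = integer(0)) {
  keep <- !(rows$day %in% excludeDays)
  rows <- rows[keep, , drop = FALSE]
  if (!nrow(rows)) stop("no usable days in term")
  idx <- socialIndexNames()
  out <- lapply(split(rows, rows$subject), function(d) {
    ok <- stats::complete.cases(d[, idx])
    if (!any(ok)) return(NULL)
    cbind(data.frame(subject = d$subject[1], n_days = sum(ok),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(d[ok, idx, drop = FALSE]))))
  })
  miss <- names(out)[vapply(out, is.null, TRUE)]
  if (length(miss))
    warning("no usable days for subject(s): ", paste(miss, collapse = ", "))
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  names(out)[-(1:2)] <- idx
  out
}

#' Standardize term-mean indices by group average
#'
#' Divides each subject's index by the mean of that index over the subject's
#' group, so every group x index has mean 1 afterwards. A group x index with
#' zero mean cannot be standardized and is set NA with a warning.
#'
#' @param termMeans per-subject term means from [aggregateTerm()]
#' @param groups named character vector: group label per subject
#' @return data.frame like \code{termMeans} with standardized index columns
#'   and a \code{group} column
#' @export
standardizeByGroup <- function(termMeans, groups) {
  g <- groups[termMeans$subject]
  if (any(is.na(g))) stop("every subject needs a group label")
  if (any(table(g) < 2)) stop("each group needs at least 2 subjects")
  out <- termMeans
  out$group <- unname(g)
  for (col in socialIndexNames()) {
    for (gr in unique(g)) {
      sel <- out$group == gr
      m <- mean(out[[col]][sel])
      if (is.na(m) || m == 0) {
        warning("group ", gr, " has zero/undefined mean for ", col,
                "; not standardizable")
        out[[col]][sel] <- NA_real_
      } else out[[col]][sel] <- out[[col]][sel] / m
    }
  }
  out
}
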