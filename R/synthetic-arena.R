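#' @include TrajectorySet-methods.R
NULL

#' Construct AgentTraits
#'
#' @param activity mean step length per time-step in cm (> 0)
#' @param attraction named numeric vector of social attraction weights in
#'   \[0, 1\], one per partner id
#' @param homeAffinity pull strength toward the agent's home-base point,
#'   in \[0, 1\]
#' @param noiseSd step-direction dispersion in radians
#' @param home optional (x, y) home-base coordinates in cm; when omitted the
#'   simulator assigns an arena corner
#' @return an \linkS4class{AgentTraits}
#' @export
agentTraits <- function(activity = 2, attraction = numeric(0),
                        homeAffinity = 0.1, noiseSd = 0.6, home = numeric(0)) {
  methods::new("AgentTraits", activity = activity,
               attraction = attraction, homeAffinity = homeAffinity,
               noiseSd = noiseSd, home = home)
}

setMethod("show", "AgentTraits", function(object) {
  cat(sprintf("AgentTraits: activity %.2f cm/step, home affinity %.2f, noise %.2f rad\n",
              object@activity, object@homeAffinity, object@noiseSd))
  if (length(object@attraction))
    cat("  attraction:",
        paste(sprintf("%s=%.2f", names(object@attraction), object@attraction),
              collapse = ", "), "\n")
})

#' Construct an ArenaConfig
#'
#' Defaults mirror the group-housing conditions the package emulates: a
#' 91 x 54 cm cage, nine-hour nightly sessions over a seven-day term,
#' simulated at 5 Hz.
#'
#' @param width,height arena dimensions in cm
#' @param frameRate sampling rate in Hz
#' @param sessionDuration session length in seconds
#' @param nDays sessions (days) per term
#' @param seed master RNG seed for the simulation
#' @return an \linkS4class{ArenaConfig}
#' @export
arenaConfig <- function(width = 91, height = 54, frameRate = 5,
                        sessionDuration = 9 * 3600, nDays = 7L, seed = 1L) {
  methods::new("ArenaConfig", width = width, height = height,
               frameRate = frameRate, sessionDuration = sessionDuration,
               nDays = as.integer(nDays), seed = as.integer(seed))
}

setMethod("show", "ArenaConfig", function(object) {
  cat(sprintf(
    "ArenaConfig: %.0f x %.0f cm, %.3g Hz, %.0f s/session, %d days, seed %d\n",
    object@width, object@height, object@frameRate, object@sessionDuration,
    object@nDays, object@seed))
})

# Corner home bases, cycled over agents, inset from the walls.
defaultHomes <- function(n, width, height, inset = 0.12) {
  dx <- width * inset; dy <- height * inset
  corners <- rbind(c(dx, dy), c(width - dx, dy),
                   c(width - dx, height - dy), c(dx, height - dy))
  corners[((seq_len(n) - 1L) %% 4L) + 1L, , drop = FALSE]
}

#' Simulate one term of group trajectories
#'
#' Agents follow a bounded correlated random walk: each step direction is the
#' angle of a drift vector mixing persistence along the previous heading,
#' pull toward a per-agent home base, and unit-vector attraction toward each
#' partner weighted by that partner's attraction weight, perturbed by Gaussian
#' angular noise; step length is exponentially distributed with the agent's
#' mean step length. Walls reflect. Identical (traits, config) reproduce
#' identical output: each day is simulated under a child seed derived from
#' \code{config@seed}, and the caller's RNG state is left untouched.
#'
#' @param traits list of exactly four \linkS4class{AgentTraits}, named by
#'   animal id; each agent's \code{attraction} must name the other three
#' @param config an \linkS4class{ArenaConfig}
#' @param familiarity optional named character vector: familiar partner id
#'   per animal. Familiarity is bookkeeping only; it influences movement
#'   solely through whatever attraction weights the caller chose.
#' @param persistence weight of the previous heading in the drift mixture
#' @return a list of \linkS4class{TrajectorySet}, one per day
#' @export
simulateGroup <- function(traits, config, familiarity = NULL,
                          persistence = 0.5) {
  if (!is.list(traits) || length(traits) != 4L)
    stop("simulateGroup requires exactly 4 agents")
  methods::validObject(config)
  ids <- names(traits)
  if (is.null(ids)) stop("traits must be a named list of AgentTraits")
  for (tr in traits) methods::validObject(tr)
  n <- length(ids)
  att <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in ids) {
    w <- traits[[a]]@attraction
    missing_p <- setdiff(ids[ids != a], names(w))
    if (length(w) && length(missing_p))
      stop("attraction weights of ", a, " must cover all partners")
    if (length(w)) att[a, names(w)] <- w
  }
  nf <- max(2L, as.integer(round(config@sessionDuration * config@frameRate)))
  homes <- defaultHomes(n, config@width, config@height)
  for (i in seq_len(n))
    if (length(traits[[i]]@home) == 2L) homes[i, ] <- traits[[i]]@home
  tt <- (seq_len(nf) - 1) / config@frameRate
  lapply(seq_len(config@nDays), function(day) {
    withSeed(childSeed(config@seed, day), {
      sx <- runif(n, 0, config@width)
      sy <- runif(n, 0, config@height)
      m <- simulate_crw_cpp(
        nf, att, vapply(traits, methods::slot, 0, "activity"),
        vapply(traits, methods::slot, 0, "homeAffinity"),
        vapply(traits, methods::slot, 0, "noiseSd"),
        homes, sx, sy, config@width, config@height, persistence)
      TrajectorySet(m[, seq_len(n), drop = FALSE],
                    m[, n + seq_len(n), drop = FALSE],
                    tt, animal_ids = ids,
                    arena = c(config@width, config@height),
                    frame_rate = config@frameRate, day = day,
                    familiar = familiarity)
    })
  })
}

#' The 13 items of the behavioral-test battery
#'
#' Column names of the battery score table, in canonical order: novel object
#' (NO), elevated plus maze (EPM), open field (OF), glove (GL) and
#' three-chamber (TC) test indices.
#'
#' @return character(13)
#' @export
batteryItems <- function() c(
  "NO center area entry", "NO distance", "NO head entry",
  "EPM open area entry", "EPM close area entry", "EPM distance",
  "OF distance", "OF center area entry",
  "GL handling", "GL avoid", "GL approach",
  "TC distance", "TC animal area entry")

#' Default ground-truth loading matrix for the simulated battery
#'
#' A 13 x 4 loading matrix emulating a low-rank latent-trait structure in
#' which each test's items load chiefly on one latent factor (exploration,
#' boldness, activity, tameness) while the three-chamber items load on none —
#' mirroring the empirical finding that sociability does not emerge as a
#' major axis. Factor strengths are distinct so recovered components have a
#' well-defined order.
#'
#' @return numeric matrix with rownames [batteryItems()] and columns F1..F4
#' @export
defaultLoadingMatrix <- function() {
  L <- matrix(0, 13, 4, dimnames = list(batteryItems(), paste0("F", 1:4)))
  L[1:3, 1] <- 0.90      # novel object -> exploration
  L[4:6, 2] <- 0.85      # elevated plus maze -> boldness
  L[7:8, 3] <- 0.90      # open field -> activity
  L[9:11, 4] <- 0.80     # glove -> tameness
  L[12:13, ] <- 0.15     # three-chamber: weak, diffuse
  L
}

#' Simulate a behavioral-test score battery with planted factor structure
#'
#' Scores are \code{latent \%*\% t(loadings) + noise}, returned
#' unstandardized, with the planted structure retained as attributes for
#' parameter-recovery testing.
#'
#' @param latent subjects x 4 matrix of latent factor values
#' @param loadingMatrix 13 x 4 loading matrix with rows named as
#'   [batteryItems()]; defaults to [defaultLoadingMatrix()]
#' @param noiseSd standard deviation of the additive Gaussian noise
#' @param seed RNG seed
#' @return data.frame of 13 battery columns, one row per subject, with
#'   attributes \code{latent} and \code{loadings}
#' @export
simulateTestBattery <- function(latent, loadingMatrix = defaultLoadingMatrix(),
                                noiseSd = 0.3, seed = 1L) {
  latent <- as.matrix(latent)
  loadingMatrix <- as.matrix(loadingMatrix)
  if (nrow(loadingMatrix) != 13L)
    stop("loadingMatrix must have 13 rows, one per battery item")
  if (is.null(rownames(loadingMatrix)))
    stop("loadingMatrix rows must be named as the battery items")
  if (ncol(latent) != ncol(loadingMatrix))
    stop("latent factor count must match the loading matrix columns")
  scores <- withSeed(seed, {
    latent %*% t(loadingMatrix) +
      matrix(rnorm(nrow(latent) * 13L, sd = noiseSd), nrow(latent), 13L)
  })
  colnames(scores) <- rownames(loadingMatrix)
  out <- as.data.frame(scores, check.names = FALSE)
  attr(out, "latent") <- latent
  attr(out, "loadings") <- loadingMatrix
  out
}

#' Corrupt a TrajectorySet with tracking-like failure modes
#'
#' Inserts (i) missing animal-frames (dropout), (ii) pairwise identity swaps
#' over contiguous spans, and (iii) single-frame large displacements (jumps),
#' returning the corrupted tracks together with a ground-truth corruption log.
#'
#' @param ts a \linkS4class{TrajectorySet}
#' @param dropoutRate expected fraction of animal-frames marked invalid
#' @param swapRate expected fraction of frames lying inside a swap span
#' @param jumpRate expected fraction of animal-frames displaced
#' @param seed RNG seed
#' @param meanSpanFrames mean length of a swap span, frames
#' @return list with elements \code{tracks} (corrupted TrajectorySet) and
#'   \code{log} (data.frame: type, animal_a, animal_b, start, end)
#' @export
corruptTracks <- function(ts, dropoutRate = 0, swapRate = 0, jumpRate = 0,
                          seed = 1L, meanSpanFrames = 10) {
  stopifnot(dropoutRate >= 0, dropoutRate <= 1, swapRate >= 0, swapRate <= 1,
            jumpRate >= 0, jumpRate <= 1)
  ids <- animalIds(ts)
  nf <- nrow(ts); n <- length(ids)
  x <- coordsX(ts); y <- coordsY(ts); v <- validMask(ts)
  arena <- arenaDims(ts)
  logs <- list()
  withSeed(seed, {
    if (swapRate > 0 && n >= 2) {
      n_span <- max(0L, as.integer(round(swapRate * nf / meanSpanFrames)))
      if (n_span > 0) {
        starts <- sort(sample.int(nf, n_span))
        last_end <- 0L
        for (s in starts) {
          if (s <= last_end + 1L) next  # keep spans disjoint
          len <- max(3L, as.integer(stats::rgeom(1, 1 / meanSpanFrames)) + 1L)
          e <- min(nf, s + len - 1L)
          last_end <- e
          pr <- sample.int(n, 2L)
          idxf <- s:e
          tmp <- x[idxf, pr[1]]
          x[idxf, pr[1]] <- x[idxf, pr[2]]; x[idxf, pr[2]] <- tmp
          tmp <- y[idxf, pr[1]]
          y[idxf, pr[1]] <- y[idxf, pr[2]]; y[idxf, pr[2]] <- tmp
          logs[[length(logs) + 1L]] <- data.frame(
            type = "swap", animal_a = ids[pr[1]], animal_b = ids[pr[2]],
            start = s, end = e, stringsAsFactors = FALSE)
        }
      }
    }
    if (jumpRate > 0) {
      hit <- which(matrix(runif(nf * n) < jumpRate, nf, n) & v)
      if (length(hit)) {
        ang <- runif(length(hit), 0, 2 * pi)
        mag <- runif(length(hit), 30, 60)
        x[hit] <- pmin(pmax(x[hit] + mag * cos(ang), 0), arena[1])
        y[hit] <- pmin(pmax(y[hit] + mag * sin(ang), 0), arena[2])
        fr <- ((hit - 1L) %% nf) + 1L
        an <- ((hit - 1L) %/% nf) + 1L
        logs[[length(logs) + 1L]] <- data.frame(
          type = "jump", animal_a = ids[an], animal_b = NA_character_,
          start = fr, end = fr, stringsAsFactors = FALSE)
      }
    }
    if (dropoutRate > 0) {
      drop <- which(matrix(runif(nf * n) < dropoutRate, nf, n) & v)
      if (length(drop)) {
        v[drop] <- FALSE
        x[drop] <- NA_real_
        y[drop] <- NA_real_
        fr <- ((drop - 1L) %% nf) + 1L
        an <- ((drop - 1L) %/% nf) + 1L
        logs[[length(logs) + 1L]] <- data.frame(
          type = "dropout", animal_a = ids[an], animal_b = NA_character_,
          start = fr, end = fr, stringsAsFactors = FALSE)
      }
    }
  })
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(type = character(), animal_a = character(),
               animal_b = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  out <- TrajectorySet(x, y, frameTimes(ts), valid = v, animal_ids = ids,
                       arena = arena, frame_rate = frameRate(ts),
                       day = metadata(ts)$day,
                       familiar = setNames(colData(ts)$familiar_partner, ids))
  list(tracks = out, log = log)
}

#' Apply the swap entries of a corruption log
#'
#' Exchanges the logged coordinate spans between the two animals of each
#' swap row. Applying the same log twice restores the original tracks, so
#' this both re-creates and undoes logged identity swaps.
#'
#' @param ts a \linkS4class{TrajectorySet}
#' @param log a corruption log from [corruptTracks()]
#' @return a \linkS4class{TrajectorySet}
#' @export
applySwapLog <- function(ts, log) {
  x <- coordsX(ts); y <- coordsY(ts)
  ids <- animalIds(ts)
  sw <- log[log$type == "swap", , drop = FALSE]
  for (i in seq_len(nrow(sw))) {
    idxf <- sw$start[i]:sw$end[i]
    a <- match(sw$animal_a[i], ids); b <- match(sw$animal_b[i], ids)
    tmp <- x[idxf, a]; x[idxf, a] <- x[idxf, b]; x[idxf, b] <- tmp
    tmp <- y[idxf, a]; y[idxf, a] <- y[idxf, b]; y[idxf, b] <- tmp
  }
  TrajectorySet(x, y, frameTimes(ts), valid = validMask(ts), animal_ids = ids,
                arena = arenaDims(ts), frame_rate = frameRate(ts),
                day = metadata(ts)$day,
                familiar = setNames(colData(ts)$familiar_partner, ids))
}
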