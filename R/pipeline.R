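#' @include stats-suite.R
NULL

#' Default end-to-end run configuration
#'
#' Every tunable that affects results lives in this one list; the whole list
#' is serialized next to the outputs so a run is reproducible from its own
#' record. Defaults mirror the emulated study conditions: three groups of
#' four animals, one familiar and two unfamiliar partners per subject,
#' nine-hour nightly sessions at 5 Hz over two seven-day terms, a 13-item
#' battery measured on 18 subjects of which 12 are tracked.
#'
#' @param seed master seed; every stage derives a child seed from it
#' @param sessionDuration session length in seconds (scale down for quick
#'   runs)
#' @param nDays days per term
#' @return a named list (see fields in the source)
#' @export
defaultRunConfig <- function(seed = 1L, sessionDuration = 9 * 3600,
                             nDays = 7L) {
  mk_group <- function(name, ids) list(
    name = name, animals = ids,
    familiar = setNames(ids[c(2, 1, 4, 3)], ids))
  list(
    seed = as.integer(seed),
    arena = list(width = 91, height = 54, frameRate = 5,
                 sessionDuration = sessionDuration, nDays = as.integer(nDays)),
    groups = list(
      mk_group("hippo", c("h1", "h2", "h3", "h4")),
      mk_group("okapi", c("o1", "o2", "o3", "o4")),
      mk_group("panda", c("p1", "p2", "p3", "p4"))),
    nTerms = 2L,
    excludeDays = list(),  # e.g. list(okapi = list(`1` = c(4, 5)))
    traits = list(baseActivity = 2, activityCoupling = 0.25,
                  attractionMax = 0.25, homeAffinity = 0.1, noiseSd = 0.6),
    corruption = list(enabled = FALSE, dropoutRate = 0.02, swapRate = 0.01,
                      jumpRate = 0.002),
    repair = list(maxSpeed = 100, maxGapS = 1, tol = 5),
    proximity = list(thresholdCm = 20, minBoutS = 2, windowS = 3),
    battery = list(nExtraSubjects = 6L, noiseSd = 0.3),
    stats = list(nKeep = 4L, cutoff = 0.4))
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [defaultRunConfig()]; missing keys take their defaults.
#'
#' @param path YAML file
#' @return a run-config list
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  merge2 <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]) &&
                       k != "groups")
        merge2(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- merge2(cfg, user)
  if (!is.null(user$groups))
    cfg$groups <- lapply(user$groups, function(g) {
      g$familiar <- unlist(g$familiar)
      g$animals <- unlist(g$animals)
      g
    })
  cfg
}

#' Validate a run configuration
#'
#' Stops with the offending field named on any schema violation.
#'
#' @param cfg a run-config list
#' @return the config, invisibly
#' @export
validateRunConfig <- function(cfg) {
  need <- c("seed", "arena", "groups", "nTerms", "traits", "corruption",
            "repair", "proximity", "battery", "stats")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing field(s): ",
                         paste(miss, collapse = ", "))
  a <- cfg$arena
  for (f in c("width", "height", "frameRate", "sessionDuration", "nDays"))
    if (is.null(a[[f]]) || a[[f]] <= 0)
      stop("config field arena$", f, " must be positive")
  for (g in cfg$groups) {
    if (length(g$animals) != 4L)
      stop("config field groups: group '", g$name,
           "' must have exactly 4 animals")
    if (!all(sort(names(g$familiar)) == sort(g$animals)))
      stop("config field groups: group '", g$name,
           "' familiar map must cover its 4 animals")
  }
  ids <- unlist(lapply(cfg$groups, `[[`, "animals"))
  if (anyDuplicated(ids)) stop("config field groups: duplicated animal ids")
  if (cfg$nTerms < 1L) stop("config field nTerms must be at least 1")
  for (f in c("dropoutRate", "swapRate", "jumpRate"))
    if (cfg$corruption[[f]] < 0 || cfg$corruption[[f]] > 1)
      stop("config field corruption$", f, " must lie in [0, 1]")
  if (cfg$proximity$thresholdCm <= 0)
    stop("config field proximity$thresholdCm must be positive")
  invisible(cfg)
}

# Ground-truth agent traits for one group, derived from the master seed and
# the subjects' latent battery factors (factor 3 scales step length, so the
# simulated "activity" trait is the one the battery is meant to measure).
groupTraits <- function(cfg, group, latent) {
  ids <- group$animals
  tcfg <- cfg$traits
  withSeed(childSeed(cfg$seed, 7000L + match(group$name,
                                             vapply(cfg$groups, `[[`, "",
                                                    "name"))), {
    lapply(setNames(ids, ids), function(id) {
      act <- tcfg$baseActivity *
        exp(tcfg$activityCoupling * latent[id, 3])
      partners <- setdiff(ids, id)
      agentTraits(
        activity = act,
        attraction = setNames(runif(3, 0, tcfg$attractionMax), partners),
        homeAffinity = tcfg$homeAffinity,
        noiseSd = tcfg$noiseSd)
    })
  })
}

#' Run the full pipeline: simulate, repair, metrics, battery, statistics
#'
#' Writes all intermediate CSVs, a machine-readable \code{results.json} and a
#' human-readable \code{report.md} into \code{outDir}. Identical
#' configurations produce byte-identical results.
#'
#' @param cfg run configuration from [defaultRunConfig()] or
#'   [readRunConfig()]
#' @param outDir output directory (created if needed); NULL skips all file
#'   output and just returns the results list
#' @return the results list, invisibly when written to disk
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outDir = NULL) {
  validateRunConfig(cfg)
  ids <- unlist(lapply(cfg$groups, `[[`, "animals"))
  group_of <- setNames(rep(vapply(cfg$groups, `[[`, "", "name"),
                           each = 4L), ids)
  n_extra <- cfg$battery$nExtraSubjects
  all_subjects <- c(ids, if (n_extra > 0) sprintf("x%d", seq_len(n_extra)))

  # behavioral-test battery with planted 4-factor structure
  latent <- withSeed(childSeed(cfg$seed, 1L),
                     matrix(rnorm(length(all_subjects) * 4L),
                            ncol = 4L,
                            dimnames = list(all_subjects, paste0("F", 1:4))))
  battery <- simulateTestBattery(latent, noiseSd = cfg$battery$noiseSd,
                                 seed = childSeed(cfg$seed, 2L))
  rownames(battery) <- all_subjects
  pca <- pcaBattery(battery, nKeep = cfg$stats$nKeep,
                    cutoff = cfg$stats$cutoff)
  scores <- pca@scores[ids, seq_len(pca@nKeep), drop = FALSE]

  # group trajectories, optional corruption + repair, daily social metrics
  daily <- list(); dyad_daily <- list(); events_all <- list()
  repair_reports <- list()
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    traits <- groupTraits(cfg, g, latent)
    for (term in seq_len(cfg$nTerms)) {
      ac <- arenaConfig(width = cfg$arena$width, height = cfg$arena$height,
                        frameRate = cfg$arena$frameRate,
                        sessionDuration = cfg$arena$sessionDuration,
                        nDays = cfg$arena$nDays,
                        seed = childSeed(cfg$seed, 100L * gi + term))
      days <- simulateGroup(traits, ac, familiarity = g$familiar)
      for (ts in days) {
        day <- metadata(ts)$day
        if (isTRUE(cfg$corruption$enabled)) {
          cr <- corruptTracks(ts, dropoutRate = cfg$corruption$dropoutRate,
                              swapRate = cfg$corruption$swapRate,
                              jumpRate = cfg$corruption$jumpRate,
                              seed = childSeed(cfg$seed,
                                               1000L * gi + 10L * term + day))
          rp <- repairTracks(cr$tracks, maxSpeed = cfg$repair$maxSpeed,
                             maxGapS = cfg$repair$maxGapS, reference = ts,
                             tol = cfg$repair$tol)
          repair_reports[[sprintf("%s_t%d_d%d", g$name, term, day)]] <-
            rp$report
          ts <- rp$tracks
        }
        ps <- proximitySeries(ts, thresholdCm = cfg$proximity$thresholdCm,
                              minBoutS = cfg$proximity$minBoutS)
        ev <- detectEvents(ps, ts, windowS = cfg$proximity$windowS)
        si <- socialIndices(ts, ps, ev)
        si$group <- g$name; si$term <- term
        daily[[length(daily) + 1L]] <- si
        pt <- proximityTime(ps)
        dyad_daily[[length(dyad_daily) + 1L]] <- data.frame(
          group = g$name, term = term, day = day,
          a = ps@dyadA, b = ps@dyadB, proximity_s = unname(pt),
          stringsAsFactors = FALSE)
        if (nrow(ev)) {
          ev$group <- g$name; ev$term <- term; ev$day <- day
          events_all[[length(events_all) + 1L]] <- ev
        }
      }
    }
  }
  daily <- do.call(rbind, daily)
  dyad_daily <- do.call(rbind, dyad_daily)
  events_all <- if (length(events_all)) do.call(rbind, events_all) else NULL

  excluded <- function(gname, term) {
    ex <- cfg$excludeDays[[gname]]
    if (is.null(ex)) return(integer(0))
    d <- ex[[as.character(term)]]
    if (is.null(d)) integer(0) else as.integer(d)
  }

  # term aggregation + group standardization
  term_tables <- list()
  for (term in seq_len(cfg$nTerms)) {
    tm <- do.call(rbind, lapply(cfg$groups, function(g) {
      rows <- daily[daily$term == term & daily$group == g$name, ,
                    drop = FALSE]
      agg <- aggregateTerm(rows, excludeDays = excluded(g$name, term))
      agg
    }))
    std <- standardizeByGroup(tm, group_of)
    term_tables[[term]] <- list(means = tm, standardized = std)
  }

  # dyad term means (per group standardized), ICCs, LMM, correlation panels
  famflag <- function(a, b) {
    g <- group_of[a]
    fam <- Find(function(x) x$name == g, cfg$groups)$familiar
    identical(unname(fam[a]), b)
  }
  stats_out <- list()
  for (term in seq_len(cfg$nTerms)) {
    dd <- dyad_daily[dyad_daily$term == term, , drop = FALSE]
    dd <- do.call(rbind, lapply(split(dd, dd$group), function(d) {
      d[!(d$day %in% excluded(d$group[1], term)), , drop = FALSE]
    }))
    dyad_means <- aggregate(proximity_s ~ group + a + b, data = dd, FUN = mean)
    gm <- tapply(dyad_means$proximity_s, dyad_means$group, mean)
    dyad_means$proximity_std <-
      as.numeric(dyad_means$proximity_s / gm[dyad_means$group])

    # ICC needs >= 2 subjects and >= 2 complete occasions; with fewer usable
    # days (heavy exclusions) the consistency is reported as not computed
    tryIcc <- function(m) {
      m2 <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
      if (nrow(m2) < 2L || ncol(m2) < 2L) NULL else icc3k(m)
    }
    icc_iso <- lapply(setNames(nm = vapply(cfg$groups, `[[`, "", "name")),
                      function(gname) {
      rows <- daily[daily$term == term & daily$group == gname, , drop = FALSE]
      rows <- rows[!(rows$day %in% excluded(gname, term)), , drop = FALSE]
      m <- tapply(rows$isolation_s, list(rows$subject, rows$day), mean)
      tryIcc(m)
    })
    icc_partner <- lapply(setNames(nm = ids), function(id) {
      d <- dd[dd$a == id | dd$b == id, , drop = FALSE]
      d$partner <- ifelse(d$a == id, d$b, d$a)
      m <- tapply(d$proximity_s, list(d$partner, d$day), mean)
      tryIcc(m)
    })

    lmm_rows <- do.call(rbind, lapply(seq_len(nrow(dyad_means)), function(i) {
      r <- dyad_means[i, ]
      data.frame(subject = c(r$a, r$b), partner = c(r$b, r$a),
                 proximity = r$proximity_std,
                 stringsAsFactors = FALSE)
    }))
    lmm_rows$familiar <- mapply(famflag, lmm_rows$subject, lmm_rows$partner)
    lrt <- lmmFamiliarityLrt(lmm_rows)

    std <- term_tables[[term]]$standardized
    idx <- std[match(ids, std$subject), socialIndexNames(), drop = FALSE]
    panel <- correlationPanel(scores, idx, cutoff = cfg$stats$cutoff)
    sim <- similarityAnalysis(pca@scores[, seq_len(pca@nKeep), drop = FALSE],
                              data.frame(a = dyad_means$a, b = dyad_means$b,
                                         proximity = dyad_means$proximity_std,
                                         stringsAsFactors = FALSE))
    stats_out[[term]] <- list(dyad_means = dyad_means, icc_isolation = icc_iso,
                              icc_partner = icc_partner, lrt = lrt,
                              panel = panel, similarity = sim)
  }

  battery_plain <- battery
  attr(battery_plain, "latent") <- NULL
  attr(battery_plain, "loadings") <- NULL
  results <- list(
    config = cfg,
    battery = cbind(subject = rownames(battery), battery_plain),
    pca = list(
      loadings = pca@loadings[, seq_len(pca@nKeep), drop = FALSE],
      eigenvalues = pca@eigenvalues,
      proportion_of_variance = pca@proportionOfVariance,
      kaiser_count = kaiserCount(pca@eigenvalues),
      cumulative_variance_pct = cumulativeVariance(
        pca@proportionOfVariance, seq_len(pca@nKeep)),
      salience = pca@salience,
      scores = cbind(subject = rownames(pca@scores),
                     as.data.frame(pca@scores[, seq_len(pca@nKeep),
                                              drop = FALSE]))),
    daily = daily, dyad_daily = dyad_daily, events = events_all,
    terms = lapply(seq_len(cfg$nTerms), function(term) list(
      means = term_tables[[term]]$means,
      standardized = term_tables[[term]]$standardized,
      icc_isolation = lapply(stats_out[[term]]$icc_isolation, function(r)
        if (is.null(r)) NULL else
          list(value = r@value, k = r@k, n = r@n, class = r@consistency)),
      icc_partner = lapply(stats_out[[term]]$icc_partner, function(r)
        if (is.null(r)) NULL else
          list(value = r@value, k = r@k, n = r@n, class = r@consistency)),
      lrt = stats_out[[term]]$lrt,
      panel = stats_out[[term]]$panel,
      similarity = stats_out[[term]]$similarity,
      dyad_means = stats_out[[term]]$dyad_means)),
    repair = lapply(repair_reports, function(r) list(
      n_frames = r@nFrames, n_flagged = r@nFlagged,
      n_interpolated = r@nInterpolated, n_swap_frames = r@nSwapFrames,
      accuracy = r@accuracy)))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results$battery, file.path(outDir, "battery.csv"),
              row.names = FALSE)
    write.csv(cbind(item = rownames(pca@loadings),
                    as.data.frame(pca@loadings[, seq_len(pca@nKeep),
                                               drop = FALSE])),
              file.path(outDir, "pca_loadings.csv"), row.names = FALSE)
    write.csv(daily, file.path(outDir, "daily_indices.csv"),
              row.names = FALSE)
    write.csv(dyad_daily, file.path(outDir, "dyad_daily.csv"),
              row.names = FALSE)
    if (!is.null(events_all))
      write.csv(events_all, file.path(outDir, "events.csv"),
                row.names = FALSE)
    for (term in seq_len(cfg$nTerms)) {
      write.csv(term_tables[[term]]$means,
                file.path(outDir, sprintf("term%d_means.csv", term)),
                row.names = FALSE)
      write.csv(term_tables[[term]]$standardized,
                file.path(outDir, sprintf("term%d_standardized.csv", term)),
                row.names = FALSE)
      write.csv(stats_out[[term]]$panel,
                file.path(outDir, sprintf("term%d_correlations.csv", term)),
                row.names = FALSE)
    }
    jsonlite::write_json(results, file.path(outDir, "results.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    writeLines(renderReport(results), file.path(outDir, "report.md"))
    return(invisible(results))
  }
  results
}

fmtNum <- function(x, d = 3) ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"), x))

#' Render a human-readable report from pipeline results
#'
#' Formats the four headline tables — battery loadings with salience markers
#' (assigned salient loadings in bold, salient-but-lower loadings in
#' italics), ICC consistency with classes, correlation panels with
#' moderate-to-high flags, and trait-similarity correlations — purely from
#' the results list; no statistic is recomputed at report time. Missing
#' sections are stated as not computed.
#'
#' @param results a results list from [runPipeline()]
#' @return character vector of markdown lines
#' @export
renderReport <- function(results) {
  out <- c("# Group social-behavior pipeline report", "")
  cutoff <- results$config$stats$cutoff
  if (!is.null(results$pca)) {
    p <- results$pca
    L <- as.matrix(as.data.frame(p$loadings))
    sal <- p$salience
    out <- c(out, "## Battery loadings (correlation-matrix PCA)", "",
             paste(c("| Item |", paste0("PC", seq_len(ncol(L)), " |")),
                   collapse = " "),
             paste(rep("| ---", ncol(L) + 1), collapse = " ") %+% " |")
    for (i in seq_len(nrow(L))) {
      cells <- vapply(seq_len(ncol(L)), function(j) {
        v <- fmtNum(L[i, j])
        if (!is.na(sal$component[i]) && sal$component[i] == j)
          paste0("**", v, "**")
        else if (abs(L[i, j]) >= cutoff) paste0("*", v, "*")
        else v
      }, "")
      out <- c(out, paste0("| ", rownames(L)[i], " | ",
                           paste(cells, collapse = " | "), " |"))
    }
    pv <- p$proportion_of_variance[seq_len(ncol(L))]
    out <- c(out, paste0("| Proportion of variance | ",
                         paste(fmtNum(pv), collapse = " | "), " |"), "",
             sprintf("Retained components explain %.1f%% of total variance;",
                     cumulativeVariance(p$proportion_of_variance,
                                        seq_len(ncol(L)))),
             sprintf("the Kaiser criterion (eigenvalue > 1) supports %d.",
                     p$kaiser_count),
             "Bold: assigned salient loading; italics: salient on another",
             "component with a lower loading.", "")
  } else out <- c(out, "## Battery loadings", "", "not computed", "")

  if (!is.null(results$terms)) {
    out <- c(out, "## Consistency of social indices (ICC(3,k))", "",
             "| Measure | Unit | Term | ICC | k | class |",
             "| --- | --- | --- | --- | --- | --- |")
    for (term in seq_along(results$terms)) {
      tt <- results$terms[[term]]
      for (g in names(tt$icc_isolation)) {
        r <- tt$icc_isolation[[g]]
        if (is.null(r)) {
          out <- c(out, sprintf(
            "| time in isolation | %s | %d | not computed | | |", g, term))
          next
        }
        v <- fmtNum(r$value)
        if (identical(r$class, "substantial")) v <- paste0("**", v, "**")
        out <- c(out, sprintf("| time in isolation | %s | %d | %s | %d | %s |",
                              g, term, v, r$k, r$class))
      }
      for (id in names(tt$icc_partner)) {
        r <- tt$icc_partner[[id]]
        if (is.null(r)) next
        v <- fmtNum(r$value)
        if (identical(r$class, "substantial")) v <- paste0("**", v, "**")
        out <- c(out, sprintf("| partner proximity | %s | %d | %s | %d | %s |",
                              id, term, v, r$k, r$class))
      }
    }
    out <- c(out, "", "Bold: substantial consistency (ICC > 0.7);",
             "0.4-0.7 moderate.", "")
    out <- c(out, "## Familiarity and partner preference (LMM + LRT)", "")
    for (term in seq_along(results$terms)) {
      l <- results$terms[[term]]$lrt
      out <- c(out, sprintf(
        "Term %d: chi-square(%d) = %s, p = %s%s", term, l$df,
        fmtNum(l$chi2), fmtNum(l$p),
        if (isTRUE(l$converged)) "" else " (convergence warnings)"))
    }
    out <- c(out, "", "## Component scores vs social indices (Pearson r)", "")
    for (term in seq_along(results$terms)) {
      panel <- results$terms[[term]]$panel
      if (is.null(panel) || !nrow(panel)) {
        out <- c(out, sprintf("Term %d: not computed", term), "")
        next
      }
      panel <- as.data.frame(panel)
      comps <- unique(panel$component)
      out <- c(out, sprintf("### Term %d", term), "",
               paste0("| Index | ", paste(comps, collapse = " | "), " |"),
               paste(rep("| ---", length(comps) + 1), collapse = " ") %+% " |")
      for (idx in unique(panel$index)) {
        cells <- vapply(comps, function(cc) {
          r <- panel[panel$component == cc & panel$index == idx, ]
          v <- fmtNum(r$display_r)
          if (isTRUE(r$flagged)) paste0("**", v, "**") else v
        }, "")
        out <- c(out, paste0("| ", idx, " | ",
                             paste(cells, collapse = " | "), " |"))
      }
      out <- c(out, "")
    }
    out <- c(out, sprintf(
      paste0("Bold: |r| >= %.1f (moderate to high). PC3 columns show ",
             "sign-inverted values for ease of interpretation."), cutoff), "")
    out <- c(out, "## Trait similarity vs dyad proximity", "")
    for (term in seq_along(results$terms)) {
      sim <- results$terms[[term]]$similarity
      if (is.null(sim) || !nrow(sim)) {
        out <- c(out, sprintf("Term %d: not computed", term))
        next
      }
      sim <- as.data.frame(sim)
      out <- c(out, sprintf("Term %d: %s", term,
                            paste(sprintf("%s r = %s", sim$component,
                                          fmtNum(sim$r)), collapse = ", ")))
    }
    out <- c(out, "")
  } else {
    out <- c(out, "## Social-index statistics", "", "not computed", "")
  }
  out
}

`%+%` <- function(a, b) paste0(a, b)
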