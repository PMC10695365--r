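# Shared fixture builders. Everything is generated in code; no stored data.

# A TrajectorySet from explicit per-animal coordinate columns.
mkTS <- function(xs, ys, frame_rate = 5, arena = c(91, 54), valid = NULL,
                 ids = NULL, familiar = NULL) {
  x <- do.call(cbind, xs)
  y <- do.call(cbind, ys)
  if (is.null(ids)) ids <- paste0("A", seq_len(ncol(x)))
  colnames(x) <- colnames(y) <- ids
  tt <- (seq_len(nrow(x)) - 1) / frame_rate
  TrajectorySet(x, y, tt, valid = valid, animal_ids = ids, arena = arena,
                frame_rate = frame_rate, familiar = familiar)
}

# Traits for four asocial agents (no attraction, no home pull).
zeroTraits <- function(ids = c("a", "b", "c", "d"), activity = 2,
                       noiseSd = 0.6) {
  lapply(setNames(ids, ids), function(id)
    agentTraits(activity = activity,
                attraction = setNames(rep(0, length(ids) - 1),
                                      setdiff(ids, id)),
                homeAffinity = 0, noiseSd = noiseSd))
}

# Traits with one mutually attracted dyad (first two ids), others asocial.
pairTraits <- function(ids = c("a", "b", "c", "d"), w = 0.9) {
  tr <- zeroTraits(ids)
  tr[[ids[1]]]@attraction[ids[2]] <- w
  tr[[ids[2]]]@attraction[ids[1]] <- w
  tr
}

famMap <- function(ids = c("a", "b", "c", "d")) setNames(ids[c(2, 1, 4, 3)], ids)

# Independent pure-R correlated random walk with the same movement rules as
# the simulator (persistence 0.5, exponential step length, reflective
# walls), used as a Monte-Carlo oracle that shares no code with the C++ path.
rwalkOracle <- function(nf, activity = 2, noiseSd = 0.6, w = 91, h = 54) {
  refl <- function(u, lim) {
    p <- u %% (2 * lim)
    if (p > lim) 2 * lim - p else p
  }
  x <- numeric(nf); y <- numeric(nf)
  x[1] <- runif(1, 0, w); y[1] <- runif(1, 0, h)
  heading <- runif(1, 0, 2 * pi)
  for (i in 2:nf) {
    ang <- heading + rnorm(1, 0, noiseSd)
    len <- rexp(1, 1 / activity)
    nx <- refl(x[i - 1] + len * cos(ang), w)
    ny <- refl(y[i - 1] + len * sin(ang), h)
    dx <- nx - x[i - 1]; dy <- ny - y[i - 1]
    if (dx^2 + dy^2 > 0) heading <- atan2(dy, dx) else heading <- ang
    x[i] <- nx; y[i] <- ny
  }
  cbind(x = x, y = y)
}

# Build a ProximitySeries by hand from a logical frames x dyads matrix.
mkPS <- function(series, dyadA, dyadB, dt = 0.2) {
  vf <- colMeans(!is.na(series))
  methods::new("ProximitySeries", series = series, dyadA = dyadA,
               dyadB = dyadB, dt = dt,
               sessionDuration = nrow(series) * dt, validFraction = vf,
               usable = vf >= 0.5, thresholdCm = 20, minBoutS = 0)
}

# Independent two-way ANOVA mean squares via stats::aov, used as the ICC
# oracle.
aovICC3k <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   occ = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  a <- summary(stats::aov(y ~ subj + occ, data = df))[[1]]
  bms <- a["subj", "Mean Sq"]
  ems <- a["Residuals", "Mean Sq"]
  (bms - ems) / bms
}

# Orthogonal disjoint-support loading matrix with unit row norms and
# distinct column norms (5, 4, 3, 1 items), for exact noiseless recovery.
plantedOrthoLoadings <- function() {
  L <- matrix(0, 13, 4, dimnames = list(batteryItems(), paste0("F", 1:4)))
  L[1:5, 1] <- 1
  L[6:9, 2] <- 1
  L[10:12, 3] <- 1
  L[13, 4] <- 1
  L
}

# Latent scores whitened so the sample covariance is exactly the identity.
whitenedLatent <- function(n, k, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * k), n, k)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(stats::cov(z)))
  colnames(z) <- paste0("F", seq_len(k))
  z
}

# Tucker congruence between two loading columns.
congruence <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))

# Mean congruence after orthogonal Procrustes alignment of the recovered
# components to the planted columns. Components with close eigenvalues are
# only identified up to rotation of their subspace, so recovery is assessed
# after the best orthogonal rotation (standard practice in factor-recovery
# simulation studies).
meanCongruence <- function(planted, recovered) {
  s <- svd(t(recovered) %*% planted)
  aligned <- recovered %*% (s$u %*% t(s$v))
  mean(vapply(seq_len(ncol(planted)), function(j)
    congruence(planted[, j], aligned[, j]), 0))
}

refPath <- function(f) system.file("extdata", f, package = "grouptrax")
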