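#' @include brs.R
NULL

#' CohortSpec: parameters of a synthetic two-run EEG cohort
#'
#' Describes the statistical structure the between-run-similarity analysis
#' assumes: per-region per-band baseline powers (log-normal across subjects
#' and epochs), within-run epoch-to-epoch jitter, and a group-dependent
#' run-2 perturbation of the band-power profile (multiplicative on power,
#' i.e. additive on log power).  A larger perturbation displaces the run-2
#' power vectors further from run 1 and therefore lowers the expected
#' between-run similarity of that group.
#'
#' @slot counts named numeric vector of participant counts per group (names
#'   from HC, MCI, AD).
#' @slot bands band-scheme data frame.
#' @slot montage [ScalpMontage-class] defining regions (and, for
#'   signal-level simulation, channels).
#' @slot regionPower regions x bands matrix of mean band powers (uV^2).
#' @slot subjectLogSd between-subject sd of log band power.
#' @slot jitterLogSd within-run epoch-to-epoch sd of log band power.
#' @slot perturbLogSd groups x bands matrix: sd of the run-2 log-power
#'   shift drawn once per participant per band.
#' @slot rate sampling rate in Hz (signal level).
#' @slot duration run duration in seconds (signal level).
#' @slot seed global seed; each participant uses a derived substream, so
#'   adding participants leaves existing ones unchanged.
#' @seealso [cohortSpec()], [simulateCohort()], [simulatePowerVectors()]
#' @exportClass CohortSpec
setClass("CohortSpec",
         representation(counts = "numeric", bands = "data.frame",
                        montage = "ScalpMontage", regionPower = "matrix",
                        subjectLogSd = "numeric", jitterLogSd = "numeric",
                        perturbLogSd = "matrix", rate = "numeric",
                        duration = "numeric", seed = "numeric"))

setValidity("CohortSpec", function(object) {
  if (any(object@counts < 0)) return("participant counts must be >= 0")
  if (!all(names(object@counts) %in% c("HC", "MCI", "AD")))
    return("count names must be among HC, MCI, AD")
  if (object@jitterLogSd < 0 || object@subjectLogSd < 0 ||
      any(object@perturbLogSd < 0))
    return("jitter/subject/perturbation scales must be >= 0")
  if (!identical(sort(rownames(object@regionPower)),
                 sort(regionNames(object@montage))))
    return("regionPower rows must match the montage regions")
  if (!identical(colnames(object@regionPower), object@bands$name))
    return("regionPower columns must match the band scheme")
  if (!identical(colnames(object@perturbLogSd), object@bands$name))
    return("perturbLogSd columns must match the band scheme")
  if (object@rate <= 0 || object@duration <= 0)
    return("rate and duration must be positive")
  TRUE
})

#' Build a synthetic-cohort specification
#'
#' Defaults mirror a clean eyes-open resting-state study: cohort sizes
#' 27 HC / 24 MCI / 23 AD; alpha-dominant mean band powers 8, 8, 10, 10,
#' 8, 6, 4 uV^2 for delta through gamma in every region; between-subject
#' log-power sd 0.2; epoch-to-epoch log-power jitter 0.15 (clean epochs of
#' a stationary resting run); and run-2 perturbations of log-sd
#' 0.05 for HC in all bands, 0.6 for MCI in the low-beta/high-beta/gamma
#' bands, and 0.5 for AD in the delta/theta bands (0.1 elsewhere for the
#' patient groups), reflecting the band-specific pattern of elevated
#' task-induced variability in the patient groups.
#'
#' @param counts named participant counts (default \code{c(HC = 27,
#'   MCI = 24, AD = 23)}).
#' @param bands band scheme (default [defaultBands()]).
#' @param montage montage (default [defaultMontage()]).
#' @param regionPower regions x bands mean-power matrix; default as above.
#' @param subjectLogSd,jitterLogSd log-power spread parameters.
#' @param perturbLogSd groups x bands run-2 shift matrix; default as above.
#' @param rate sampling rate in Hz (default 500).
#' @param duration run duration in seconds (default 90).
#' @param seed global seed (default 1).
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(counts = c(HC = 27, MCI = 24, AD = 23),
                       bands = defaultBands(), montage = defaultMontage(),
                       regionPower = NULL, subjectLogSd = 0.2,
                       jitterLogSd = 0.15, perturbLogSd = NULL,
                       rate = 500, duration = 90, seed = 1) {
  bands <- validateBands(bands)
  nb <- nrow(bands)
  regions <- regionNames(montage)
  if (is.null(regionPower)) {
    base <- c(8, 8, 10, 10, 8, 6, 4)
    profile <- if (nb == 7L) base else rep(5, nb)
    regionPower <- matrix(rep(profile, each = length(regions)),
                          nrow = length(regions),
                          dimnames = list(regions, bands$name))
  }
  if (is.null(perturbLogSd)) {
    perturbLogSd <- matrix(0.1, nrow = length(names(counts)), ncol = nb,
                           dimnames = list(names(counts), bands$name))
    if ("HC" %in% rownames(perturbLogSd))
      perturbLogSd["HC", ] <- 0.05
    if ("MCI" %in% rownames(perturbLogSd) &&
        all(c("low_beta", "high_beta", "gamma") %in% bands$name))
      perturbLogSd["MCI", c("low_beta", "high_beta", "gamma")] <- 0.6
    if ("AD" %in% rownames(perturbLogSd) &&
        all(c("delta", "theta") %in% bands$name))
      perturbLogSd["AD", c("delta", "theta")] <- 0.5
  }
  new("CohortSpec", counts = counts, bands = bands, montage = montage,
      regionPower = regionPower, subjectLogSd = subjectLogSd,
      jitterLogSd = jitterLogSd, perturbLogSd = perturbLogSd,
      rate = rate, duration = duration, seed = seed)
}

specParticipants <- function(spec) {
  groups <- rep(names(spec@counts), times = spec@counts)
  ids <- sprintf("%s%02d", groups, unlist(lapply(spec@counts, seq_len)))
  stats::setNames(groups, ids)
}

# Deterministic per-participant substream seed (kept below 2^31).
participantSeed <- function(seed, index) {
  as.integer(((seed %% 100000) * 10007 + index * 101 + 7) %% 2147483647)
}

# Per-participant latent structure: subject profile (log power,
# region x band), and the run-2 log-power shift (band vector).
drawParticipantProfile <- function(spec, group) {
  regions <- rownames(spec@regionPower)
  nb <- nrow(spec@bands)
  mu <- log(spec@regionPower) +
    matrix(rnorm(length(regions) * nb, sd = spec@subjectLogSd),
           nrow = length(regions), dimnames = dimnames(spec@regionPower))
  delta <- rnorm(nb, sd = spec@perturbLogSd[group, ])
  list(mu = mu, delta = delta)
}

#' Simulate region power-vector series directly
#'
#' Fast fixture level: draws each epoch's region band-power vector as a
#' log-normal deviate around the participant's profile, with the run-2
#' profile shifted by the group's perturbation.  Bypasses signal synthesis
#' entirely.
#'
#' @param spec a [CohortSpec-class].
#' @param nEpochs epochs per run (default 36).
#' @return list with \code{series} (participant -> region ->
#'   list(run1, run2) epoch x band matrices), \code{groups} (named label
#'   vector) and \code{manifest} (data frame).
#' @export
simulatePowerVectors <- function(spec, nEpochs = 36) {
  stopifnot(is(spec, "CohortSpec"))
  if (nEpochs < 1) stop("nEpochs must be >= 1")
  groups <- specParticipants(spec)
  regions <- rownames(spec@regionPower)
  nb <- nrow(spec@bands)
  series <- list()
  for (k in seq_along(groups)) {
    id <- names(groups)[k]
    set.seed(participantSeed(spec@seed, k))
    prof <- drawParticipantProfile(spec, groups[[k]])
    perRegion <- list()
    for (region in regions) {
      mats <- lapply(1:2, function(r) {
        shift <- if (r == 2L) prof$delta else rep(0, nb)
        eps <- matrix(rnorm(nEpochs * nb, sd = spec@jitterLogSd),
                      nrow = nEpochs)
        m <- exp(sweep(eps, 2, prof$mu[region, ] + shift, "+"))
        colnames(m) <- spec@bands$name
        m
      })
      perRegion[[region]] <- list(run1 = mats[[1]], run2 = mats[[2]])
    }
    series[[id]] <- perRegion
  }
  manifest <- data.frame(participant = names(groups),
                         group = unname(groups),
                         run1 = "", run2 = "", stringsAsFactors = FALSE)
  list(series = series, groups = groups, manifest = manifest)
}

# Band-limited Gaussian noise of unit variance via the preprocessing FIR
# design, then scaled per block to the target power envelope.
synthBandComponent <- function(nSamples, rate, band, power, envelope,
                               blockLen, taps) {
  x <- zeroPhaseFilter(taps, rnorm(nSamples))
  x <- x / stats::sd(x)
  amp <- sqrt(power * envelope)            # per-block amplitude
  scale <- rep(amp, each = blockLen, length.out = nSamples)
  x * scale
}

#' Simulate a two-run cohort at the raw-signal level
#'
#' Every channel is a sum of band-limited Gaussian noise components (white
#' noise filtered with the same FIR band-pass design used in
#' preprocessing), one per band, scaled so that the per-band variances
#' follow the participant's power profile; channels within a region share
#' the profile but carry independent noise.  Epoch-to-epoch jitter is
#' realized as a piecewise-constant per-band power envelope over
#' epoch-step-length blocks; run 2 uses the run-1 profile shifted by the
#' group's perturbation.
#'
#' @param spec a [CohortSpec-class].
#' @param epochS epoch length (s) the recording must accommodate; used only
#'   to validate the duration and to size the jitter blocks (default 6,
#'   overlap 0.6 -> 2.4 s blocks).
#' @param overlap assumed downstream epoch overlap for jitter-block sizing.
#' @param filterOrder FIR order used in band synthesis (default 300).
#' @return list with \code{recordings} (participant -> list(run1, run2)
#'   [EEGRecording-class]), \code{groups} and \code{manifest}.
#' @export
simulateCohort <- function(spec, epochS = 6, overlap = 0.6,
                           filterOrder = 300) {
  stopifnot(is(spec, "CohortSpec"))
  if (spec@duration < epochS)
    stop(sprintf("run duration %g s is shorter than one epoch (%g s)",
                 spec@duration, epochS))
  nSamples <- round(spec@duration * spec@rate)
  blockLen <- max(1L, round(epochS * (1 - overlap) * spec@rate))
  nBlocks <- ceiling(nSamples / blockLen)
  groups <- specParticipants(spec)
  regions <- regionNames(spec@montage)
  bands <- spec@bands
  taps <- lapply(seq_len(nrow(bands)), function(b)
    firBandpassTaps(bands$low[b], bands$high[b], spec@rate, filterOrder))
  recordings <- list()
  for (k in seq_along(groups)) {
    id <- names(groups)[k]
    group <- groups[[k]]
    set.seed(participantSeed(spec@seed, k))
    prof <- drawParticipantProfile(spec, group)
    runs <- list()
    for (r in 1:2) {
      shift <- if (r == 2L) prof$delta else rep(0, nrow(bands))
      chans <- list()
      for (region in regions) {
        # shared per-region per-band jitter envelope (multiplicative power)
        env <- matrix(exp(rnorm(nBlocks * nrow(bands),
                                sd = spec@jitterLogSd)),
                      nrow = nrow(bands))
        for (el in regionElectrodes(spec@montage, region)) {
          if (!is.null(chans[[el]])) next   # electrode shared across regions
          sig <- numeric(nSamples)
          for (b in seq_len(nrow(bands))) {
            p <- exp(prof$mu[region, b] + shift[b])
            sig <- sig + synthBandComponent(nSamples, spec@rate,
                                            c(bands$low[b], bands$high[b]),
                                            p, env[b, ], blockLen, taps[[b]])
          }
          chans[[el]] <- sig
        }
      }
      samples <- do.call(rbind, chans)
      rownames(samples) <- names(chans)
      runs[[paste0("run", r)]] <- eegRecording(
        samples, rate = spec@rate, channels = names(chans),
        participant = id, group = group, run = r)
    }
    recordings[[id]] <- runs
  }
  manifest <- data.frame(participant = names(groups),
                         group = unname(groups),
                         run1 = "", run2 = "", stringsAsFactors = FALSE)
  list(recordings = recordings, groups = groups, manifest = manifest)
}

#' Write a simulated cohort to disk in the package array format
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed); writes
#'   \code{<id>_run<r>.csv/.yaml} pairs and \code{manifest.csv}.
#' @return the manifest data frame (with file paths filled in), invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$participant[i]
    for (r in 1:2) {
      base <- file.path(dir, sprintf("%s_run%d", id, r))
      writeRecordingArray(cohort$recordings[[id]][[paste0("run", r)]], base)
      manifest[[paste0("run", r)]][i] <- paste0(base, ".csv")
    }
  }
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
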