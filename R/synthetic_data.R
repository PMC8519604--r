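#' Specification for synthetic multi-domain "blob" benchmarks
#'
#' Describes a family of Gaussian-blob classification domains used to
#' exercise the adaptation losses and the training loop quickly.  All
#' domains share the same class means; each domain additionally applies its
#' own random rotation and offset whose magnitude is controlled by
#' `domain_shift_scale`, emulating the covariate shift between subjects.
#' The last domain plays the role of the unlabeled target; its true labels
#' are emitted in a separate element so that no training path can touch
#' them.
#'
#' @param n_domains Total number of domains, sources plus one target
#'   (>= 2).
#' @param n_classes Number of classes C (>= 2).
#' @param n_per_class Samples drawn per class in every domain.
#' @param dim Feature dimension.
#' @param class_separation Distance of each class mean from the origin;
#'   class means are random unit directions scaled by this value, noise is
#'   unit Gaussian.
#' @param domain_shift_scale Standard deviation of the per-domain affine
#'   perturbation (skew entries of a Cayley rotation and the offset
#'   vector).  Zero means every domain is drawn from the identical
#'   distribution.
#' @param seed Integer seed; identical specs produce bit-identical data.
#' @return An object of class `blob_spec`.
#' @seealso [make_blob_domains()]
#' @export
blob_spec <- function(n_domains = 4, n_classes = 2, n_per_class = 100,
                      dim = 8, class_separation = 2.5,
                      domain_shift_scale = 0.5, seed = 1) {
  spec <- list(
    n_domains = check_count(n_domains, "n_domains", min = 2L),
    n_classes = check_count(n_classes, "n_classes", min = 2L),
    n_per_class = check_count(n_per_class, "n_per_class", min = 1L),
    dim = check_count(dim, "dim", min = 1L),
    class_separation = check_number(class_separation, "class_separation",
                                    min = 0),
    domain_shift_scale = check_number(domain_shift_scale,
                                      "domain_shift_scale", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(spec, class = "blob_spec")
}

# Cayley transform of a random skew-symmetric matrix: an orthogonal matrix
# that equals the identity when scale = 0 and drifts away continuously.
random_rotation <- function(dim, scale) {
  a <- matrix(stats::rnorm(dim * dim, sd = scale), dim, dim)
  s <- (a - t(a)) / 2
  solve(diag(dim) + s, diag(dim) - s)
}

#' Generate labeled source domains and an unlabeled target domain
#'
#' Draws `n_domains` Gaussian-blob datasets under a [blob_spec()].  The
#' first `n_domains - 1` are labeled sources; the last is returned without
#' labels as the target.  The target's ground-truth labels are returned in
#' the separate `target_labels` element, which exists only for evaluation.
#'
#' @param spec A [blob_spec()].
#' @return A list of class `blob_domains` with elements `sources` (list of
#'   `list(x, y)` with `y` in 0..C-1), `target_x` (unlabeled matrix),
#'   `target_labels` (hidden ground truth) and `spec`.
#' @export
make_blob_domains <- function(spec) {
  if (!inherits(spec, "blob_spec")) stopf("`spec` must be a blob_spec")
  with_seed(spec$seed, {
    mu <- matrix(stats::rnorm(spec$n_classes * spec$dim),
                 spec$n_classes, spec$dim)
    mu <- mu / pmax(sqrt(rowSums(mu^2)), 1e-12) * spec$class_separation
    domains <- vector("list", spec$n_domains)
    for (d in seq_len(spec$n_domains)) {
      rot <- random_rotation(spec$dim, spec$domain_shift_scale)
      off <- stats::rnorm(spec$dim, sd = spec$domain_shift_scale)
      xs <- vector("list", spec$n_classes)
      for (c in seq_len(spec$n_classes)) {
        e <- matrix(stats::rnorm(spec$n_per_class * spec$dim),
                    spec$n_per_class, spec$dim)
        pts <- sweep(e, 2L, mu[c, ], `+`) %*% t(rot)
        xs[[c]] <- sweep(pts, 2L, off, `+`)
      }
      domains[[d]] <- list(
        x = do.call(rbind, xs),
        y = rep(seq_len(spec$n_classes) - 1L, each = spec$n_per_class)
      )
    }
  })
  n_src <- spec$n_domains - 1L
  tgt <- domains[[spec$n_domains]]
  structure(list(
    sources = domains[seq_len(n_src)],
    target_x = tgt$x,
    target_labels = tgt$y,
    spec = spec
  ), class = "blob_domains")
}

#' Specification for a synthetic multi-subject EEG cohort
#'
#' Describes a cohort of subjects recorded under two mental states, awake
#' and fatigue, with the same geometry as a 61-channel, 200 Hz driving
#' study: per subject, 700 half-second segments per state.  Each segment is
#' band-limited noise synthesised in the frequency domain; the two states
#' differ by multiplicative band-power gains (`band_effects`), and each
#' subject applies its own random per-channel gains and band-gain jitter —
#' the cross-subject domain shift the adaptation model must overcome.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param n_channels Number of EEG channels (default 61).
#' @param fs Sampling rate in Hz (default 200).
#' @param segments_per_class Segments per mental state per subject
#'   (default 700).
#' @param window_s Segment length in seconds; `fs * window_s` must be a
#'   positive integer (default 0.5).
#' @param band_effects Named list over `theta`, `alpha`, `beta`; each entry
#'   is `c(awake = g0, fatigue = g1)` giving the power gain applied inside
#'   that band for the two states.  The defaults raise theta and alpha
#'   power and lower beta power under fatigue, the direction reported for
#'   drowsy EEG.
#' @param subject_gain_sd Log-scale standard deviation of the per-channel
#'   gains and band jitter that differentiate subjects; 0 removes the
#'   inter-subject shift.
#' @param noise_model `"pink"` (1/f-shaped, EEG-plausible, default) or
#'   `"white"`.
#' @param seed Integer seed.  Per-subject seeds are derived from it;
#'   `subject_seeds` may override them (e.g. to make all subjects draw the
#'   identical noise realisation).
#' @param subject_seeds Optional integer vector of length `n_subjects`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 15, n_channels = 61, fs = 200,
                        segments_per_class = 700, window_s = 0.5,
                        band_effects = list(
                          theta = c(awake = 1, fatigue = 1.6),
                          alpha = c(awake = 1, fatigue = 1.5),
                          beta  = c(awake = 1.2, fatigue = 0.8)),
                        subject_gain_sd = 0.2, noise_model = c("pink", "white"),
                        seed = 1, subject_seeds = NULL) {
  noise_model <- match.arg(noise_model)
  n_subjects <- check_count(n_subjects, "n_subjects")
  fs <- check_number(fs, "fs", min = 1)
  window_s <- check_number(window_s, "window_s", min = 1e-9)
  if (abs(fs * window_s - round(fs * window_s)) > 1e-9 ||
      round(fs * window_s) < 1) {
    stopf("fs * window_s must be a positive integer (got %g)", fs * window_s)
  }
  if (!all(names(band_effects) %in% c("theta", "alpha", "beta"))) {
    stopf("band_effects keys must be among theta, alpha, beta")
  }
  for (b in names(band_effects)) {
    g <- band_effects[[b]]
    if (length(g) != 2L || any(!is.finite(g)) || any(g < 0)) {
      stopf("band_effects$%s must be c(awake=, fatigue=) nonnegative gains", b)
    }
  }
  if (!is.null(subject_seeds) && length(subject_seeds) != n_subjects) {
    stopf("subject_seeds must have length n_subjects")
  }
  structure(list(
    n_subjects = n_subjects,
    n_channels = check_count(n_channels, "n_channels"),
    fs = fs,
    segments_per_class = check_count(segments_per_class,
                                     "segments_per_class"),
    window_s = window_s,
    band_effects = band_effects,
    subject_gain_sd = check_number(subject_gain_sd, "subject_gain_sd",
                                   min = 0),
    noise_model = noise_model,
    seed = check_count(seed, "seed", min = 0L),
    subject_seeds = if (is.null(subject_seeds)) NULL
                    else as.integer(subject_seeds)
  ), class = "cohort_spec")
}

band_ranges <- function() {
  list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30))
}

# one-sided amplitude template (length L/2 + 1) for a window of L samples
# at rate fs: 1/f (pink) or flat (white) shaping times sqrt of the band
# power gains active for this state, times per-band jitter.
spectral_amplitude <- function(spec, state, band_jitter) {
  L <- as.integer(round(spec$fs * spec$window_s))
  freqs <- (0:(L %/% 2)) * spec$fs / L
  amp <- if (spec$noise_model == "pink") 1 / sqrt(pmax(freqs, 1)) else
    rep(1, length(freqs))
  amp[1] <- 0  # no DC component
  ranges <- band_ranges()
  for (b in names(spec$band_effects)) {
    r <- ranges[[b]]
    sel <- freqs >= r[1] & freqs <= r[2]
    gain <- spec$band_effects[[b]][[state]] * band_jitter[[b]]
    amp[sel] <- amp[sel] * sqrt(gain)
  }
  amp
}

# Synthesise n_seg windows x n_ch channels of length-L noise with the given
# one-sided amplitude profile (per-channel multiplicative gain applied on
# top), returning a channels x (n_seg * L) matrix of concatenated windows.
synth_windows <- function(amp, channel_gains, n_seg, L) {
  n_ch <- length(channel_gains)
  m <- n_seg * n_ch
  nh <- L %/% 2
  # columns ordered channel-fastest within each segment
  spec_mat <- matrix(0 + 0i, nrow = L, ncol = m)
  ch_amp <- outer(amp, sqrt(channel_gains))  # (nh+1) x n_ch amplitude
  if (nh >= 2) {
    k <- 2:nh  # strictly positive, non-Nyquist bins
    re <- matrix(stats::rnorm(length(k) * m, sd = sqrt(0.5)), length(k), m)
    im <- matrix(stats::rnorm(length(k) * m, sd = sqrt(0.5)), length(k), m)
    a <- ch_amp[k, rep(seq_len(n_ch), times = n_seg), drop = FALSE]
    spec_mat[k, ] <- (re + 1i * im) * a
    spec_mat[L + 2 - k, ] <- Conj(spec_mat[k, ])
  }
  if (L %% 2 == 0) {  # real Nyquist bin
    nyq <- stats::rnorm(m)
    spec_mat[nh + 1, ] <- nyq * ch_amp[nh + 1, rep(seq_len(n_ch), n_seg)]
  }
  x <- Re(stats::mvfft(spec_mat, inverse = TRUE)) / sqrt(L)
  arr <- array(x, dim = c(L, n_ch, n_seg))
  out <- aperm(arr, c(2L, 1L, 3L))
  dim(out) <- c(n_ch, L * n_seg)
  out
}

#' Simulate one subject of the synthetic cohort
#'
#' Deterministic given the spec and subject index: the subject's seed is
#' derived from `spec$seed` (or taken from `spec$subject_seeds`).
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index in 1..n_subjects.
#' @return A list with `subject_id`, and [eeg_recording()] objects `awake`
#'   and `fatigue` holding the concatenated non-overlapping segments.
#' @export
simulate_subject <- function(spec, subject) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  subject <- check_count(subject, "subject")
  if (subject > spec$n_subjects) stopf("subject index out of range")
  sseed <- if (!is.null(spec$subject_seeds)) spec$subject_seeds[subject]
           else child_seed(spec$seed, subject)
  L <- as.integer(round(spec$fs * spec$window_s))
  with_seed(sseed, {
    gains <- stats::rlnorm(spec$n_channels, 0, spec$subject_gain_sd)
    jitter <- as.list(stats::rlnorm(length(spec$band_effects), 0,
                                    spec$subject_gain_sd / 2))
    names(jitter) <- names(spec$band_effects)
    recs <- lapply(c(awake = "awake", fatigue = "fatigue"), function(state) {
      amp <- spectral_amplitude(spec, state, jitter)
      data <- synth_windows(amp, gains, spec$segments_per_class, L)
      eeg_recording(data, spec$fs)
    })
  })
  list(subject_id = sprintf("S%02d", subject),
       awake = recs$awake, fatigue = recs$fatigue)
}

#' Simulate the full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `eeg_cohort`: one [simulate_subject()] result per
#'   subject.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  structure(lapply(seq_len(spec$n_subjects),
                   function(i) simulate_subject(spec, i)),
            class = "eeg_cohort", spec = spec)
}
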