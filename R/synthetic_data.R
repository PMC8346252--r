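# Seeded synthetic-data generators. Each generator emulates the statistical
# structure one analysis stage assumes and returns the ground truth exactly
# as generated, so downstream operations can be checked by recovery
# experiments. Identical seed + arguments give bitwise-identical output.

#' Generate a fully crossed study design
#'
#' 2 genotypes x 2 sexes x 3 ages with `n_per_cell` replicates per cell
#' (6 per cell gives the standard 72-sample transcriptome design).
#'
#' @param n_per_cell replicates per design cell (>= 1).
#' @param seed integer seed (affects nothing here but kept for interface
#'   uniformity).
#' @param ages ages in months (default 4, 6, 12).
#' @return A data.frame: `subject_id`, `genotype` (TG/WT), `sex` (F/M),
#'   `age_months`, `replicate`.
#' @export
gen_study_design <- function(n_per_cell, seed = 1, ages = c(4, 6, 12)) {
  check_scalar_number(n_per_cell, "n_per_cell", lower = 1)
  grid <- expand.grid(replicate = seq_len(n_per_cell),
                      age_months = ages, sex = c("F", "M"),
                      genotype = c("TG", "WT"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "sex", "age_months", "replicate")]
  grid$subject_id <- sprintf("%s_%s_%02dm_r%d", grid$genotype, grid$sex,
                             grid$age_months, grid$replicate)
  grid[, c("subject_id", "genotype", "sex", "age_months", "replicate")]
}

#' EEG simulation specification
#'
#' Targets are expressed directly in the staging features: per-stage delta
#' ratio (delta/total) and theta ratio (theta/delta), and per-stage EMG tone
#' (RMS, microvolts). Defaults keep a >= 0.15 margin beyond the staging
#' thresholds (SWS delta 0.6 vs threshold 0.4; paradoxical theta 5 vs 3) and
#' wake EMG well above the 40 uV gate.
#'
#' @param duration_s recording length in seconds.
#' @param stage_dwell_means named mean episode durations (s) of the
#'   semi-Markov stage process.
#' @param stage_delta,stage_theta named per-stage target ratios.
#' @param emg_tone_uV named per-stage EMG RMS.
#' @param eeg_rms_uV overall EEG RMS scale.
#' @param swd_events data.frame of events to inject (`start_s`, `n_spikes`,
#'   `inter_spike_s`, `amplitude_multiplier`), or NULL.
#' @param spike_width_ms width of the injected biphasic transient (default
#'   20 ms; admissible detection window is 1-200 ms).
#' @param sample_rate_hz,epoch_length_s sampling and scoring geometry.
#' @param seed integer seed.
#' @return A list of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(duration_s = 600,
                         stage_dwell_means = c(WAKE = 240, SWS = 180,
                                               PARADOXICAL = 60),
                         stage_delta = c(WAKE = 0.2, SWS = 0.6,
                                         PARADOXICAL = 0.08),
                         stage_theta = c(WAKE = 1, SWS = 0.5,
                                         PARADOXICAL = 5),
                         emg_tone_uV = c(WAKE = 90, SWS = 15,
                                         PARADOXICAL = 10),
                         eeg_rms_uV = 50,
                         swd_events = NULL,
                         spike_width_ms = 20,
                         sample_rate_hz = 500, epoch_length_s = 10,
                         seed = 1) {
  if (any(stage_dwell_means <= epoch_length_s))
    stop_invalid("stage dwell means must exceed the epoch length")
  stages <- names(stage_dwell_means)
  stage_delta <- stage_delta[stages]
  stage_theta <- stage_theta[stages]
  emg_tone_uV <- emg_tone_uV[stages]
  if ("SWS" %in% stages && stage_delta[["SWS"]] <= 0.4 + 0.05)
    stop_invalid("SWS delta-ratio target must clear the 0.4 threshold")
  if ("PARADOXICAL" %in% stages && stage_theta[["PARADOXICAL"]] <= 3 + 0.05)
    stop_invalid("paradoxical theta-ratio target must clear the 3 threshold")
  if ("WAKE" %in% stages && emg_tone_uV[["WAKE"]] <= 40)
    stop_invalid("wake EMG tone must exceed the gating threshold")
  rest <- 1 - stage_delta - stage_theta * stage_delta
  if (any(rest < 0))
    stop_invalid("per-stage targets imply negative residual band power")
  if (!is.null(swd_events) && nrow(swd_events) > 1) {
    ends <- swd_events$start_s +
      (swd_events$n_spikes - 1) * swd_events$inter_spike_s +
      spike_width_ms / 1000
    o <- order(swd_events$start_s)
    if (any(swd_events$start_s[o][-1] < ends[o][-length(o)]))
      stop_invalid("overlapping SWD events")
  }
  structure(list(duration_s = duration_s,
                 stage_dwell_means = stage_dwell_means,
                 stage_delta = stage_delta, stage_theta = stage_theta,
                 emg_tone_uV = emg_tone_uV, eeg_rms_uV = eeg_rms_uV,
                 swd_events = swd_events, spike_width_ms = spike_width_ms,
                 sample_rate_hz = sample_rate_hz,
                 epoch_length_s = epoch_length_s, seed = seed),
            class = "eeg_sim_spec")
}

# Band-limited noise for one epoch, synthesized in the frequency domain so
# the periodogram band powers hit the targets exactly: constant amplitude
# within each band, uniform random phases, conjugate-symmetric spectrum.
synth_epoch_eeg <- function(n, fs, delta_ratio, theta_ratio, rms,
                            delta_band = c(0.5, 4), theta_band = c(4, 8),
                            total_band = c(0.5, 80)) {
  freqs <- (seq_len(n) - 1) * fs / n
  half_k <- 2:(floor(n / 2))            # positive frequencies, excl. DC/Nyquist
  f_half <- freqs[half_k]
  in_delta <- f_half > delta_band[1] & f_half <= delta_band[2]
  in_theta <- f_half > theta_band[1] & f_half <= theta_band[2]
  in_rest <- f_half > theta_band[2] & f_half <= total_band[2]
  p_total <- n * rms^2 / 2               # half-spectrum band-power total
  p_delta <- delta_ratio * p_total
  p_theta <- theta_ratio * delta_ratio * p_total
  p_rest <- p_total - p_delta - p_theta
  amp2 <- numeric(length(half_k))
  amp2[in_delta] <- p_delta * n / sum(in_delta)
  amp2[in_theta] <- p_theta * n / sum(in_theta)
  amp2[in_rest] <- p_rest * n / sum(in_rest)
  phases <- runif(length(half_k), 0, 2 * pi)
  spec <- complex(modulus = sqrt(amp2), argument = phases)
  X <- complex(real = numeric(n))
  X[half_k] <- spec
  X[n - half_k + 2] <- Conj(spec)
  Re(fft(X, inverse = TRUE)) / n
}

#' Generate a synthetic EEG/EMG recording with ground truth
#'
#' The stage sequence follows a semi-Markov process (exponential dwell times
#' truncated at one epoch minimum). Each epoch's EEG is band-limited noise
#' whose periodogram band-power ratios equal the stage targets; EMG is
#' band-limited (10-100 Hz) noise at the stage tone; activity counts are
#' Poisson during wake and zero during sleep. Spike-wave events are injected
#' as trains of biphasic transients whose amplitude is a multiple of the
#' realized median absolute EEG amplitude.
#'
#' @param spec an \code{\link{eeg_sim_spec}}.
#' @return A list: `recording` (a `fad_recording`), `hypnogram` (true
#'   per-epoch stages), `swd_events` (true event table: `start_s`, `end_s`,
#'   `n_spikes`, `duration_s`).
#' @export
gen_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  with_seed(spec$seed, {
    fs <- spec$sample_rate_hz
    ep_len <- spec$epoch_length_s
    n_epochs <- floor(spec$duration_s / ep_len)
    stages <- names(spec$stage_dwell_means)
    # semi-Markov stage sequence
    seq_stages <- character(0)
    cur <- if (length(stages) > 1) sample(stages, 1) else stages
    while (length(seq_stages) < n_epochs) {
      dwell <- max(ep_len, rexp(1, 1 / spec$stage_dwell_means[[cur]]))
      k <- max(1L, round(dwell / ep_len))
      seq_stages <- c(seq_stages, rep(cur, k))
      if (length(seq_stages) >= n_epochs) break
      nxt <- setdiff(stages, cur)
      cur <- if (length(nxt) > 1) sample(nxt, 1) else nxt
    }
    seq_stages <- seq_stages[seq_len(n_epochs)]
    n_ep_samp <- round(ep_len * fs)
    eeg <- numeric(n_epochs * n_ep_samp)
    emg <- numeric(n_epochs * n_ep_samp)
    activity <- numeric(n_epochs * ep_len)
    for (e in seq_len(n_epochs)) {
      st <- seq_stages[e]
      idx <- ((e - 1) * n_ep_samp + 1):(e * n_ep_samp)
      eeg[idx] <- synth_epoch_eeg(n_ep_samp, fs, spec$stage_delta[[st]],
                                  spec$stage_theta[[st]], spec$eeg_rms_uV)
      # EMG: band-limited 10-100 Hz noise at the stage tone (delta/theta
      # placeholders put all power in the 10-100 "rest" band)
      emg[idx] <- synth_epoch_eeg(n_ep_samp, fs, 0, 0, spec$emg_tone_uV[[st]],
                                  delta_band = c(10, 12),
                                  theta_band = c(12, 14),
                                  total_band = c(10, 100))
      sec <- ((e - 1) * ep_len + 1):(e * ep_len)
      activity[sec] <- if (st == "WAKE") rpois(ep_len, 3) else 0
    }
    truth_events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                               n_spikes = integer(0), duration_s = numeric(0))
    if (!is.null(spec$swd_events) && nrow(spec$swd_events)) {
      baseline <- median(abs(eeg))
      w <- round(spec$spike_width_ms / 1000 * fs)
      half <- floor(w / 2)
      shape <- c(sin(pi * seq_len(half) / half),
                 -sin(pi * seq_len(w - half) / (w - half)))
      ev <- spec$swd_events
      for (i in seq_len(nrow(ev))) {
        times <- ev$start_s[i] + (seq_len(ev$n_spikes[i]) - 1) * ev$inter_spike_s[i]
        for (t0 in times) {
          s0 <- round(t0 * fs) + 1
          idx <- s0:(s0 + w - 1)
          idx <- idx[idx <= length(eeg)]
          eeg[idx] <- eeg[idx] +
            ev$amplitude_multiplier[i] * baseline * shape[seq_along(idx)]
        }
        truth_events <- rbind(truth_events, data.frame(
          start_s = times[1], end_s = times[length(times)],
          n_spikes = ev$n_spikes[i],
          duration_s = times[length(times)] - times[1]))
      }
      truth_events <- truth_events[order(truth_events$start_s), ]
      rownames(truth_events) <- NULL
    }
    rec <- recording(eeg, emg, activity = activity,
                     sample_rate_hz = fs)
    hyp <- data.frame(epoch_start_s = (seq_len(n_epochs) - 1) * ep_len,
                      stage = seq_stages, stringsAsFactors = FALSE)
    attr(hyp, "epoch_length_s") <- ep_len
    attr(hyp, "start_clock_s") <- rec$start_clock_s
    attr(hyp, "lights_on_s") <- rec$lights_on_s
    attr(hyp, "lights_off_s") <- rec$lights_off_s
    list(recording = rec, hypnogram = hyp, swd_events = truth_events)
  })
}

#' Evenly spaced spike-wave event schedule
#'
#' Convenience builder for \code{\link{eeg_sim_spec}}'s `swd_events`.
#'
#' @param n_events number of events.
#' @param first_start_s start of the first event (seconds).
#' @param spacing_s event-to-event spacing (must exceed the train span plus
#'   the join interval to keep events distinct).
#' @param n_spikes,inter_spike_s,amplitude_multiplier per-event parameters.
#' @return A data.frame suitable for `swd_events`.
#' @export
swd_schedule <- function(n_events, first_start_s = 30, spacing_s = 8,
                         n_spikes = 6, inter_spike_s = 0.2,
                         amplitude_multiplier = 8) {
  data.frame(start_s = first_start_s + (seq_len(n_events) - 1) * spacing_s,
             n_spikes = n_spikes, inter_spike_s = inter_spike_s,
             amplitude_multiplier = amplitude_multiplier)
}

disc_offsets <- function(r) {
  d <- expand.grid(di = -r:r, dj = -r:r)
  d[d$di^2 + d$dj^2 <= r^2, ]
}

#' Generate synthetic serial-section images with plaques
#'
#' Channel 1 holds a smooth autofluorescent background; channel 3 holds
#' `leak_fraction` of channel 1 plus disc-shaped plaques rendered at the
#' requested per-region fractional-area densities (discs are placed wholly
#' inside their region). The returned truth is measured from the rendered
#' masks, not from the requested densities.
#'
#' @param labels integer atlas label matrix (0 = background), shared by all
#'   sections.
#' @param per_region_density named numeric vector (names = region ids) of
#'   target fractional areas, each in `[0, 0.2]`.
#' @param n_sections number of sections.
#' @param plaque_radius_px inclusive integer radius range of plaque discs.
#' @param background_level,leak_fraction,plaque_intensity,noise_sd image
#'   formation parameters (arbitrary intensity units).
#' @param seed integer seed.
#' @return A list: `ch1`, `ch3`, `masks` (per-section lists of matrices),
#'   `labels`, `truth` (pooled region density table).
#' @export
gen_sections <- function(labels, per_region_density, n_sections = 10,
                         plaque_radius_px = c(2, 4), background_level = 50,
                         leak_fraction = 0.2, plaque_intensity = 100,
                         noise_sd = 1, seed = 1) {
  if (any(per_region_density < 0 | per_region_density > 0.2))
    stop_invalid("densities must lie in [0, 0.2]")
  region_ids <- as.integer(names(per_region_density))
  if (any(!region_ids %in% labels))
    stop_invalid("density given for a region absent from the labels")
  nr <- nrow(labels); nc <- ncol(labels)
  for (r in region_ids) {
    area <- sum(labels == r)
    if (per_region_density[[as.character(r)]] > 0 &&
        nrow(disc_offsets(plaque_radius_px[1])) > area)
      stop_invalid("density infeasible given region area for region ", r)
  }
  with_seed(seed, {
    bg_base <- background_level *
      (1 + 0.2 * outer(sin(seq_len(nr) / nr * pi), cos(seq_len(nc) / nc * pi)))
    ch1 <- ch3 <- masks <- vector("list", n_sections)
    for (s in seq_len(n_sections)) {
      mask <- matrix(FALSE, nr, nc)
      for (r in region_ids) {
        target <- per_region_density[[as.character(r)]]
        if (target <= 0) next
        in_region <- which(labels == r)
        area <- length(in_region)
        attempts <- 0
        while (sum(mask[in_region]) / area < target) {
          attempts <- attempts + 1
          if (attempts > 5000)
            stop_invalid("density infeasible given region area for region ", r)
          rad <- sample(seq(plaque_radius_px[1], plaque_radius_px[2]), 1)
          off <- disc_offsets(rad)
          ctr <- in_region[sample.int(area, 1)]
          ci <- (ctr - 1) %% nr + 1
          cj <- (ctr - 1) %/% nr + 1
          pi_ <- ci + off$di
          pj <- cj + off$dj
          if (any(pi_ < 1 | pi_ > nr | pj < 1 | pj > nc)) next
          pidx <- (pj - 1) * nr + pi_
          if (any(labels[pidx] != r)) next   # disc must stay inside region
          mask[pidx] <- TRUE
        }
      }
      c1 <- bg_base + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
      c3 <- leak_fraction * c1 + plaque_intensity * mask +
        matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
      ch1[[s]] <- c1
      ch3[[s]] <- pmax(c3, 0)
      masks[[s]] <- mask
    }
    # truth measured from the rendered masks (pooled over sections)
    all_ids <- sort(unique(labels[labels != 0]))
    truth <- do.call(rbind, lapply(all_ids, function(r) {
      rp <- sum(labels == r) * n_sections
      mp <- sum(vapply(masks, function(m) sum(m[labels == r]), numeric(1)))
      data.frame(region_id = r, masked_pixels = mp, region_pixels = rp,
                 fractional_area = mp / rp)
    }))
    list(ch1 = ch1, ch3 = ch3, masks = masks, labels = labels, truth = truth)
  })
}

#' Generate a Y-maze arm-entry sequence
#'
#' The agent never re-enters its current arm. At each step after the second
#' entry it completes a triad (enters the arm distinct from the last two)
#' with probability `p_alt`, otherwise returns to the other non-current arm.
#' `p_alt = 0.5` is a memoryless agent choosing uniformly between the two
#' available arms (chance-level alternation).
#'
#' @param p_alt triad-completion probability in `[0, 1]`.
#' @param n number of entries (>= 3).
#' @param seed integer seed.
#' @return Character vector of arm labels in `{"A","B","C"}`.
#' @export
gen_arm_entries <- function(p_alt, n, seed = 1) {
  check_scalar_number(p_alt, "p_alt", lower = 0, upper = 1)
  if (n < 3) stop_invalid("n must be at least 3")
  arms <- c("A", "B", "C")
  with_seed(seed, {
    out <- character(n)
    out[1] <- sample(arms, 1)
    out[2] <- sample(setdiff(arms, out[1]), 1)
    for (i in 3:n) {
      completing <- setdiff(arms, c(out[i - 2], out[i - 1]))
      returning <- out[i - 2]
      out[i] <- if (runif(1) < p_alt) completing else returning
    }
    out
  })
}

#' Generate a synthetic expression study with known effects
#'
#' Log2 expression is drawn gene-wise from the sex x genotype linear model
#' (0/1 coding, WT male reference) with Gaussian noise; TPM is recovered by
#' exponentiation and counts by rounding after per-sample depth factors. The
#' counts model is a rounded log-normal: a deliberate simplification, since
#' the downstream model operates on log2 values.
#'
#' @param design a \code{\link{gen_study_design}} table.
#' @param n_genes number of genes.
#' @param effects data.frame (`gene` index, `beta1`, `beta2`, `beta12`) of
#'   nonzero effects; genes absent from it are null. NULL = all null.
#' @param sigma residual SD on the log2 scale (> 0).
#' @param beta0 baseline log2 expression.
#' @param depth_sd log-normal SD of per-sample depth factors.
#' @param seed integer seed.
#' @return A list: `counts`, `tpm`, `log_expr` (all gene x sample),
#'   `design`, `truth` (per-gene effect table).
#' @export
gen_expression <- function(design, n_genes, effects = NULL, sigma = 0.5,
                           beta0 = 5, depth_sd = 0.1, seed = 1) {
  check_scalar_number(n_genes, "n_genes", lower = 1)
  check_scalar_number(sigma, "sigma", lower = 1e-12)
  truth <- data.frame(gene = paste0("gene", seq_len(n_genes)),
                      beta1 = 0, beta2 = 0, beta12 = 0)
  if (!is.null(effects)) {
    if (anyDuplicated(effects$gene))
      stop_invalid("effects must target disjoint gene subsets")
    truth[effects$gene, c("beta1", "beta2", "beta12")] <-
      effects[, c("beta1", "beta2", "beta12")]
  }
  X <- design_matrix_sex_genotype(design)
  B <- as.matrix(cbind(beta0, truth$beta1, truth$beta2, truth$beta12))
  with_seed(seed, {
    E <- B %*% t(X) +
      matrix(rnorm(n_genes * nrow(design), 0, sigma), n_genes)
    dimnames(E) <- list(truth$gene, design$subject_id)
    depth <- rlnorm(nrow(design), 0, depth_sd)
    tpm <- pmax(2^E - 1, 0)
    counts <- round(sweep(tpm, 2, depth, "*"))
    list(counts = counts, tpm = tpm, log_expr = E, design = design,
         truth = truth)
  })
}

#' Generate regional PET uptake with genotype/age effects
#'
#' Per subject x region uptake values with additive transgenic-genotype
#' shifts and a linear age trend plus Gaussian noise. The cerebellum (the
#' SUVR reference) carries no genotype or age effect.
#'
#' @param regions character vector of region names (cerebellum appended if
#'   absent).
#' @param n_per_cell subjects per genotype x age cell.
#' @param ages ages in months.
#' @param base_uptake baseline uptake (arbitrary units).
#' @param genotype_shift named (or scalar) additive TG shift per region.
#' @param age_slope named (or scalar) additive shift per month of age.
#' @param noise_sd Gaussian noise SD.
#' @param lateralized if TRUE, each non-cerebellum region is emitted as
#'   `_left` / `_right` halves sharing the bilateral mean.
#' @param seed integer seed.
#' @return A list: `uptake` (long data.frame: `subject`, `genotype`, `sex`,
#'   `age`, `region`, `value`), `truth` (per-region effect table).
#' @export
gen_pet <- function(regions = c("hippocampus", "thalamus", "cortex",
                                "striatum", "cerebellum"),
                    n_per_cell = 8, ages = c(4, 12), base_uptake = 100,
                    genotype_shift = 10, age_slope = 1, noise_sd = 3,
                    lateralized = FALSE, seed = 1) {
  if (!"cerebellum" %in% regions) regions <- c(regions, "cerebellum")
  expand_named <- function(x) {
    v <- if (length(x) == 1) stats::setNames(rep(x, length(regions)), regions)
         else x[regions]
    v["cerebellum"] <- 0
    v
  }
  gshift <- expand_named(genotype_shift)
  aslope <- expand_named(age_slope)
  subj <- expand.grid(replicate = seq_len(n_per_cell), age = ages,
                      genotype = c("TG", "WT"), stringsAsFactors = FALSE)
  subj$sex <- rep_len(c("F", "M"), nrow(subj))
  subj$subject <- sprintf("s%02d_%s_%dm", seq_len(nrow(subj)),
                          subj$genotype, subj$age)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(subj)), function(i) {
      mu <- base_uptake + gshift * (subj$genotype[i] == "TG") +
        aslope * (subj$age[i] - min(ages))
      val <- mu + rnorm(length(regions), 0, noise_sd)
      if (lateralized) {
        lat <- setdiff(regions, "cerebellum")
        data.frame(subject = subj$subject[i], genotype = subj$genotype[i],
                   sex = subj$sex[i], age = subj$age[i],
                   region = c(paste0(rep(lat, each = 2), c("_left", "_right")),
                              "cerebellum"),
                   value = c(rep(val[match(lat, regions)], each = 2) +
                               rnorm(2 * length(lat), 0, noise_sd / 2),
                             val[match("cerebellum", regions)]))
      } else {
        data.frame(subject = subj$subject[i], genotype = subj$genotype[i],
                   sex = subj$sex[i], age = subj$age[i],
                   region = regions, value = val)
      }
    })
    uptake <- do.call(rbind, rows)
    rownames(uptake) <- NULL
    list(uptake = uptake,
         truth = data.frame(region = regions, genotype_shift = unname(gshift),
                            age_slope = unname(aslope)))
  })
}

#' Generate a frailty assessment cohort sheet
#'
#' Each of the 26 traits is present with its stated prevalence; present
#' traits score 0.5 or 1 with equal probability (severities in {0, 0.5, 1}).
#'
#' @param n_subjects cohort size.
#' @param prevalence scalar or 26-vector of per-trait presence
#'   probabilities.
#' @param seed integer seed.
#' @return A data.frame: `subject_id`, the 26 trait columns
#'   (\code{\link{FRAILTY_TRAITS}}), `body_temp_c`.
#' @export
gen_frailty <- function(n_subjects, prevalence = 0.15, seed = 1) {
  prev <- rep_len(prevalence, 26)
  with_seed(seed, {
    scores <- sapply(seq_len(26), function(j) {
      present <- rbinom(n_subjects, 1, prev[j]) == 1
      ifelse(present, sample(c(0.5, 1), n_subjects, replace = TRUE), 0)
    })
    colnames(scores) <- FRAILTY_TRAITS
    out <- data.frame(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                      scores, check.names = FALSE)
    out$body_temp_c <- round(rnorm(n_subjects, 37, 0.3), 1)
    out
  })
}

#' Generate a home-cage wheel-running log
#'
#' Per-1-minute distances over `hours` hours: in each minute the animal runs
#' with a phase-dependent probability (higher in the dark/active phase) and,
#' if running, covers an exponentially distributed distance.
#'
#' @param hours session length (default 72).
#' @param p_run_dark,p_run_light per-minute running probabilities.
#' @param mean_distance_m mean per-minute distance when running.
#' @param lights_on_h,lights_off_h light-phase clock hours.
#' @param start_clock_h clock hour of the session start.
#' @param seed integer seed.
#' @return A data.frame: `minute`, `phase` (light/dark), `distance_m`.
#' @export
gen_wheel <- function(hours = 72, p_run_dark = 0.6, p_run_light = 0.15,
                      mean_distance_m = 5, lights_on_h = 7, lights_off_h = 19,
                      start_clock_h = 12, seed = 1) {
  n_min <- hours * 60
  clock_h <- (start_clock_h + (seq_len(n_min) - 1) / 60) %% 24
  light <- clock_h >= lights_on_h & clock_h < lights_off_h
  with_seed(seed, {
    p <- ifelse(light, p_run_light, p_run_dark)
    running <- rbinom(n_min, 1, p) == 1
    d <- numeric(n_min)
    d[running] <- rexp(sum(running), 1 / mean_distance_m)
    data.frame(minute = seq_len(n_min),
               phase = ifelse(light, "light", "dark"), distance_m = d)
  })
}

#' Generate open-field samples
#'
#' Per-second samples over the session: locomotion distance, rearing counts,
#' and center-zone occupancy.
#'
#' @param duration_min session length (default 60).
#' @param rate_cm_s mean locomotion speed.
#' @param vertical_rate_s rearing events per second.
#' @param p_center probability of being in the center zone at a sample.
#' @param seed integer seed.
#' @return A data.frame: `t` (s), `distance_delta` (cm), `vertical_count`,
#'   `in_center`.
#' @export
gen_openfield <- function(duration_min = 60, rate_cm_s = 10,
                          vertical_rate_s = 0.1, p_center = 0.2, seed = 1) {
  n <- duration_min * 60
  with_seed(seed, {
    data.frame(t = seq_len(n) - 1,
               distance_delta = rexp(n, 1 / rate_cm_s),
               vertical_count = rpois(n, vertical_rate_s),
               in_center = runif(n) < p_center)
  })
}

#' Generate rotarod trials
#'
#' @param n_subjects cohort size.
#' @param n_trials trials per subject (default 3).
#' @param mean_latency_s,sd_latency_s latency distribution (capped at 300 s).
#' @param p_fall_before probability a trial ends before acceleration starts.
#' @param seed integer seed.
#' @return A data.frame: `subject_id`, `trial`, `latency_s`,
#'   `fell_before_acceleration`.
#' @export
gen_rotarod <- function(n_subjects, n_trials = 3, mean_latency_s = 120,
                        sd_latency_s = 40, p_fall_before = 0.05, seed = 1) {
  with_seed(seed, {
    n <- n_subjects * n_trials
    data.frame(
      subject_id = rep(sprintf("s%03d", seq_len(n_subjects)), each = n_trials),
      trial = rep(seq_len(n_trials), n_subjects),
      latency_s = pmin(pmax(rnorm(n, mean_latency_s, sd_latency_s), 1), 300),
      fell_before_acceleration = runif(n) < p_fall_before
    )
  })
}
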