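# Synthetic two-region session generator.
#
# Plants a known low-rank, theta-gated communication structure: Poisson spike
# counts in CA1 and PFC driven by shared AR(1) latents whose gain switches
# with the theta state, plus region-private latents; LFP with delta/theta/
# ripple band structure and a controllable inter-region theta phase lag; and
# W-track behavior with the four trajectory types. Every downstream analysis
# stage can be validated against the returned ground truth.

#' Configuration for the synthetic session generator
#'
#' Defaults describe the targeted recording regime: eight 900 s run epochs in
#' one day, 50 ms count bins, 1.5 kHz LFP with theta (8 Hz), ripple (180 Hz)
#' and delta (2 Hz) carriers, and a rank-3 shared latent whose gain is
#' 2.0 in theta-high bins and 0.5 in theta-low bins. Firing-rate bases are
#' drawn log-uniformly between 2 and 10 Hz; unit loadings are Gaussian with
#' sd 0.2 on the log-rate scale (rate excursions stay within roughly e^1).
#'
#' @param n_ca1,n_pfc number of CA1 / PFC units.
#' @param n_epochs number of run epochs.
#' @param epoch_duration_s seconds per epoch.
#' @param trials_per_epoch trials per epoch (trajectories cycle C-to-L,
#'   L-to-C, C-to-R, R-to-C).
#' @param bin_s latent / count bin width in seconds.
#' @param comm_rank planted shared-latent dimension.
#' @param comm_gain_high,comm_gain_low shared-latent gain in theta-high vs
#'   theta-low bins.
#' @param private_rank per-region private latent dimension.
#' @param base_rate_hz length-2 range of per-unit mean rates (Hz).
#' @param loading_sd sd of unit loadings on the log-rate scale.
#' @param lfp_fs_hz LFP sample rate (Hz); must exceed twice \code{ripple_hz}.
#' @param theta_hz,ripple_hz,delta_hz carrier frequencies (Hz).
#' @param theta_amp,ripple_amp,delta_amp,noise_amp carrier / pink-noise
#'   amplitudes (arbitrary units).
#' @param phase_lag_rad planted CA1-to-PFC theta phase offset (radians; PFC
#'   lags CA1 by this angle).
#' @param behavior_coupling list of couplings, each
#'   \code{list(var = <behavior column>, latent = <index>, strength = <sd units>)};
#'   by default linearized position loads shared latent 1 with strength 2.5.
#' @param behavior_target \code{"shared"} (default: couplings enter the shared
#'   latents, so behavior is reciprocated across regions) or \code{"private"}
#'   (negative control: behavior drives the two regions' communication axes in
#'   antiphase, i.e. unreciprocated motion). For the antiphase control keep
#'   the coupling strength below the effective shared-latent gain (e.g. 1.5
#'   against the default gains): a dominant antiphase signal would itself
#'   become the maximally correlated direction, flipping one region's
#'   canonical sign and re-labelling the planted signal as reciprocated.
#' @param move_frac fraction of each trial spent traversing (the rest is
#'   split between holds at the departure and arrival wells); this sets the
#'   expected theta-gate high fraction.
#' @param vte_fraction fraction of outbound trials given an elevated IdPhi
#'   bump in the choice zone.
#' @param choice_zone linearized-position interval treated as the choice zone.
#' @param accuracy_schedule per-epoch probability of a correct trial; default
#'   ramps linearly from 0.55 to 0.95 over the epochs.
#' @param speed_threshold_cms speed (cm/s) above which the animal counts as
#'   moving (theta-high).
#' @param ripple_rate_hz Poisson rate of 100 ms ripple bursts during stillness.
#' @param behavior_fs behavior sampling rate (samples/s).
#' @param path_length_cm physical length of one trajectory (cm).
#' @param seed master seed; all generator randomness flows from it through
#'   named substreams.
#' @return A validated [SynthConfig-class].
#' @export
synthConfig <- function(n_ca1 = 30, n_pfc = 20, n_epochs = 8,
                        epoch_duration_s = 900, trials_per_epoch = 40,
                        bin_s = 0.05, comm_rank = 3, comm_gain_high = 2,
                        comm_gain_low = 0.5, private_rank = 3,
                        base_rate_hz = c(2, 10), loading_sd = 0.2,
                        lfp_fs_hz = 1500, theta_hz = 8, ripple_hz = 180,
                        delta_hz = 2, theta_amp = 1, ripple_amp = 1.5,
                        delta_amp = 0.5, noise_amp = 0.5,
                        phase_lag_rad = pi / 4,
                        behavior_coupling = list(
                          list(var = "lin_pos", latent = 1, strength = 2.5)),
                        behavior_target = c("shared", "private"),
                        move_frac = 0.6, vte_fraction = 0.25,
                        choice_zone = c(0.45, 0.65),
                        accuracy_schedule = NULL,
                        speed_threshold_cms = 5, ripple_rate_hz = 0.1,
                        behavior_fs = 30, path_length_cm = 170, seed = 1L) {
  behavior_target <- match.arg(behavior_target)
  if (is.null(accuracy_schedule))
    accuracy_schedule <- seq(0.55, 0.95, length.out = n_epochs)
  params <- list(
    n_ca1 = n_ca1, n_pfc = n_pfc, n_epochs = n_epochs,
    epoch_duration_s = epoch_duration_s, trials_per_epoch = trials_per_epoch,
    bin_s = bin_s, comm_rank = comm_rank, comm_gain_high = comm_gain_high,
    comm_gain_low = comm_gain_low, private_rank = private_rank,
    base_rate_hz = base_rate_hz, loading_sd = loading_sd,
    lfp_fs_hz = lfp_fs_hz, theta_hz = theta_hz, ripple_hz = ripple_hz,
    delta_hz = delta_hz, theta_amp = theta_amp, ripple_amp = ripple_amp,
    delta_amp = delta_amp, noise_amp = noise_amp,
    phase_lag_rad = phase_lag_rad, behavior_coupling = behavior_coupling,
    behavior_target = behavior_target, move_frac = move_frac,
    vte_fraction = vte_fraction, choice_zone = choice_zone,
    accuracy_schedule = accuracy_schedule,
    speed_threshold_cms = speed_threshold_cms,
    ripple_rate_hz = ripple_rate_hz, behavior_fs = behavior_fs,
    path_length_cm = path_length_cm, seed = as.integer(seed))
  new("SynthConfig", params = params)
}

#' Parameters of a SynthConfig
#' @param cfg a [SynthConfig-class].
#' @return named list of parameters.
#' @export
configParams <- function(cfg) cfg@params

TRAJ_TYPES <- c("C-to-L", "L-to-C", "C-to-R", "R-to-C")

# W-track geometry: arms at x = 10 (L), 40 (C), 70 (R); wells at y = 0,
# top rail at y = 70. Linearized position 0 = center well, 1 = side well.
wtrackXY <- function(lin, traj) {
  side_x <- if (traj %in% c("C-to-L", "L-to-C")) 10 else 70
  p <- if (traj %in% c("C-to-L", "C-to-R")) lin else 1 - lin  # 0=center well
  x <- numeric(length(p)); y <- numeric(length(p))
  seg1 <- p <= 0.5                       # center arm: up
  y[seg1] <- p[seg1] / 0.5 * 70; x[seg1] <- 40
  seg2 <- p > 0.5 & p <= 0.75            # top rail: across
  frac <- (p[seg2] - 0.5) / 0.25
  x[seg2] <- 40 + frac * (side_x - 40); y[seg2] <- 70
  seg3 <- p > 0.75                       # side arm: down
  x[seg3] <- side_x; y[seg3] <- 70 - (p[seg3] - 0.75) / 0.25 * 70
  cbind(x = x, y = y)
}

#' Generate W-track behavior
#'
#' Produces a behavior table sampled at \code{behavior_fs} samples/s. Trials
#' cycle through the four trajectory types; within a trial the animal holds at
#' the departure well, traverses with a raised-cosine linearized-position
#' profile (0 at the center well, 1 at the side wells; rising for outbound,
#' falling for inbound), then holds at the arrival well. Velocity and
#' acceleration are smoothed derivatives of 2-D position; IdPhi is planted
#' with an elevated choice-zone bump on a random subset of outbound trials;
#' correct/error labels follow the per-epoch accuracy schedule.
#'
#' @param cfg a [SynthConfig-class].
#' @param seed integer seed (defaults to the config seed).
#' @return data.frame with columns \code{time, x, y, lin_pos, velocity,
#'   acceleration, idphi, traj_type, direction, turn, turn_sign, dir_sign,
#'   correct, epoch, trial} (the \code{*_sign} columns are signed numeric
#'   encodings of turn and direction, convenient as coupling variables).
#' @export
generateBehavior <- function(cfg, seed = configParams(cfg)$seed) {
  p <- configParams(cfg)
  validObject(cfg)
  fs <- p$behavior_fs
  trial_dur <- p$epoch_duration_s / p$trials_per_epoch
  if (trial_dur <= 0) stop("non-positive trial duration")
  n_trials <- p$n_epochs * p$trials_per_epoch
  hold <- (1 - p$move_frac) / 2

  withSubstream(seed, "behavior", {
    traj <- rep(TRAJ_TYPES, length.out = n_trials)
    outbound <- traj %in% c("C-to-L", "C-to-R")
    vte <- logical(n_trials)
    out_idx <- which(outbound)
    n_vte <- round(p$vte_fraction * length(out_idx))
    if (n_vte > 0) vte[sample(out_idx, n_vte)] <- TRUE
    epoch_of <- rep(seq_len(p$n_epochs), each = p$trials_per_epoch)
    correct <- rbinom(n_trials, 1, p$accuracy_schedule[epoch_of])

    rows <- vector("list", n_trials)
    n_per <- round(trial_dur * fs)
    s <- (seq_len(n_per) - 1) / n_per          # within-trial phase [0,1)
    prog <- pmin(pmax((s - hold) / p$move_frac, 0), 1)
    ramp <- (1 - cos(pi * prog)) / 2           # raised-cosine traverse
    for (i in seq_len(n_trials)) {
      tr <- traj[i]
      out_i <- outbound[i]
      lin <- if (out_i) ramp else 1 - ramp
      t0 <- (i - 1) * trial_dur
      xy <- wtrackXY(lin, tr)
      idphi <- abs(rnorm(n_per, 0, 0.2))
      if (vte[i]) {
        cz <- lin >= p$choice_zone[1] & lin <= p$choice_zone[2]
        idphi[cz] <- idphi[cz] + 3
      }
      rows[[i]] <- data.frame(
        time = t0 + (seq_len(n_per) - 1) / fs,
        x = xy[, "x"], y = xy[, "y"], lin_pos = lin, idphi = idphi,
        traj_type = tr, direction = if (out_i) "out" else "in",
        turn = if (tr %in% c("C-to-L", "L-to-C")) "L" else "R",
        correct = correct[i], epoch = epoch_of[i], trial = i)
    }
    beh <- do.call(rbind, rows)
    # speed from smoothed 2-D displacement; acceleration from speed
    dx <- c(0, diff(beh$x)); dy <- c(0, diff(beh$y))
    speed <- boxcarSmooth(sqrt(dx^2 + dy^2) * fs, round(0.5 * fs))
    beh$velocity <- speed
    beh$acceleration <- boxcarSmooth(c(0, diff(speed)) * fs, round(0.5 * fs))
    # signed numeric encodings, usable as coupling variables
    beh$turn_sign <- ifelse(beh$turn == "R", 1, -1)
    beh$dir_sign <- ifelse(beh$direction == "out", 1, -1)
    beh <- beh[, c("time", "x", "y", "lin_pos", "velocity", "acceleration",
                   "idphi", "traj_type", "direction", "turn", "turn_sign",
                   "dir_sign", "correct", "epoch", "trial")]
    rownames(beh) <- NULL
    beh
  })
}

# Per-bin movement state from the behavior table: the theta gate, plus a
# continuous amplitude drive (with realistic bin-to-bin jitter so its
# quantiles are well defined for threshold-triggered windowing).
movementGate <- function(cfg, behavior, seed = configParams(cfg)$seed) {
  p <- configParams(cfg)
  span <- p$n_epochs * p$epoch_duration_s
  nbin <- floor(span / p$bin_s)
  bin_start <- (seq_len(nbin) - 1) * p$bin_s
  sp <- interpTo(behavior$time, behavior$velocity, bin_start + p$bin_s / 2)
  moving <- as.numeric(sp > p$speed_threshold_cms)
  drive <- 0.2 + 0.8 * boxcarSmooth(moving, max(1, round(0.5 / p$bin_s)))
  drive <- pmax(drive + withSubstream(seed, "gate", rnorm(nbin, 0, 0.05)), 0)
  list(gate = ifelse(moving > 0.5, "high", "low"), thetaDrive = drive,
       bin_start = bin_start)
}

#' Generate two-region LFP traces and the theta-state gate
#'
#' Each region's trace is an amplitude-modulated theta carrier (amplitude high
#' during movement bouts, which defines the gate), ripple bursts during
#' stillness, a delta carrier, and 1/f noise. The PFC theta component lags the
#' CA1 component by \code{phase_lag_rad}.
#'
#' @param cfg a [SynthConfig-class].
#' @param behavior behavior table from [generateBehavior()].
#' @param seed integer seed.
#' @return list with elements \code{lfp} (named list of [LfpTrace-class]),
#'   \code{gate} (per-bin \code{"high"}/\code{"low"}), \code{thetaDrive}
#'   (per-bin continuous theta amplitude drive) and \code{bin_start}.
#' @export
generateLfp <- function(cfg, behavior, seed = configParams(cfg)$seed) {
  p <- configParams(cfg)
  if (p$lfp_fs_hz < 2 * p$ripple_hz)
    stop("lfp_fs_hz below twice the ripple carrier: aliasing")
  span <- p$n_epochs * p$epoch_duration_s
  if (max(behavior$time) < span - 2 / p$behavior_fs - 1)
    stop("behavior does not span the configured duration")
  fs <- p$lfp_fs_hz
  n <- round(span * fs)
  tt <- (seq_len(n) - 1) / fs
  gateinfo <- movementGate(cfg, behavior)

  withSubstream(seed, "lfp", {
    sp <- interpTo(behavior$time, behavior$velocity, tt)
    moving <- as.numeric(sp > p$speed_threshold_cms)
    env <- 0.2 + 0.8 * boxcarSmooth(moving, round(0.5 * fs))
    phi0 <- runif(1, 0, 2 * pi)
    theta1 <- p$theta_amp * env * sin(2 * pi * p$theta_hz * tt + phi0)
    theta2 <- p$theta_amp * env *
      sin(2 * pi * p$theta_hz * tt + phi0 - p$phase_lag_rad)

    # ripple bursts: 100 ms Hann-windowed packets during stillness
    ripple <- numeric(n)
    if (p$ripple_amp > 0) {
      still <- which(moving == 0)
      if (length(still)) {
        n_ev <- rpois(1, p$ripple_rate_hz * length(still) / fs)
        if (n_ev > 0) {
          starts <- sort(sample(still, min(n_ev, length(still))))
          w <- round(0.1 * fs)
          hann <- 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))
          for (s0 in starts) {
            idx <- s0:min(s0 + w - 1, n)
            ripple[idx] <- ripple[idx] + p$ripple_amp * hann[seq_along(idx)] *
              sin(2 * pi * p$ripple_hz * tt[idx] + runif(1, 0, 2 * pi))
          }
        }
      }
    }
    delta1 <- p$delta_amp * sin(2 * pi * p$delta_hz * tt + runif(1, 0, 2 * pi))
    delta2 <- p$delta_amp * sin(2 * pi * p$delta_hz * tt + runif(1, 0, 2 * pi))
    noise1 <- if (p$noise_amp > 0) p$noise_amp * pinkNoise(n) else numeric(n)
    noise2 <- if (p$noise_amp > 0) p$noise_amp * pinkNoise(n) else numeric(n)

    list(lfp = list(
           CA1 = LfpTrace(theta1 + ripple + delta1 + noise1, fs, "CA1"),
           PFC = LfpTrace(theta2 + 0.3 * ripple + delta2 + noise2, fs, "PFC")),
         gate = gateinfo$gate, thetaDrive = gateinfo$thetaDrive,
         bin_start = gateinfo$bin_start)
  })
}

#' Generate the spiking ensembles and ground truth
#'
#' Per-bin log-rates are \code{base + L [g(gate) z_shared ; z_private]} plus
#' any behavior couplings; spike counts are Poisson draws, and spike times are
#' placed uniformly within their bin. Shared latents load on both regions;
#' private latents load on one. With \code{behavior_target = "shared"}
#' (default) behavior enters the shared latents, so it is reciprocated across
#' regions; with \code{"private"} it drives the two regions' shared-loading
#' columns in antiphase (unreciprocated motion), a negative control.
#'
#' @param cfg a [SynthConfig-class].
#' @param behavior behavior table from [generateBehavior()].
#' @param gate per-bin \code{"high"}/\code{"low"} theta state, aligned to the
#'   bin grid.
#' @param seed integer seed.
#' @return list with elements \code{spikes} ([SpikeSet-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @export
generateEnsembles <- function(cfg, behavior, gate,
                              seed = configParams(cfg)$seed) {
  p <- configParams(cfg)
  if (p$comm_rank > min(p$n_ca1, p$n_pfc))
    stop("comm_rank exceeds min(n_ca1, n_pfc)")
  nbin <- length(gate)
  bin_start <- (seq_len(nbin) - 1) * p$bin_s
  k <- p$comm_rank; kp <- p$private_rank

  withSubstream(seed, "ensembles", {
    z <- ar1Series(k, nbin)
    zc <- if (kp > 0) ar1Series(kp, nbin) else matrix(0, 0, nbin)
    zp <- if (kp > 0) ar1Series(kp, nbin) else matrix(0, 0, nbin)

    Lc <- matrix(rnorm(p$n_ca1 * (k + kp), 0, p$loading_sd), p$n_ca1)
    Lp <- matrix(rnorm(p$n_pfc * (k + kp), 0, p$loading_sd), p$n_pfc)
    base_c <- runif(p$n_ca1, log(p$base_rate_hz[1]), log(p$base_rate_hz[2]))
    base_p <- runif(p$n_pfc, log(p$base_rate_hz[1]), log(p$base_rate_hz[2]))

    # behavior couplings: separate un-gated log-rate terms routed through the
    # shared loading columns (same sign in both regions = reciprocated;
    # antiphase under the private-target negative control)
    coup_used <- FALSE
    coup_c <- matrix(0, p$n_ca1, nbin); coup_p <- matrix(0, p$n_pfc, nbin)
    for (bc in p$behavior_coupling) {
      bv <- interpTo(behavior$time, as.numeric(behavior[[bc$var]]),
                     bin_start + p$bin_s / 2)
      bv <- as.numeric(scale(bv))
      sgn <- if (p$behavior_target == "shared") 1 else -1
      coup_used <- TRUE
      coup_c <- coup_c + Lc[, bc$latent] %o% (bc$strength * bv)
      coup_p <- coup_p + sgn * Lp[, bc$latent] %o% (bc$strength * bv)
    }

    g <- ifelse(gate == "high", p$comm_gain_high, p$comm_gain_low)
    zg <- z * rep(g, each = k)
    lr_c <- base_c + Lc %*% rbind(zg, zc)
    lr_p <- base_p + Lp %*% rbind(zg, zp)
    if (coup_used) { lr_c <- lr_c + coup_c; lr_p <- lr_p + coup_p }
    lam_c <- exp(pmin(lr_c, log(100))) * p$bin_s
    lam_p <- exp(pmin(lr_p, log(100))) * p$bin_s

    drawUnit <- function(lam_row) {
      cnt <- rpois(nbin, lam_row)
      nz <- which(cnt > 0)
      if (!length(nz)) return(numeric(0))
      sort(rep(bin_start[nz], cnt[nz]) + runif(sum(cnt[nz])) * p$bin_s)
    }
    times <- c(lapply(seq_len(p$n_ca1), function(i) drawUnit(lam_c[i, ])),
               lapply(seq_len(p$n_pfc), function(i) drawUnit(lam_p[i, ])))
    ids <- c(sprintf("ca1_%02d", seq_len(p$n_ca1)),
             sprintf("pfc_%02d", seq_len(p$n_pfc)))
    region <- c(rep("CA1", p$n_ca1), rep("PFC", p$n_pfc))

    truth <- new("GroundTruth", sharedLatents = z, gate = gate,
                 thetaDrive = numeric(0), loadingsCa1 = Lc, loadingsPfc = Lp,
                 privateCa1 = zc, privatePfc = zp,
                 behaviorLoadings = p$behavior_coupling)
    list(spikes = SpikeSet(times, ids, region), truth = truth)
  })
}

#' Generate a complete synthetic session
#'
#' Composition of [generateBehavior()], [generateLfp()] and
#' [generateEnsembles()]; deterministic under (config, seed).
#'
#' @param cfg a [SynthConfig-class].
#' @param seed integer master seed (defaults to the config seed).
#' @param lfp logical; set \code{FALSE} to skip LFP synthesis (the gate is
#'   then computed directly from behavior, which is how the LFP generator
#'   derives it too).
#' @return A [SyntheticSession-class].
#' @export
generateSession <- function(cfg, seed = configParams(cfg)$seed, lfp = TRUE) {
  validObject(cfg)
  behavior <- generateBehavior(cfg, seed)
  if (lfp) {
    lf <- generateLfp(cfg, behavior, seed)
    gate <- lf$gate; drive <- lf$thetaDrive; traces <- lf$lfp
  } else {
    gi <- movementGate(cfg, behavior)
    gate <- gi$gate; drive <- gi$thetaDrive
    traces <- list()
  }
  ens <- generateEnsembles(cfg, behavior, gate, seed)
  truth <- ens$truth
  truth@thetaDrive <- drive
  new("SyntheticSession", spikes = ens$spikes, lfp = traces,
      behavior = behavior, truth = truth, config = cfg)
}
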