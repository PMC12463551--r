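# Synthetic session generator: behavior, LFP, ensembles, composition.

test_that("behavior table has the configured trial structure and is deterministic", {
  cfg <- synthConfig(n_epochs = 8, epoch_duration_s = 40, trials_per_epoch = 4,
                     seed = 5)
  beh <- generateBehavior(cfg)
  expect_equal(max(beh$trial), 32)
  expect_equal(sort(unique(beh$epoch)), 1:8)
  expect_equal(unname(table(beh$epoch)), rep(nrow(beh) / 8, 8),
               ignore_attr = TRUE)
  expect_setequal(unique(beh$traj_type),
                  c("C-to-L", "L-to-C", "C-to-R", "R-to-C"))
  # identical (cfg, seed) -> identical tables
  expect_identical(beh, generateBehavior(cfg))
  # different seed -> different VTE / correct draws
  beh2 <- generateBehavior(cfg, seed = 6)
  expect_false(identical(beh$correct, beh2$correct))
})

test_that("outbound linearized position rises 0 to 1; inbound falls", {
  cfg <- synthConfig(n_epochs = 1, epoch_duration_s = 60, trials_per_epoch = 4,
                     seed = 1)
  beh <- generateBehavior(cfg)
  for (tr in unique(beh$trial)) {
    sub <- beh[beh$trial == tr, ]
    d <- diff(sub$lin_pos)
    if (sub$direction[1] == "out") {
      expect_true(all(d >= -1e-9))
      expect_equal(range(sub$lin_pos), c(0, 1), tolerance = 1e-6)
    } else {
      expect_true(all(d <= 1e-9))
    }
  }
  expect_true(all(beh$velocity >= 0))
})

test_that("planted IdPhi is elevated in the choice zone of VTE trials only", {
  cfg <- synthConfig(n_epochs = 2, epoch_duration_s = 100,
                     trials_per_epoch = 10, vte_fraction = 0.5, seed = 3)
  beh <- generateBehavior(cfg)
  cz <- beh$lin_pos >= 0.45 & beh$lin_pos <= 0.65 & beh$direction == "out"
  by_trial <- tapply(beh$idphi[cz], beh$trial[cz], mean)
  # bimodal: VTE trials carry the +3 bump
  expect_gt(sum(by_trial > 1.5), 0)
  expect_gt(sum(by_trial < 1.5), 0)
  expect_gt(min(by_trial[by_trial > 1.5]) - max(by_trial[by_trial < 1.5]), 1)
})

test_that("LFP carries the planted inter-region theta phase lag", {
  cfg <- synthConfig(n_epochs = 1, epoch_duration_s = 60, noise_amp = 0,
                     ripple_amp = 0, delta_amp = 0, phase_lag_rad = pi / 2,
                     seed = 2)
  beh <- generateBehavior(cfg)
  lf <- generateLfp(cfg, beh)
  th1 <- bandpassFilter(lf$lfp$CA1, c(6, 12))
  th2 <- bandpassFilter(lf$lfp$PFC, c(6, 12))
  ph <- Arg(mean(exp(1i * Arg(neurocomm:::analyticSignal(th1) *
                                Conj(neurocomm:::analyticSignal(th2))))))
  expect_equal(ph, pi / 2, tolerance = 0.05)
})

test_that("theta envelope separates gate states and zero carriers leave noise", {
  ss <- lfpSession()
  env <- lfpBandEnvelope(ss@lfp$CA1, c(6, 12), "theta")
  gate <- ss@truth@gate
  bin_of <- floor(seq_along(env@envelope) / (1500 * 0.05)) + 1
  e_bin <- tapply(env@envelope, pmin(bin_of, length(gate)), mean)
  e_bin <- e_bin[seq_along(gate)]
  expect_gt(mean(e_bin[gate == "high"]), mean(e_bin[gate == "low"]))
  expect_gt(cor(e_bin, as.numeric(gate == "high")), 0.5)

  cfg0 <- synthConfig(n_epochs = 1, epoch_duration_s = 20, theta_amp = 0,
                      ripple_amp = 0, delta_amp = 0, noise_amp = 0, seed = 1)
  lf0 <- generateLfp(cfg0, generateBehavior(cfg0))
  expect_equal(max(abs(lf0$lfp$CA1@samples)), 0)
})

test_that("LFP generation rejects aliasing configurations", {
  expect_error(synthConfig(lfp_fs_hz = 300), "aliasing")
})

test_that("ensembles have the configured layout and Poisson means", {
  ss <- smallSession()
  expect_length(ss@spikes@times, 50)
  expect_equal(sum(regionLabels(ss@spikes) == "CA1"), 30)
  expect_equal(sum(regionLabels(ss@spikes) == "PFC"), 20)
  expect_error(
    generateEnsembles(synthConfig(n_ca1 = 3, n_pfc = 2, comm_rank = 3),
                      ss@behavior, ss@truth@gate), "comm_rank")

  # flat 0.05 Hz unit: mean count/bin = rate * bin width
  cfg <- synthConfig(n_ca1 = 5, n_pfc = 5, n_epochs = 2,
                     epoch_duration_s = 500, base_rate_hz = c(0.05, 0.05),
                     loading_sd = 0, behavior_coupling = list(), seed = 8)
  beh <- generateBehavior(cfg)
  gi <- neurocomm:::movementGate(cfg, beh)
  ens <- generateEnsembles(cfg, beh, gi$gate)
  counts <- binSpikes(ens$spikes, 0.05, c(0, 1000))
  expect_equal(mean(countsMatrix(counts)), 0.0025, tolerance = 0.15)
})

test_that("zero communication gain leaves regions uncorrelated", {
  cfg <- synthConfig(n_epochs = 2, epoch_duration_s = 500,
                     comm_gain_high = 0, comm_gain_low = 0,
                     behavior_coupling = list(), seed = 9)
  ss <- generateSession(cfg, lfp = FALSE)  # T = 20000 bins
  counts <- sessionCounts(ss)
  m <- countsMatrix(counts)
  region <- regionLabels(counts)
  cc <- cor(m[, region == "CA1"], m[, region == "PFC"])
  expect_lt(max(abs(cc)), 0.05)
})

test_that("sessions are deterministic, seed-sensitive, and internally aligned", {
  cfg <- synthConfig(n_epochs = 1, epoch_duration_s = 50, trials_per_epoch = 3,
                     seed = 4)
  s1 <- generateSession(cfg)
  s2 <- generateSession(cfg)
  expect_identical(s1@spikes@times, s2@spikes@times)
  expect_identical(s1@lfp$CA1@samples, s2@lfp$CA1@samples)
  s3 <- generateSession(cfg, seed = 99)
  expect_false(identical(s1@spikes@times, s3@spikes@times))
  expect_identical(configParams(s1@config), configParams(s3@config))
  # spikes, lfp, behavior span the same interval
  span <- sessionSpan(s1)
  expect_true(all(unlist(s1@spikes@times) >= span[1] &
                    unlist(s1@spikes@times) <= span[2]))
  expect_equal(length(s1@lfp$CA1@samples) / 1500, span[2])
  expect_equal(max(s1@behavior$time), span[2] - 1 / 30, tolerance = 1e-6)
  # gate high fraction tracks the configured movement fraction
  expect_equal(mean(s1@truth@gate == "high"),
               configParams(cfg)$move_frac, tolerance = 0.1)
})
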