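# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small (reduced sample rates, few trials, few
# permutations) so the whole suite runs on one CPU in minutes.

# A tiny hand-built trial table with known conditions.
tiny_trials <- function(n = 24, seed = 1) {
  set.seed(seed)
  trial_table(
    subject_id = "t01",
    speed = rep(c("fast", "slow"), length.out = n),
    direction = rep(c("down", "right", "up", "left"), length.out = n),
    perturbation = rep(c("unperturbed", "unperturbed", "towards", "away"),
                       length.out = n),
    rt_seconds = 0.8 + 0.1 * rnorm(n),
    speed_error = round(runif(n, -0.3, 0.3), 3),
    perturb_force = 5, perturb_angle = 1
  )
}

# One subject's worth of epoch-locked spectrograms from the full synthetic
# LFP + preprocessing chain, for cluster/encoding tests.
# Returns list(spect = list of per-channel epoch lists, states, trials).
synth_subject_spect <- function(seed, n_trials = 40, fs = 200,
                                epoch_layout = c(go_cue = 1.0),
                                channels = data.frame(
                                  channel_id = c("c1", "c2"),
                                  region = "A", network = "DAN"),
                                targets = list(), freqs = cwt_freqs(4, 80, 4)) {
  seeds <- statereach:::derive_seeds(seed, 2)
  gs <- generator_spec(n_trials = n_trials, seed = seeds[1])
  sim <- simulate_session(gs)
  tr <- evolve_states(sim$trials, gs$true_params)
  spec <- lfp_spec(channels, sample_rate = fs, epoch_layout = epoch_layout,
                   encoding_targets = targets)
  rec <- synthesize_lfp(sim$trials,
                        states = list(error = tr$x_se_z,
                                      perturbed = tr$x_p_z),
                        spec = spec, seed = seeds[2])
  spects <- lapply(channels$channel_id, function(ch)
    preprocess_channel(rec, ch, freqs = freqs,
                       trials_keep = which(sim$trials$completed)))
  names(spects) <- channels$channel_id
  list(spect = spects, states = tr, trials = sim$trials, rec = rec,
       freqs = freqs)
}

# Trial power series with a planted state coupling, for encoding/
# connectivity tests: series = gain * state + noise.
planted_series <- function(state, gain, n_channels = 2, noise_sd = 1,
                           seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_channels), function(i)
    gain * state + rnorm(length(state), 0, noise_sd))
}
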