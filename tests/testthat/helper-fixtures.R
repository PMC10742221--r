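# Shared fixtures, built in code at test time.

fixture_montage <- function() standard_montage_32()

# a short but realistic single recording (31 s rest + task + rest)
fixture_recording <- function(task_s = 15, snr_db = 0, seed = 9,
                              group = "expert", bad_channel_prob = 0) {
  spec <- simulation_spec(n_experts = 1, n_novices = 1, trials_per_subject = 1,
                          task_s = task_s, rest_s = 5, pre_trigger_s = 31,
                          snr_db = snr_db, bad_channel_prob = bad_channel_prob,
                          seed = seed)
  simulate_subject(spec, group, subject_id = 1, trial_id = 1)
}

# a small fully-preprocessed two-group cohort of task-onset epochs
fixture_epoch_sets <- function(n_per_group = 4, trials = 2, task_s = 15,
                               snr_db = 10, seed = 101,
                               expert_weights = c(1, 0, 0, 0, 0, 0),
                               novice_weights = c(0, 1, 0, 0, 0, 0)) {
  mon <- fixture_montage()
  spec <- simulation_spec(n_experts = n_per_group, n_novices = n_per_group,
                          trials_per_subject = trials, task_s = task_s,
                          rest_s = 5, pre_trigger_s = 31, snr_db = snr_db,
                          expert_weights = expert_weights,
                          novice_weights = novice_weights, seed = seed)
  cfg <- preprocess_config()
  sets <- list()
  for (g in c("expert", "novice")) {
    for (s in seq_len(n_per_group)) {
      for (tr in seq_len(trials)) {
        rec <- simulate_subject(spec, g,
                                subject_id = s + ifelse(g == "expert", 0L, 100L),
                                trial_id = tr)
        sets[[length(sets) + 1L]] <- preprocess_recording(
          rec, mon, cfg, subject = paste0(g, s), trial = tr, group = g)
      }
    }
  }
  sets
}

# flatten epoch sets into (epochs, labels)
flatten_epochs <- function(sets) {
  eps <- list(); labels <- character()
  for (es in sets) {
    for (i in seq_along(es$epochs)) {
      eps[[length(eps) + 1L]] <- es$epochs[[i]]
      labels <- c(labels, es$info$group[i])
    }
  }
  list(epochs = eps, labels = labels)
}

# independent dense biharmonic interpolation oracle (constant-augmented
# Green's system), written without the package's operator code
biharm_oracle <- function(coords, values, targets) {
  G <- function(r) ifelse(r == 0, 0, r^2 * (log(r) - 1))
  k <- nrow(coords)
  A <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    A[i, j] <- G(sqrt(sum((coords[i, ] - coords[j, ])^2)))
  }
  Aaug <- rbind(cbind(A, 1), c(rep(1, k), 0))
  sol <- solve(Aaug, c(values, 0))
  vapply(seq_len(nrow(targets)), function(m) {
    s <- 0
    for (j in seq_len(k)) {
      s <- s + sol[j] * G(sqrt(sum((targets[m, ] - coords[j, ])^2)))
    }
    s + sol[k + 1]
  }, 0)
}
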