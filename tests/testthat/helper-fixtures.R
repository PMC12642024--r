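# Builders for small hand-constructed fixtures used across test files.

make_trials <- function(id, levels, responses) {
  validate_trials(data.frame(
    participant_id = id,
    trial_index = seq_along(levels),
    morph_level = levels,
    face_id = NA_character_,
    response = responses,
    stringsAsFactors = FALSE
  ))
}

# Deterministic noise-free level counts from a known curve: k = round(n * F).
noise_free_counts <- function(mu, sigma, n_per_level = 1000,
                              levels = c(-80, -40, -20, -10, 0, 10, 20, 40, 80),
                              gamma = 0, lambda = 0) {
  f <- gamma + (1 - gamma - lambda) * pnorm((levels - mu) / sigma)
  data.frame(level = levels, n_valid = n_per_level,
             k_happy = round(n_per_level * f))
}

# A perfectly attentive step observer (sigma ~ 0): happy iff level > 0.
step_observer_trials <- function(id = "step1") {
  des <- design_spec()
  levels <- rep(des$levels, des$trials_per_level)
  resp <- ifelse(levels > 0, "happy", ifelse(levels < 0, "angry", "happy"))
  make_trials(id, levels, resp)
}

expect_validation_error <- function(expr, pattern) {
  expect_error(expr, pattern)
}
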