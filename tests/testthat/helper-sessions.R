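# Shared fixture builders: all sessions are generated in code at test time.

avg_eye <- function() subject_eye_params(3, 1.5)

# A small session; noise off by default so geometric identities are exact.
tiny_session <- function(params = avg_eye(), rolls = c(0, 45, 90),
                         frames = 5, feature_sigma = 0, tracker_sigma = 0,
                         seed = 1, ...) {
  simulate_session(params,
                   protocol = fixation_protocol(rolls = rolls,
                                                frames_per_target = frames),
                   noise = noise_config(feature_sigma = feature_sigma,
                                        tracker_sigma = tracker_sigma,
                                        seed = seed),
                   ...)
}

# Angle (degrees) between two 3-vectors.
vec_angle_deg <- function(a, b) {
  acos(min(1, max(-1, sum(a * b) / sqrt(sum(a * a) * sum(b * b))))) * 180 / pi
}
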