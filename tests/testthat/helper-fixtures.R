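# Shared fixture builders; everything is generated in code at test time.

sim_store <- function(duration_s = 30, fps = 30, hr = 72, spo2 = 97,
                      noise_sd = 0.2, seed = 1, ...) {
  if (!is.list(hr)) hr <- list(type = "constant", value = hr)
  if (!is.list(spo2)) spo2 <- list(type = "constant", value = spo2)
  cfg <- sim_config(duration_s = duration_s, fps_colour = fps,
                    fps_ir = fps, hr = hr, spo2 = spo2,
                    noise_sd = noise_sd, seed = seed, ...)
  gt <- generate_ground_truth(cfg)
  list(cfg = cfg, gt = gt, store = generate_region_store(gt, cfg))
}

# Two well-separated sinusoidal sources through a well-conditioned mixing
# matrix: the standard toy problem for ICA/JADE validation.
toy_mixture <- function(fs = 30, dur = 10) {
  t <- seq(0, dur, by = 1 / fs)
  S <- rbind(sin(2 * pi * 1.2 * t), sin(2 * pi * 0.5 * t))
  A <- matrix(c(0.8, 0.3, 0.4, 0.9), 2, 2)
  list(S = S, X = A %*% S)
}

best_abs_cor <- function(candidates, source) {
  max(vapply(candidates,
             function(c) abs(cor(c$values, source)), numeric(1)))
}
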