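# channel-isolated models used across the suite; leak zeroed in the
# voltage-clamp isolations (ideal offline leak subtraction)

a_only_model <- function(...) {
  m <- isolate_channels(reference_cr_cell(...), "A")
  m$g_leak <- 0
  m
}

na_only_model <- function(e_na = 63, ...) {
  m <- isolate_channels(reference_cr_cell(...), "Na")
  m$g_leak <- 0
  modify_channel(m, "Na", e_rev = e_na)
}

h_only_model <- function(...) isolate_channels(reference_cr_cell(...), "h")

passive_model <- function(...) isolate_channels(reference_cr_cell(...), character(0))

# minimal recording wrapper for analysis functions that only need a trace
fake_vc_recording <- function(time, i, pre_duration, step_duration,
                              pre_level = -100, step_level = 20) {
  structure(list(
    data = data.frame(time = time, v = ifelse(time < pre_duration,
                                              pre_level, step_level), i = i),
    dt = diff(time[1:2]), mode = "vc",
    segments = data.frame(duration = c(pre_duration, step_duration),
                          level = c(pre_level, step_level)),
    label = "synthetic", seed = NA_integer_, noise_sd = 0,
    model_fingerprint = "synthetic"), class = "recording")
}
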