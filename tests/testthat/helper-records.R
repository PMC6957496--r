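# Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

clean_equine_record <- function() {
  fixture("clean_equine", function() {
    generate_record(beat_template("equine"),
                    rhythm_spec(60, 60, seed = 1),
                    noise_preset("clean"))
  })
}

filtered_equine_lead <- function() {
  fixture("filtered_equine_lead", function() {
    rec <- clean_equine_record()
    frec <- filter_record(rec)
    record_lead(frec, "II")
  })
}

# one isolated S-like deflection (negative Gaussian dip) on a zero baseline
s_dip_signal <- function(n, at, amp = -1.5, sigma_s = 0.010, fs = 500) {
  x <- numeric(n)
  i <- seq_len(n)
  x + amp * exp(-((i - at) / (sigma_s * fs))^2 / 2)
}
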