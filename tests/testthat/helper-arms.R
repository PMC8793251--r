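# Shared fixtures built in code.

# An arm mimicking the published case study: 17 of 30 patients beyond a 50%
# reduction, wide spread, several near-complete responses.
hofman_like_arm <- function() {
  cfg <- synthetic_arm_config(30, mu_log = -1.2, sigma_log = 1.1,
                              threshold = 50, seed = 2203L)
  generate_arm(cfg)
}

# Tiny deterministic arm for exact checks.
tiny_arm <- function(values = c(90, 55, 50, 10, -20, -120), d = 50)
  psa_dataset(values, threshold = d)

write_tmp_arm <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
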