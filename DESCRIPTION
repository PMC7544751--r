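Package: handdose
Title: Monte Carlo Extremity Dosimetry for Shielded-Syringe Radiopharmaceutical Handling
Version: 0.1.0
Authors@R:
    person("handdose", "developers", email = "handdose@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo assessment of per-finger skin doses,
    expressed as the personal dose equivalent Hp(0.07), to the dominant hand
    of workers handling a tungsten-shielded syringe of a positron-emitting
    radiopharmaceutical (F-18 FDG). Provides a constructive-solid-geometry
    scene (air world, mathematical hand model, shielded syringe), an F-18
    beta-plus decay and annihilation-photon source, analog photon transport
    with Klein-Nishina Compton sampling under the kerma approximation,
    per-region energy-deposition tallies with history-by-history statistics,
    dose-versus-decays slope fitting with extrapolation to a handling
    scenario (activity times handling time), conversion to Hp(0.07) with
    Q(L) = 1, and comparison of simulated doses against measured
    thermoluminescent dosimeter records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
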