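Package: attractormask
Title: Spiking Cortical Attractor-Network Simulation of Metacontrast Backward Masking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates a biophysical spiking model of early visual
    cortex (LGN, V1 and V2) in which visual features are stored as sparse,
    distributed attractor memory patterns spanning cortical minicolumns.
    Conductance-based multi-compartment neurons (pyramidal, basket and RSNP
    interneurons plus LGN relay cells) are wired into hypercolumn
    microcircuits with lateral inhibition, long-range within-pattern
    excitation, di-synaptic inhibition between competing patterns, and
    delayed feedforward/feedback projections between V1 and V2. The package
    implements the full metacontrast backward-masking protocol - brief
    target, trailing mask, sliding stimulus onset asynchrony (SOA), multiple
    simulated individuals and trials - together with attractor-completion
    detection, masking-curve aggregation and type-A/type-B masking
    classification, for studying how lateral inhibition and cortico-cortical
    feedback shape visual masking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
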