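Package: eyestate
Title: Camera-Free Eye-State Detection from Functional MRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Determines whether a subject's eyes were open or closed at each
    time point of a functional MRI (EPI) acquisition, using the images alone.
    The eye bulbs are segmented inside per-eye regions of interest with a
    continuous max-flow (convex min-cut) formulation, each bulb is reduced to
    its maximum-diameter orientation vector and axis angles, and the mean
    in-bulb MR intensity is tracked over time, band-pass filtered in the BOLD
    band and rescaled. Eye state is classified by thresholds learned from
    distribution tails on a training fraction of the run and evaluated by
    jackknife congruency against a known stimulus protocol. A synthetic
    ovoid-bulb phantom generator provides a fully controlled test bed with
    ground truth. Includes a minimal NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
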