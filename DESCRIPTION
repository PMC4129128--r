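Package: adlsense
Title: Rule-Based Recognition of Activities of Daily Living from Ambient
    Smart-Home Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-intrusive recognition of eight activities of daily living
    (ADL) from ambient smart-home sensor streams. Provides the full chain of a
    wireless sensor deployment without any hardware: a packet model with
    even-parity error handling, a compartment-wise bucket sort followed by a
    chronological least-significant-digit radix sort, a declarative rule
    repository driving a forward-chaining inference engine with priority-based
    conflict resolution, and event-level sensitivity/specificity evaluation
    with activity-map rendering. A synthetic single-occupant home simulator
    (agent-based daily routine plus per-channel emission models for
    temperature, humidity, luminance, passive-infrared motion and
    acceleration) generates labelled benchmark data for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
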