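Package: dissolvr
Title: Mixing-Time and Dissolution-Time Analytics for Reconstitution Devices
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify macromixing and powder dissolution in small
    stirred vessels such as autoinjector reconstitution chambers. Extracts
    per-pixel discoloration thresholds and percent-mixed curves from
    grayscale video of a decolorization assay, reports the 90%-mixed time
    (t90) and first-mixed maps; normalizes raw conductivity traces per run
    to 0-100% and extracts dissolution t90 with window censoring; provides
    one-way ANOVA with Tukey HSD, full-factorial effect screening,
    two-sample t-tests, cell-mean response tables, and an impeller
    Reynolds-number scale-up helper. A synthetic-data generator with
    closed-form ground truth (exponential discoloration videos, first-order
    conductivity traces, planted-effect factorial designs) makes the whole
    pipeline verifiable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
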