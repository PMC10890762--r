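Package: mestress
Title: Stress-Coupled Metabolism and Expression Models at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based modeling of microbial growth under combined
    thermal, acid and oxidative stress with metabolism-and-expression (ME)
    coupling: enzyme synthesis costs scale with growth rate through
    effective turnover rates (keff), and the maximal growth rate is located
    by bisection over growth-rate-parameterized linear programs solved with
    a built-in bounded-variable simplex. Includes temperature-dependent
    protein stability and a chaperone folding network (DnaK, GroEL, Lon),
    pH-dependent periplasmic stability with HdeB protection plus membrane
    lipid and activity responses, reactive-oxygen-species damage and repair
    of metalloproteins (demetallation, mismetallation, Fe-S cluster cycling,
    Fenton chemistry, Dps sequestration), kinetome management with a
    single-effect keff sensitivity screen, flux variability analysis,
    proteome mass-fraction analytics, condition-grid simulation with CSV
    reports, and a deterministic synthetic mini-model generator that
    exercises every mechanism without an external reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
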