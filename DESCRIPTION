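Package: aortasim
Title: Digital Twin of a Hardware Cardiovascular Simulator for Central
    Aortic Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates central aortic blood-pressure waveforms by
    superposing forward and reflected pressure waves in a geometrically and
    mechanically faithful model of an artificial aorta (tapered silicone
    vessel, aortic-bifurcation reflection site, two-element Windkessel
    terminal load), and provides a pulse-wave-analysis toolkit: systolic and
    diastolic pressure, mean arterial pressure, pulse pressure, augmentation
    pressure and index, foot-to-foot pulse transit time, and forward and
    inverse Moens-Korteweg pulse wave velocity. Includes scripted parameter
    sweeps over heart rate, stroke volume, peripheral resistance and
    transmural pressure, with machine-checkable trend reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
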