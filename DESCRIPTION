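Package: loricaballast
Title: Biomineral Ballast Accounting for Agglomerated Tintinnid Loricae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-quantitative accounting of the biomineral ballast (coccolith
    calcium carbonate and diatom biogenic silica) that some planktonic tintinnid
    ciliates agglomerate onto their loricae. Converts per-lorica particle-count
    ledgers into per-lorica ballast estimates using literature lith masses and a
    biovolume-to-silica conversion, summarises assemblages (means, population
    standard deviations, occurrence counts), derives ecological metrics
    (extra-lorica-weight fraction, regional ballast ratios, a size-ordered
    taxon-preference matrix), and simulates ledgers under a size-selective
    particle-capture model with a coccolith-scarcity shift to diatom fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
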