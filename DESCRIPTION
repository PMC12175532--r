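Package: RubiscoTherm
Title: Rubisco Carboxylation Trade-Offs and Thermal Adaptation Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the carboxylation/oxygenation trade-off between Rubisco
    enzyme forms (II, IAc, IAq) across CO2, O2 and temperature using
    competitive-inhibition Michaelis-Menten kinetics, Arrhenius temperature
    scaling of kinetic parameters and the carbon cost of phosphoglycolate
    salvage, and scores Rubisco protein sequences for signals of cold or hot
    thermal adaptation with ten amino-acid composition and physicochemical
    indices tested against a mesophilic reference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
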