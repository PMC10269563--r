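#!/usr/bin/env Rscript
# Regenerate the plain-text fixtures shipped under inst/extdata.
suppressMessages(library(fermdfba))
write_sbml(build_toy_model(), "inst/extdata/toy_network.xml",
           model_id = "toy_yeast_fermentation")
cat("wrote inst/extdata/toy_network.xml\n")
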