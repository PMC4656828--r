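#!/usr/bin/env Rscript
# Build the two-microcosm input bundle (uric-acid vs ammonium biostimulation)
# under results/fixture/. The bundle is an aggregate-preserving
# disaggregation of the published counts; the manifest records every
# constraint the build satisfies.

library(aromnet)

fx <- build_ancona_fixture(dir = "results/fixture")

message("bundle written to ", fx$dir)
message("constraints satisfied: ", sum(fx$manifest$status == "satisfied"),
        " / ", nrow(fx$manifest),
        " (", sum(fx$manifest$status == "deviates"), " documented deviation)")
print(fx$manifest, n = Inf)
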