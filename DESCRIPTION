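Package: srnaforge
Title: Design of Synthetic Bacterial Small RNAs and Golden Gate Assembly Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs antisense seed regions for synthetic bacterial small
    regulatory RNAs (sRNAs) against annotated mRNA targets and turns the
    chosen designs into verified, scarless Golden Gate cloning plans.
    Candidate seeds are enumerated over a user-defined mRNA binding window,
    screened genome-wide for off-targets with an ungapped seed-and-extend
    scan under Karlin-Altschul E-value statistics, scored with
    nearest-neighbor duplex hybridization energies, and compared against the
    wild-type sRNA with a McCaskill-style partition function and a
    base-pairing-profile distance. The assembly designer computes scarless
    type IIS junction overhangs, checks overhang fidelity, designs annealing
    oligonucleotides and PCR primers with nearest-neighbor melting
    temperatures, simulates the one-pot digestion-ligation, and writes
    ordering sheets and GenBank records of the expected constructs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
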