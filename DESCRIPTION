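Package: phosphoswitch
Title: Predicting Enabling and Disabling Phosphosite Switches at
    Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates log-odds residue pair-potentials over 23 residue
    classes (the 20 amino acids plus phosphoserine, phosphothreonine and
    phosphotyrosine) from contacts observed at protein-protein interfaces,
    computes the Interaction Effect (IE) of phosphorylating a serine,
    threonine or tyrosine that sits in an interface, and combines IE with
    template sequence identity (f_ID) and orthologue conservation (f_Cons)
    into the switch score S_switch = IE * f_ID * f_Cons.  Sites with
    |S_switch| above a threshold are called enabling (interaction
    strengthened) or disabling (weakened).  Includes structure parsing with
    phosphoresidue detection, interface contact extraction, side-chain
    accessible surface area, sequence-to-structure site mapping, redundancy
    grouping, exposure-matched shuffled negative benchmark construction,
    ROC/PR evaluation with threshold selection at a fixed false positive
    rate, cross-validated logistic regression, and synthetic-fixture
    generators for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
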