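Package: GrooveFlex
Title: Geometric Analysis of Conformational Flexibility in the MHC Class I
    Peptide-Binding Groove
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing conformational flexibility at the
    N-terminus of the MHC class I peptide-binding groove. Reads crystal
    structures (PDB/mmCIF) and multi-model coordinate trajectories, detects
    unmodeled (missing-density) residue ranges, superposes structures and
    measures per-position peptide C-alpha displacements, extracts
    hydrogen-bond and hydrophobic contact networks, computes per-residue
    RMSF profiles, evaluates aromatic ring stacking (pi-pi) and CH-pi
    interaction geometry between the peptide P1 anchor and groove residues
    Tyr59/Ile52, tracks rotation of the peptide terminal amino group via a
    dihedral angle with unwrapping, sliding-window smoothing and event
    detection, and extracts melting temperatures from thermal-denaturation
    fluorescence curves. A synthetic-data module generates every input kind
    with known ground truth so all stages are testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
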