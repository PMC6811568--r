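Package: hostlattice
Title: Host-Guest Crystal Lattice Engineering Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for engineering host:guest protein crystal
    lattices. Screens candidate host lattices by Matthews coefficient and
    solvent content, parses and expands space-group symmetry to enumerate
    crystal packing neighbours, quantifies crystal contacts by
    solvent-accessible surface area, enumerates rigid shared-helix fusion
    orientations of a binder domain by stepwise helical linker extension,
    scans packed lattices for engineerable intra- and inter-molecular
    disulfide crosslinks, sizes guest cavities, and analyses model rigidity
    (Kabsch superposition RMSD, per-domain B-factor statistics, atom census).
    Reads and writes PDB (with hybrid-36 serials) and mmCIF coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
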