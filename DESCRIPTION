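Package: ttfieldsim
Title: Voxel-Based Simulation of Tumor Treating Fields in Head Phantoms
Version: 0.1.0
Authors@R:
    person("TTFieldsim", "Developers", email = "ttfieldsim@example.org",
           role = c("aut", "cre"))
Description: Simulates the delivery of tumor treating fields (TTFields),
    200 kHz alternating electric fields applied through scalp transducer
    arrays, in synthetic voxel head phantoms. Builds concentric-layer head
    phantoms with a two-compartment glioblastoma (enhancing shell and
    necrotic core), an optional craniectomy window refilled with scalp
    tissue, and two opposed 3x3 transducer arrays coupled through hydrogel
    pads. Solves the electro-quasistatic volume-conductor equation
    div((sigma + i*omega*eps)*grad(phi)) = 0 with a finite-volume scheme on
    the voxel grid, including a contact-impedance thin-film condition for an
    insulating layer between transducer and gel. Computes dose and
    thermogenesis metrics: per-tissue field statistics, above-threshold
    volumes of the tumor shell, per-gel Joule heating power, and the
    power-normalized field strength used to compare intact-skull,
    defective-skull and insulated treatment cases. Closed-form layered-slab
    and concentric-sphere solutions are included as validation oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
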