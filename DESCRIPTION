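Package: protrender
Title: Sketch-Based Photorealistic-Style Rendering of Protein Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts protein structures into simplified two-dimensional
    atom-sphere "sketch" images in which the red and green channels encode
    the chemical element and the blue channel encodes depth from a virtual
    camera.  Provides a deterministic analytic renderer that turns the same
    scenes into photorealistic-style target images (diffuse lighting,
    ambient-occlusion proxy, fade-to-white fog, optional cast shadows), a
    paired-image corpus builder with structure-level augmentation, a
    conditional adversarial image-to-image translator (U-Net generator with
    instance normalization plus a patch discriminator) that learns the
    sketch-to-render mapping, a matrix-based post-inference colorization
    procedure, and a command-line animation driver (still, rock, turntable,
    zoom) for multi-frame PDB trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
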