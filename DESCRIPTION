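Package: demarcate
Title: Unsupervised Demarcation-Line Candidates for Magnifying Endoscopy
    Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Proposes demarcation-line (DL) candidates between gastric
    cancer lesions and background mucosa on magnifying narrow-band imaging
    (M-NBI) endoscopy stills, without any annotated training data. The
    pipeline segments an image into SLIC superpixels on smoothed CIE
    L*a*b* planes, summarises every superpixel by a 12-dimensional feature
    vector (mean L*, a*, b*, H, S, V plus the local Shannon entropy of
    each plane), groups superpixels by multi-trial k-means with k-means++
    seeding, and extracts pixel-level cluster boundaries as DL candidates
    over a sweep of cluster counts. Includes the nearest-pixel Euclidean
    distance metric for scoring candidates against expert-drawn DLs, and a
    seeded synthetic-image generator with known ground-truth boundaries
    for benchmarking every stage.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
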