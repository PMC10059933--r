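Package: ChromaThresh
Title: Two-Stage Automatic Color Thresholding in HSV Chromaticity Space
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Unsupervised two-stage background suppression for 8-bit color
        images based on the chromaticity (hue and saturation) of the pixels.
        Stage one derives image-wide background hue and saturation ranges from
        smoothed channel probability mass functions using a gradient/area
        nomination rule followed by maximum-continuous-range selection; stage
        two refines the result inside every sufficiently large foreground blob
        by re-deriving confined local ranges. Includes the Dice similarity
        index, Matthews correlation coefficient and PSNR evaluation metrics, a
        deterministic synthetic board/lesion image generator with ground-truth
        masks, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, grDevices, utils, EBImage, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
biocViews: ImageProcessing, Segmentation, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
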