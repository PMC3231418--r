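Package: frostmap
Title: Unsupervised Frost-Damage Classification of Crop Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies colour photographs of cereal canopies (oat crops after
    frost) into damage classes without training data. Images are converted to
    CIE L*a*b*; each channel histogram is split by a fused automatic threshold
    (average of Isodata, Otsu and fuzzy-entropy thresholds); pixels are coded
    and labelled across the three channels; spectrally overlapping classes are
    merged under a within- versus between-class variance criterion, with the
    number of classes emerging dynamically. Includes the accuracy-assessment
    framework used to validate such thematic maps: multinomial sample-size
    design, polygon sample units, deterministic and fuzzy error matrices, and
    classifier's/expert's accuracies with commission and omission errors. A
    synthetic field-scene generator with known ground truth supports testing
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, EBImage, jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
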