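Package: fpquant
Title: Automated Detection, Quantification and Spatial Mapping of
    Fungiform Papillae in Tongue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, counts, sizes and spatially maps fungiform papillae
    on colour photographs of the anterior 2 cm of an unstained human
    tongue.  Tissue classes (fungiform papillae, filiform papillae,
    tongue base) are learned as mean CIELAB colours from user regions of
    interest and every pixel is assigned to its nearest colour marker by
    Euclidean distance; papillae are extracted as connected components
    and summarised per tongue side, 1-cm band and 16-grid partition,
    including the conventional 6-mm circle count near the tongue tip.
    Ships a seeded synthetic tongue-image generator with exact ground
    truth for end-to-end validation, and the method-agreement statistics
    used to validate automated against manual counts (Bland-Altman
    limits of agreement, two-way random absolute-agreement intraclass
    correlation, Spearman correlation, forward stepwise regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
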