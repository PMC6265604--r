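Package: mrmcsize
Title: Power and Sample Size for Multireader Multicase Diagnostic Studies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical power and minimal case sample sizes for multireader
    multicase (MRMC) reader-performance studies, such as ROC studies comparing
    two diagnostic imaging modalities, under the Obuchowski-Rockette
    correlated-error ANOVA model.  Supports three inference situations (readers
    and cases random, readers fixed, cases fixed), nonequivalence and
    noninferiority hypotheses, and split-plot study designs in addition to the
    fully crossed factorial design.  Includes conversion utilities for
    Dorfman-Berbaum-Metz variance components and conjectured parameter inputs
    (Obuchowski's error-variance formula, test-by-reader variance from a
    plausible range of between-test reader differences), and a Monte Carlo
    simulator of the model used to validate the analytic power formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
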