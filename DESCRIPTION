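Package: mvtforage
Title: Marginal Value Theorem Analysis of Supermarket Foraging Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing survey records of human foraging trips to
    supermarkets under the marginal value theorem (MVT). Models cumulative
    gain in a patch as an asymptotic exponential curve g(T) = A(1 - exp(-kT)),
    fits it by nonlinear orthogonal-distance regression (appropriate when
    both residence time and gain are self-reported with error), predicts
    round-trip travel times from the tangent-line optimality condition, and
    provides the surrounding pipeline: a synthetic survey generator,
    exclusion and subset filters, agglomerative hierarchical clustering with
    elbow selection, residual diagnostics (chi-square(2) Q-Q of squared
    orthogonal residuals, observed-versus-predicted bias regression), and
    paired and Welch t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
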